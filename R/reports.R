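# Report and manifest I/O. Reports live in long form: one row per
# (lesion, rater, session, variable) with a categorical value. Two on-disk
# formats: nested JSON (one record per lesion x rater x session with a values
# mapping) and long CSV with columns lesion_id, rater_id, session, variable,
# value. Missing values are simply absent; the NOT_APPLICABLE sentinel is a
# stored value, so rater omission and explicit non-applicability stay distinct.

.report_cols <- c("lesion_id", "rater_id", "session", "variable", "value")

#' Construct a lesion manifest
#'
#' The manifest fixes the study composition: one row per lesion with its
#' prostate zone (`PZ`, `TZ`, or `AFMS`) and clinical-significance label.
#' Note the manifest zone is a study-level field distinct from the
#' `lesion_location` report CDE (whose domain has no AFMS level).
#'
#' @param lesion_id Character vector of unique lesion identifiers.
#' @param zone Zone per lesion, each one of `"PZ"`, `"TZ"`, `"AFMS"`.
#' @param clinically_significant Logical vector: histopathology-confirmed
#'   clinically significant cancer.
#' @return A data frame of class `lesion_manifest`.
#' @export
lesion_manifest <- function(lesion_id, zone, clinically_significant) {
  lesion_id <- as.character(lesion_id)
  if (anyDuplicated(lesion_id)) {
    stop_piradscde("duplicate lesion_id in manifest", "manifest_error")
  }
  if (!all(zone %in% c("PZ", "TZ", "AFMS"))) {
    stop_piradscde("zone must be one of PZ, TZ, AFMS", "manifest_error")
  }
  out <- data.frame(lesion_id = lesion_id, zone = as.character(zone),
                    clinically_significant = as.logical(clinically_significant),
                    stringsAsFactors = FALSE)
  class(out) <- c("lesion_manifest", "data.frame")
  out
}

as_reports <- function(df) {
  missing_cols <- setdiff(.report_cols, names(df))
  if (length(missing_cols)) {
    stop_piradscde(sprintf("report table lacks column(s): %s",
                           paste(missing_cols, collapse = ", ")),
                   "report_format_error")
  }
  df <- df[, .report_cols]
  df$lesion_id <- as.character(df$lesion_id)
  df$rater_id <- as.character(df$rater_id)
  df$session <- as.integer(df$session)
  df$variable <- as.character(df$variable)
  df$value <- as.character(df$value)
  key <- do.call(paste, c(df[c("lesion_id", "rater_id", "session", "variable")], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("lesion_id", "rater_id", "session", "variable")]
    stop_piradscde(
      sprintf("duplicate report record(s), e.g. lesion %s / rater %s / session %d / %s",
              dup$lesion_id[1], dup$rater_id[1], dup$session[1], dup$variable[1]),
      "duplicate_record_error"
    )
  }
  df[order(df$lesion_id, df$rater_id, df$session, df$variable), , drop = FALSE]
}

#' Read and write CDE lesion reports
#'
#' Reports are exchanged as nested JSON (records with `lesion_id`,
#' `rater_id`, `session`, and a `values` object) or as long CSV with columns
#' `lesion_id, rater_id, session, variable, value`. A JSON file may embed the
#' lesion manifest. Reading is round-trip stable with writing.
#'
#' @param path File path.
#' @param format `"json"` or `"csv"`; inferred from the file extension when
#'   omitted.
#' @param schema Optional `cde_schema`; when supplied, variable names outside
#'   the schema raise an `unknown_variable_error`.
#' @return `read_reports()`: a list with `reports` (long data frame) and
#'   `manifest` (a `lesion_manifest` or `NULL`).
#' @export
read_reports <- function(path, format = c("auto", "json", "csv"), schema = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    stop_piradscde(sprintf("no such file: %s", path), "io_error")
  }
  manifest <- NULL
  if (format == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    recs <- lapply(doc$reports, function(r) {
      vals <- unlist(r$values)
      if (length(vals) == 0L) return(NULL)
      data.frame(lesion_id = r$lesion_id, rater_id = r$rater_id,
                 session = r$session, variable = names(vals),
                 value = unname(vals), stringsAsFactors = FALSE)
    })
    reports <- do.call(rbind, recs)
    if (length(doc$manifest)) {
      m <- do.call(rbind, lapply(doc$manifest, as.data.frame))
      manifest <- lesion_manifest(m$lesion_id, m$zone, m$clinically_significant)
    }
  } else {
    reports <- utils::read.csv(path, stringsAsFactors = FALSE,
                               colClasses = "character")
  }
  reports <- as_reports(reports)
  if (!is.null(schema)) {
    bad <- setdiff(unique(reports$variable), names(schema$variables))
    if (length(bad)) {
      stop_piradscde(sprintf("unknown variable name(s) in reports: %s",
                             paste(bad, collapse = ", ")),
                     "unknown_variable_error")
    }
  }
  list(reports = reports, manifest = manifest)
}

#' @rdname read_reports
#' @param reports Long report data frame (see [read_reports()]).
#' @param manifest Optional `lesion_manifest`, embedded in JSON output.
#' @export
write_reports <- function(reports, path, format = c("auto", "json", "csv"),
                          manifest = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  reports <- as_reports(reports)
  if (format == "csv") {
    utils::write.csv(reports, path, row.names = FALSE)
  } else {
    key <- unique(reports[, c("lesion_id", "rater_id", "session")])
    recs <- lapply(seq_len(nrow(key)), function(i) {
      sub <- reports[reports$lesion_id == key$lesion_id[i] &
                     reports$rater_id == key$rater_id[i] &
                     reports$session == key$session[i], ]
      list(lesion_id = key$lesion_id[i], rater_id = key$rater_id[i],
           session = key$session[i],
           values = as.list(stats::setNames(sub$value, sub$variable)))
    })
    doc <- list(reports = recs)
    if (!is.null(manifest)) {
      doc$manifest <- lapply(seq_len(nrow(manifest)), function(i) as.list(manifest[i, ]))
    }
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname lesion_manifest
#' @param path File path for CSV manifest I/O.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  lesion_manifest(m$lesion_id, m$zone, as.logical(m$clinically_significant))
}

#' @rdname lesion_manifest
#' @param manifest A `lesion_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

# Extract one report as a named value vector.
report_values <- function(reports, lesion, rater, session) {
  sub <- reports[reports$lesion_id == lesion & reports$rater_id == rater &
                 reports$session == session, ]
  stats::setNames(sub$value, sub$variable)
}

#' Validate a set of reports
#'
#' Applies [validate_report()] to every (lesion, rater, session) record in a
#' long report table.
#' @inheritParams validate_report
#' @param reports Long report data frame.
#' @return Data frame of violations with identifying columns prepended.
#' @export
validate_reports <- function(reports, schema, mode = c("strict", "partial")) {
  mode <- match.arg(mode)
  reports <- as_reports(reports)
  key <- unique(reports[, c("lesion_id", "rater_id", "session")])
  out <- lapply(seq_len(nrow(key)), function(i) {
    vals <- report_values(reports, key$lesion_id[i], key$rater_id[i], key$session[i])
    v <- validate_report(vals, schema, mode)
    if (nrow(v) == 0L) return(NULL)
    cbind(key[rep(i, nrow(v)), , drop = FALSE], v, row.names = NULL)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- cbind(key[0, , drop = FALSE],
                 data.frame(variable = character(), value = character(),
                            rule = character(), message = character()))
  }
  out
}
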
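# Declarative PI-RADS v2.1 scoring engine. Rule content ships as a versioned
# JSON document (ordered decision lists per sequence and zone) rather than as
# code, so the clinically contested parts of the guideline encoding are
# reviewable data. Engine semantics: within a block the first rule whose
# predicate holds determines the score; a predicate is a disjunction of
# conjunctive variable-in-values clauses; a rule flagged "otherwise" is an
# explicit catch-all. The overall-assessment blocks are written exhaustively
# and mutually exclusively with no catch-all, so every cell of the
# (t2w, dwi, dce) product is owned by exactly one rule.

.engine_cache <- new.env(parent = emptyenv())

default_schema <- function() {
  if (is.null(.engine_cache$schema)) .engine_cache$schema <- load_schema()
  .engine_cache$schema
}

default_rules <- function() {
  if (is.null(.engine_cache$rules)) .engine_cache$rules <- load_rules()
  .engine_cache$rules
}

#' Load a PI-RADS scoring rule table
#'
#' @param path Path to a rule-table JSON document; `NULL` loads the shipped
#'   PI-RADS v2.1 encoding.
#' @return An object of class `pirads_rules`.
#' @export
load_rules <- function(path = NULL) {
  path <- path %||% pkg_file("extdata", "pirads_rules.json")
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$sequences)) {
    stop_piradscde("rule table lacks a 'sequences' element", "rule_parse_error")
  }
  structure(list(version = doc$version %||% "unversioned",
                 sequences = doc$sequences),
            class = "pirads_rules")
}

#' @export
print.pirads_rules <- function(x, ...) {
  cat(sprintf("<pirads_rules %s>\n", x$version))
  for (seq_name in names(x$sequences)) {
    for (zone in names(x$sequences[[seq_name]])) {
      cat(sprintf("  %s/%s: %d rules\n", seq_name, zone,
                  length(x$sequences[[seq_name]][[zone]])))
    }
  }
  invisible(x)
}

rule_block <- function(rules, sequence, zone = NULL) {
  blk <- rules$sequences[[sequence]]
  if (is.null(blk)) {
    stop_piradscde(sprintf("rule table has no '%s' block", sequence), "rule_parse_error")
  }
  if (!is.null(blk$ALL)) return(blk$ALL)
  z <- if (identical(zone, "AFMS")) "TZ" else zone  # AFMS scored with the TZ rule set
  out <- blk[[z]]
  if (is.null(out)) {
    stop_piradscde(sprintf("no '%s' rules for zone '%s'", sequence, zone %||% "<none>"),
                   "rule_parse_error")
  }
  out
}

rule_target <- function(rule) rule$score %||% rule$category %||% rule$result

referenced_vars <- function(block) {
  unique(unlist(lapply(block, function(r) unlist(lapply(r$when, names)))))
}

# Scalar decision-list evaluation. `values` is a named list/vector; all
# referenced variables must be populated (not NA, not the NOT_APPLICABLE
# sentinel) or an incomplete-report error names them.
eval_decision_list <- function(block, values, what = "score") {
  vars <- referenced_vars(block)
  vals <- lapply(vars, function(v) {
    x <- values[[v]]
    if (is.null(x) || is.na(x) || identical(as.character(x), NOT_APPLICABLE)) NULL
    else as.character(x)
  })
  names(vals) <- vars
  missing <- vars[vapply(vals, is.null, TRUE)]
  if (length(missing)) {
    stop_piradscde(sprintf("cannot compute %s: required CDE(s) missing: %s",
                           what, paste(missing, collapse = ", ")),
                   "incomplete_report_error", variables = missing)
  }
  for (rule in block) {
    if (isTRUE(rule$otherwise)) return(rule_target(rule))
    for (clause in rule$when) {
      ok <- all(vapply(names(clause), function(v) {
        vals[[v]] %in% as.character(unlist(clause[[v]]))
      }, TRUE))
      if (ok) return(rule_target(rule))
    }
  }
  stop_piradscde("no rule fired; the rule table is incomplete for this input",
                 "rule_gap_error")
}

prepare_report_values <- function(report, schema) {
  vals <- as.list(report)
  for (nm in intersect(names(vals), names(schema$variables))) {
    vals[[nm]] <- normalize_value(schema, nm, as.character(vals[[nm]]))
  }
  vals
}

check_zone <- function(zone) {
  if (!is.character(zone) || length(zone) != 1L || !zone %in% c("PZ", "TZ", "AFMS")) {
    stop_piradscde("zone must be one of 'PZ', 'TZ', 'AFMS'", "domain_error")
  }
  zone
}

require_adequate <- function(values, flags, what) {
  for (f in flags) {
    v <- values[[f]]
    if (is.null(v) || is.na(v)) {
      stop_piradscde(sprintf("cannot compute %s: required CDE(s) missing: %s", what, f),
                     "incomplete_report_error", variables = f)
    }
    if (!identical(as.character(v), "YES")) {
      stop_piradscde(sprintf("cannot compute %s: %s = %s", what, f, v),
                     "sequence_unavailable_error")
    }
  }
}

#' Score a CDE lesion report with the PI-RADS v2.1 rule engine
#'
#' `score_t2w()` and `score_dwi()` map a completed CDE report to the T2W and
#' DWI/ADC sequence scores (integers 1-5); `score_dce()` returns the
#' three-outcome DCE result (`"Positive"`, `"Negative"`, or `"X"` when the
#' DCE sequence is absent or inadequate); `overall_category()` combines the
#' sequence results into the overall assessment category with the
#' zone-dependent dominant-sequence logic (DWI dominates in the peripheral
#' zone, T2W in the transition zone and anterior stroma, which is scored with
#' the TZ rule set). `score_report()` runs all four.
#'
#' Scoring is strict: a referenced CDE that is missing raises an
#' `incomplete_report_error` listing the absent variables; no imputation is
#' performed.
#'
#' @param report Named character vector or list of CDE values (one lesion,
#'   one rater, one session).
#' @param zone Lesion zone, one of `"PZ"`, `"TZ"`, `"AFMS"`.
#' @param rules A `pirads_rules` table; default is the shipped encoding.
#' @param schema A `cde_schema` used to normalize alias spellings.
#' @return An integer score 1-5 (`score_t2w`, `score_dwi`,
#'   `overall_category`), a character DCE result (`score_dce`), or a list
#'   with `t2w_score`, `dwi_score`, `dce_result`, `overall` (`score_report`).
#' @examples
#' rep <- c(lesion_dim_max = ">=15", t2w_present_and_adequate = "YES",
#'          t2w_abnormality = "NO")
#' score_t2w(rep, zone = "PZ")  # 1
#' @export
score_t2w <- function(report, zone, rules = default_rules(), schema = default_schema()) {
  check_zone(zone)
  vals <- prepare_report_values(report, schema)
  require_adequate(vals, "t2w_present_and_adequate", "T2W score")
  as.integer(eval_decision_list(rule_block(rules, "t2w", zone), vals, "T2W score"))
}

#' @rdname score_t2w
#' @export
score_dwi <- function(report, zone, rules = default_rules(), schema = default_schema()) {
  check_zone(zone)
  vals <- prepare_report_values(report, schema)
  require_adequate(vals, c("dwi_present_and_adequate", "adc_present_and_adequate"),
                   "DWI score")
  as.integer(eval_decision_list(rule_block(rules, "dwi", zone), vals, "DWI score"))
}

#' @rdname score_t2w
#' @export
score_dce <- function(report, rules = default_rules(), schema = default_schema()) {
  vals <- prepare_report_values(report, schema)
  flag <- vals[["dce_present_and_adequate"]]
  if (is.null(flag) || is.na(flag)) {
    stop_piradscde("cannot compute DCE result: required CDE(s) missing: dce_present_and_adequate",
                   "incomplete_report_error", variables = "dce_present_and_adequate")
  }
  if (identical(as.character(flag), "NO")) return("X")
  as.character(eval_decision_list(rule_block(rules, "dce"), vals, "DCE result"))
}

#' @rdname score_t2w
#' @param t2w,dwi Sequence scores, integers 1-5.
#' @param dce DCE result, one of `"Positive"`, `"Negative"`, `"X"`.
#' @export
overall_category <- function(t2w, dwi, dce, zone, rules = default_rules()) {
  check_zone(zone)
  if (!t2w %in% 1:5 || !dwi %in% 1:5) {
    stop_piradscde("sequence scores must be integers in 1..5", "domain_error")
  }
  if (!dce %in% c("Positive", "Negative", "X")) {
    stop_piradscde("dce must be 'Positive', 'Negative' or 'X'", "domain_error")
  }
  vals <- list(t2w = as.character(t2w), dwi = as.character(dwi), dce = dce)
  as.integer(eval_decision_list(rule_block(rules, "overall", zone), vals,
                                "overall category"))
}

#' @rdname score_t2w
#' @export
score_report <- function(report, zone, rules = default_rules(),
                         schema = default_schema()) {
  t2w <- score_t2w(report, zone, rules, schema)
  dwi <- score_dwi(report, zone, rules, schema)
  dce <- score_dce(report, rules, schema)
  list(t2w_score = t2w, dwi_score = dwi, dce_result = dce,
       overall = overall_category(t2w, dwi, dce, zone, rules))
}

#' Score every report in a long report table
#'
#' @param reports Long report data frame (see [read_reports()]).
#' @param manifest A [lesion_manifest()] supplying each lesion's zone.
#' @inheritParams score_t2w
#' @return Data frame with one row per (lesion, rater, session) and columns
#'   `t2w_score`, `dwi_score`, `dce_result`, `overall`.
#' @export
score_reports <- function(reports, manifest, rules = default_rules(),
                          schema = default_schema()) {
  reports <- as_reports(reports)
  zone_of <- stats::setNames(manifest$zone, manifest$lesion_id)
  key <- unique(reports[, c("lesion_id", "rater_id", "session")])
  bad <- setdiff(unique(key$lesion_id), names(zone_of))
  if (length(bad)) {
    stop_piradscde(sprintf("lesion(s) absent from manifest: %s",
                           paste(bad, collapse = ", ")), "manifest_error")
  }
  res <- lapply(seq_len(nrow(key)), function(i) {
    vals <- report_values(reports, key$lesion_id[i], key$rater_id[i], key$session[i])
    s <- score_report(vals, zone_of[[key$lesion_id[i]]], rules, schema)
    data.frame(key[i, , drop = FALSE], t2w_score = s$t2w_score,
               dwi_score = s$dwi_score, dce_result = s$dce_result,
               overall = s$overall, row.names = NULL)
  })
  do.call(rbind, res)
}

# Domains for the synthetic variables of the overall-assessment block.
.overall_domains <- list(t2w = as.character(1:5), dwi = as.character(1:5),
                         dce = c("Positive", "Negative", "X"))

block_grid <- function(block, schema) {
  vars <- referenced_vars(block)
  domains <- lapply(vars, function(v) {
    if (v %in% names(.overall_domains)) .overall_domains[[v]]
    else schema_domain(schema, v)
  })
  names(domains) <- vars
  do.call(expand.grid, c(domains, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
}

# Vectorized rule matching over an enumeration grid: returns a logical
# matrix inputs x rules (otherwise-rules match everything).
match_matrix <- function(block, grid) {
  n <- nrow(grid)
  sapply(block, function(rule) {
    if (isTRUE(rule$otherwise)) return(rep(TRUE, n))
    hit <- rep(FALSE, n)
    for (clause in rule$when) {
      m <- rep(TRUE, n)
      for (v in names(clause)) {
        m <- m & grid[[v]] %in% as.character(unlist(clause[[v]]))
      }
      hit <- hit | m
    }
    hit
  })
}

first_match_target <- function(block, mm) {
  n <- nrow(mm)
  idx <- rep(NA_integer_, n)
  for (j in seq_along(block)) {
    idx[is.na(idx) & mm[, j]] <- j
  }
  targets <- vapply(block, function(r) as.character(rule_target(r)), "")
  list(index = idx, target = ifelse(is.na(idx), NA_character_, targets[idx]))
}

#' Enumerate the rule engine over the full applicable input space
#'
#' Expands the finite product of the value domains of every variable a
#' sequence's rule block references and evaluates the decision list on each
#' combination. Used by [check_rule_table()] and by property tests
#' (size monotonicity, DCE relevance).
#'
#' @inheritParams score_t2w
#' @param sequence One of `"t2w"`, `"dwi"`, `"dce"`, `"overall"`.
#' @return The enumeration grid with columns `.rule` (id of the first
#'   matching rule, `NA` on a gap) and `.target` (the assigned score/result).
#' @export
enumerate_scores <- function(sequence, zone = NULL, rules = default_rules(),
                             schema = default_schema()) {
  block <- rule_block(rules, sequence, zone)
  grid <- block_grid(block, schema)
  mm <- match_matrix(block, grid)
  fm <- first_match_target(block, mm)
  ids <- vapply(block, function(r) r$id %||% NA_character_, "")
  grid$.rule <- ifelse(is.na(fm$index), NA_character_, ids[fm$index])
  grid$.target <- fm$target
  grid
}

#' Check a rule table for completeness and consistency
#'
#' Exhaustively enumerates, for every sequence/zone block, the product of the
#' referenced variables' value domains and verifies that the decision list
#' assigns a score to every combination. Reported per block:
#' \describe{
#'   \item{gaps}{inputs no rule (including a catch-all) matches — under
#'     first-match semantics these are inputs the engine would refuse;}
#'   \item{conflicts}{in blocks without a catch-all (the overall-assessment
#'     tables, which are meant to be mutually exclusive), inputs matched by
#'     two rules assigning different targets;}
#'   \item{resolved_overlaps}{inputs matched by more than one rule where
#'     list order resolves the tie (informational; by construction e.g. the
#'     score-5 rule refines the score-4 predicate).}
#' }
#'
#' @inheritParams score_t2w
#' @param schema Schema supplying the value domains for enumeration.
#' @return A list of class `rule_check` with one entry per block
#'   (`n_inputs`, `n_gaps`, `n_conflicts`, `n_resolved_overlaps`, and the gap
#'   rows themselves) plus `$ok`, `TRUE` when no block has gaps or conflicts.
#' @export
check_rule_table <- function(rules = default_rules(), schema = default_schema()) {
  out <- list()
  for (seq_name in names(rules$sequences)) {
    for (zone in names(rules$sequences[[seq_name]])) {
      block <- rules$sequences[[seq_name]][[zone]]
      label <- paste(seq_name, zone, sep = "/")
      if (length(block) == 0L) {
        out[[label]] <- list(n_inputs = NA_integer_, n_gaps = NA_integer_,
                             n_conflicts = 0L, n_resolved_overlaps = 0L,
                             gaps = NULL, empty = TRUE)
        next
      }
      grid <- block_grid(block, schema)
      mm <- match_matrix(block, grid)
      has_otherwise <- any(vapply(block, function(r) isTRUE(r$otherwise), TRUE))
      n_match <- rowSums(mm)
      gaps <- which(n_match == 0L)
      conflicts <- 0L
      if (!has_otherwise) {
        targets <- vapply(block, function(r) as.character(rule_target(r)), "")
        multi <- which(n_match > 1L)
        conflicts <- sum(vapply(multi, function(i) {
          length(unique(targets[mm[i, ]])) > 1L
        }, TRUE))
      }
      out[[label]] <- list(
        n_inputs = nrow(grid),
        n_gaps = length(gaps),
        n_conflicts = as.integer(conflicts),
        n_resolved_overlaps = sum(n_match > 1L) - conflicts,
        gaps = if (length(gaps)) grid[gaps, , drop = FALSE] else NULL,
        empty = FALSE
      )
    }
  }
  ok <- all(vapply(out, function(b) {
    !isTRUE(b$empty) && b$n_gaps == 0L && b$n_conflicts == 0L
  }, TRUE))
  structure(list(blocks = out, ok = ok), class = "rule_check")
}

#' @export
print.rule_check <- function(x, ...) {
  cat(sprintf("<rule_check: %s>\n", if (x$ok) "complete and consistent" else "PROBLEMS FOUND"))
  for (label in names(x$blocks)) {
    b <- x$blocks[[label]]
    if (isTRUE(b$empty)) {
      cat(sprintf("  %-12s EMPTY BLOCK (every input is a gap)\n", label))
    } else {
      cat(sprintf("  %-12s %6d inputs, %d gaps, %d conflicts, %d overlaps resolved by order\n",
                  label, b$n_inputs, b$n_gaps, b$n_conflicts, b$n_resolved_overlaps))
    }
  }
  invisible(x)
}
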
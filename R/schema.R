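# CDE schema: the structured-report vocabulary for PI-RADS v2.1 lesion
# assessment. The shipped definition has 34 variables spanning one global
# block (size bin, zone) and four modality blocks (T2W, DWI, ADC, DCE), each
# with a fixed categorical value domain and an applicability predicate tying
# modality descriptors to the modality's present-and-adequate flag.

#' Load a CDE schema definition
#'
#' Reads a versioned JSON schema document describing the common data elements
#' (CDEs) of a structured prostate-MRI report: one object per variable with
#' name, display label, RadLex term, value domain, modality group, and an
#' applicability predicate over other variables.
#'
#' The lesion-shape variables carry two selectable value-domain dialects: the
#' four-value report-form list (`"table1"`) and the eight-value PI-RADS
#' lexicon list (`"lexicon"`). [categorize_shape()] is defined on the union of
#' both.
#'
#' @param path Path to a schema JSON file. `NULL` (default) loads the shipped
#'   PI-RADS v2.1 CDE definition.
#' @param shape_dialect Which shape value-domain dialect to activate,
#'   `"table1"` (default) or `"lexicon"`.
#' @return An object of class `cde_schema`: a list with `version`,
#'   `shape_dialect`, and `variables` (named list of variable definitions, in
#'   schema order).
#' @examples
#' sch <- load_schema()
#' length(sch$variables)           # 34
#' schema_domain(sch, "t2w_margin")
#' @export
load_schema <- function(path = NULL, shape_dialect = c("table1", "lexicon")) {
  shape_dialect <- match.arg(shape_dialect)
  path <- path %||% pkg_file("extdata", "cde_schema.json")
  def <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop_piradscde(
      sprintf("cannot parse schema definition '%s': %s", path, conditionMessage(e)),
      "schema_parse_error"
    )
  )
  if (is.null(def$variables) || length(def$variables) == 0L) {
    stop_piradscde("schema definition contains no variables", "schema_parse_error")
  }
  dialects <- def$shape_dialects
  vars <- list()
  for (v in def$variables) {
    nm <- v$name
    if (is.null(nm) || is.null(v$label)) {
      stop_piradscde(
        sprintf("schema variable '%s' lacks a name or label", nm %||% "<unnamed>"),
        "schema_parse_error"
      )
    }
    if (!is.null(names(vars)) && nm %in% names(vars)) {
      stop_piradscde(sprintf("duplicate variable name '%s'", nm),
                     "duplicate_variable_error")
    }
    domain <- if (identical(v$domain_role, "shape")) {
      unlist(dialects[[shape_dialect]])
    } else {
      unlist(v$domain)
    }
    if (length(domain) == 0L || anyDuplicated(domain)) {
      stop_piradscde(
        sprintf("variable '%s' has an empty or duplicated value domain", nm),
        "schema_parse_error"
      )
    }
    vars[[nm]] <- list(
      name = nm,
      label = v$label,
      radlex = v$radlex %||% NA_character_,
      domain = domain,
      group = v$group %||% "GLOBAL",
      ordinal = isTRUE(v$ordinal),
      aliases = if (length(v$aliases)) unlist(v$aliases) else NULL,
      applicability = v$applicability %||% list()
    )
  }
  # applicability predicates may only reference defined variables
  for (v in vars) {
    for (cond in v$applicability) {
      if (!cond$var %in% names(vars)) {
        stop_piradscde(
          sprintf("applicability of '%s' references undefined variable '%s'",
                  v$name, cond$var),
          "schema_parse_error"
        )
      }
    }
  }
  structure(
    list(version = def$version %||% "unversioned",
         shape_dialect = shape_dialect,
         shape_union = unique(unlist(dialects)),
         variables = vars),
    class = "cde_schema"
  )
}

#' @export
print.cde_schema <- function(x, ...) {
  cat(sprintf("<cde_schema v%s: %d variables, shape dialect '%s'>\n",
              x$version, length(x$variables), x$shape_dialect))
  groups <- vapply(x$variables, `[[`, "", "group")
  for (g in unique(groups)) {
    cat(sprintf("  %-6s %s\n", g, paste(names(groups)[groups == g], collapse = ", ")))
  }
  invisible(x)
}

#' @rdname load_schema
#' @param schema A `cde_schema`.
#' @param variable Variable name.
#' @export
schema_domain <- function(schema, variable) {
  v <- schema$variables[[variable]]
  if (is.null(v)) {
    stop_piradscde(sprintf("unknown variable '%s'", variable), "unknown_variable_error")
  }
  v$domain
}

#' Canonicalize a CDE value
#'
#' Maps accepted alias spellings (e.g. the report form's
#' \dQuote{Hypointensitivity} for the ADC signal-intensity type) onto the
#' canonical domain value. Unknown values pass through unchanged; validation
#' flags them.
#' @inheritParams schema_domain
#' @param value Character vector of raw values.
#' @export
normalize_value <- function(schema, variable, value) {
  v <- schema$variables[[variable]]
  if (is.null(v) || is.null(v$aliases)) return(value)
  hit <- value %in% names(v$aliases)
  value[hit] <- unname(v$aliases[value[hit]])
  value
}

# Evaluate a variable's applicability predicate against a report's populated
# values. Three-valued: TRUE (all conditions met), FALSE (some condition
# contradicted by a populated gate), NA (a gating variable is unpopulated, so
# applicability is unknown). Unknown applicability is never a violation for a
# populated value, and strict mode does not require such variables — the
# unanswered gate itself is what gets flagged.
variable_applicable <- function(schema, variable, values) {
  conds <- schema$variables[[variable]]$applicability
  if (length(conds) == 0L) return(TRUE)
  unknown <- FALSE
  for (cond in conds) {
    val <- values[[cond$var]]
    if (is.null(val) || is.na(val)) unknown <- TRUE
    else if (!identical(unname(val), cond$value)) return(FALSE)
  }
  if (unknown) NA else TRUE
}

#' Validate a lesion report against the CDE schema
#'
#' Checks one rater's CDE assessment of one lesion. Violations are returned as
#' data, not raised: each row names the variable, the offending value, and the
#' rule violated.
#'
#' Rules checked: `unknown_variable` (value for a name not in the schema);
#' `not_in_domain` (populated value outside the variable's value domain, after
#' alias normalization); `not_applicable` (value populated although the
#' variable's applicability predicate is unmet, e.g. a DWI descriptor when
#' `dwi_present_and_adequate = NO`); and, in strict mode only, `missing`
#' (an applicable variable left unpopulated). The [NOT_APPLICABLE] sentinel is
#' admissible exactly where the applicability predicate is unmet.
#'
#' @param report Named character vector or list: variable name -> value.
#' @param schema A `cde_schema` from [load_schema()].
#' @param mode `"strict"` requires every applicable variable to be populated;
#'   `"partial"` checks only populated values.
#' @return A data frame with columns `variable`, `value`, `rule`, `message`;
#'   zero rows when the report is valid.
#' @examples
#' sch <- load_schema()
#' validate_report(c(t2w_shape = "Oval"), sch, mode = "partial")
#' @export
validate_report <- function(report, schema, mode = c("strict", "partial")) {
  mode <- match.arg(mode)
  values <- as.list(report)
  viol <- list()
  add <- function(variable, value, rule, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      variable = variable, value = value %||% NA_character_,
      rule = rule, message = message, stringsAsFactors = FALSE
    )
  }
  unknown <- setdiff(names(values), names(schema$variables))
  for (nm in unknown) {
    add(nm, as.character(values[[nm]]), "unknown_variable",
        sprintf("'%s' is not a schema variable", nm))
  }
  values <- values[setdiff(names(values), unknown)]
  for (nm in names(values)) {
    val <- normalize_value(schema, nm, as.character(values[[nm]]))
    applicable <- variable_applicable(schema, nm, values)
    if (identical(val, NOT_APPLICABLE)) {
      if (isTRUE(applicable)) {
        add(nm, val, "not_applicable",
            sprintf("'%s' is applicable but flagged %s", nm, NOT_APPLICABLE))
      }
      next
    }
    if (!val %in% schema$variables[[nm]]$domain) {
      add(nm, val, "not_in_domain",
          sprintf("'%s' = '%s' not in domain {%s}", nm, val,
                  paste(schema$variables[[nm]]$domain, collapse = ", ")))
    }
    if (isFALSE(applicable)) {
      add(nm, val, "not_applicable",
          sprintf("'%s' populated although its applicability condition is unmet", nm))
    }
  }
  if (mode == "strict") {
    for (nm in setdiff(names(schema$variables), names(values))) {
      if (isTRUE(variable_applicable(schema, nm, values))) {
        add(nm, NA_character_, "missing",
            sprintf("applicable variable '%s' is unpopulated", nm))
      }
    }
  }
  if (length(viol) == 0L) {
    return(data.frame(variable = character(), value = character(),
                      rule = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, viol)
}

# Shape grouping over the union of the two shape dialects. Linear-like shapes
# (linear, wedge) go to Linear; rounded and lentiform/teardrop shapes to
# Round; lobulated and frankly irregular shapes to Irregular.
.shape_map <- c(
  "Linear" = "Linear", "Wedge" = "Linear", "Wedge-shaped" = "Linear",
  "Round" = "Round", "Oval" = "Round", "Lenticular" = "Round",
  "Water-Drop" = "Round", "Tear-shaped" = "Round",
  "Lobulated" = "Irregular", "Irregular" = "Irregular"
)

# Margin grouping: indistinct/obscured/spiculated/erased-charcoal-sign are
# non-circumscribed; encapsulated, partly-encapsulated and well-defined
# margins are circumscribed.
.margin_map <- c(
  "Indistinct" = "Non_Circumscribed", "Obscured" = "Non_Circumscribed",
  "Spiculated" = "Non_Circumscribed", "Erased charcoal sign" = "Non_Circumscribed",
  "Encapsulated" = "Circumscribed", "Partly_Encapsulated" = "Circumscribed",
  "Well_Defined" = "Circumscribed"
)

#' Simplify raw shape and margin descriptors into category types
#'
#' `categorize_shape()` maps any raw lesion-shape value (from either shape
#' dialect) onto one of three shape types: `Linear`, `Round`, `Irregular`.
#' `categorize_margin()` maps any raw margin value onto `Circumscribed` or
#' `Non_Circumscribed`. Both are total over their input vocabulary and
#' surjective onto their codomain; an unknown value raises an error.
#'
#' @param shape,margin Character vector of raw descriptor values.
#' @return Character vector of categories, same length as the input.
#' @examples
#' categorize_shape(c("Wedge", "Oval", "Lobulated"))
#' categorize_margin(c("Indistinct", "Well_Defined"))
#' @export
categorize_shape <- function(shape) {
  bad <- setdiff(unique(shape), names(.shape_map))
  if (length(bad)) {
    stop_piradscde(sprintf("unknown shape value(s): %s", paste(bad, collapse = ", ")),
                   "unknown_value_error")
  }
  unname(.shape_map[shape])
}

#' @rdname categorize_shape
#' @export
categorize_margin <- function(margin) {
  bad <- setdiff(unique(margin), names(.margin_map))
  if (length(bad)) {
    stop_piradscde(sprintf("unknown margin value(s): %s", paste(bad, collapse = ", ")),
                   "unknown_value_error")
  }
  unname(.margin_map[margin])
}
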
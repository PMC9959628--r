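# Synthetic multi-reader multi-case study generator. Emulates a reading
# study in which raters in two experience groups independently fill the CDE
# report form for every lesion in two sessions. Each lesion carries a latent
# true CDE profile drawn from zone- and significance-conditional prevalences;
# a rater's session-1 value of a variable equals the truth with probability
# 1 - epsilon and otherwise confuses symmetrically over the remaining domain
# values; the session-2 value repeats session 1 with probability rho and is
# otherwise regenerated from the session-1 mechanism. Manual PI-RADS
# categories are derived from each rater's (noisy) CDE values through the
# rule engine, coupling the modules the way the real workflow does.

# Per-feature-class confusion rates (probability a rater departs from the
# latent truth). Chosen to mirror the qualitative ordering seen in reader
# studies: near-perfect for abnormality detection and signal-intensity type,
# poor for raw shape and margin descriptors, intermediate elsewhere.
.default_epsilon <- c(
  present_and_adequate = 0,
  abnormality = 0.04,
  signal_intensity_type = 0.03,
  signal_intensity = 0.33,
  uniformity = 0.22,
  focality = 0.20,
  invasive = 0.20,
  shape = 0.45,
  shape_category = 0.30,
  margin = 0.55,
  margin_category = 0.18,
  enhancement = 0.13,
  corresponds_to = 0.15,
  bph_features = 0.10,
  lesion_location = 0.12,
  lesion_dim_max = 0.15
)
# DCE abnormality is harder to call than anatomical-sequence abnormality.
.default_epsilon_overrides <- c(dce_abnormality = 0.13)

feature_class <- function(variable) {
  sub("^(t2w|adc|dwi|dce)_", "", variable)
}

#' Configuration for the synthetic reader study
#'
#' Defaults reproduce the reference study composition: 32 lesions (14 PZ =
#' 7 clinically significant + 7 not, 11 TZ = 5 + 6, 7 AFMS = 4 + 3), six
#' raters in two experience groups of three, and two reading sessions.
#'
#' @param composition Data frame with columns `zone`, `clinically_significant`,
#'   `n` giving per-stratum lesion counts.
#' @param raters Data frame with columns `rater_id`, `group`
#'   (`"experienced"` / `"inexperienced"`).
#' @param sessions Number of reading sessions (default 2).
#' @param epsilon Named numeric vector of per-feature confusion rates in
#'   `[0, 1]`; names are feature classes (e.g. `"shape"`) or full variable
#'   names (e.g. `"dce_abnormality"`), the latter taking precedence. Values
#'   merge over the package defaults.
#' @param epsilon_scale Named numeric vector of per-group multipliers applied
#'   to `epsilon` (rates capped at 1). The default mildly inflates the
#'   experienced group's confusion on every feature, reflecting the observed
#'   tendency of experienced readers to agree less on subjective features.
#' @param rho Intra-session consistency in `[0, 1]`: probability that a
#'   session-2 rating repeats the rater's session-1 value.
#' @param confusion Error model: `"symmetric"` (default) confuses uniformly
#'   over the other domain values; `"ordinal_adjacent"` confuses ordinal
#'   variables (signal-intensity scale, size bin) only with a neighboring
#'   level.
#' @param underscore_rate Probability that an inexperienced rater downgrades
#'   the overall category of a clinically significant lesion by one point
#'   (emulating score underestimation by less experienced readers).
#' @param shape_dialect Shape value-domain dialect for the generated reports.
#' @param seed Integer RNG seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(composition = NULL, raters = NULL, sessions = 2,
                             epsilon = NULL, epsilon_scale = NULL, rho = 0.85,
                             underscore_rate = 0.5,
                             confusion = c("symmetric", "ordinal_adjacent"),
                             shape_dialect = c("table1", "lexicon"),
                             seed = 1L) {
  shape_dialect <- match.arg(shape_dialect)
  confusion <- match.arg(confusion)
  composition <- composition %||% data.frame(
    zone = rep(c("PZ", "TZ", "AFMS"), each = 2),
    clinically_significant = rep(c(TRUE, FALSE), 3),
    n = c(7, 7, 5, 6, 4, 3)
  )
  raters <- raters %||% data.frame(
    rater_id = c("E1", "E2", "E3", "I1", "I2", "I3"),
    group = rep(c("experienced", "inexperienced"), each = 3),
    stringsAsFactors = FALSE
  )
  eps <- .default_epsilon
  over <- .default_epsilon_overrides
  if (!is.null(epsilon)) {
    cls <- intersect(names(epsilon), names(eps))
    eps[cls] <- epsilon[cls]
    extra <- epsilon[setdiff(names(epsilon), names(eps))]
    over[names(extra)] <- extra
  }
  epsilon_scale <- epsilon_scale %||% c(experienced = 1.2, inexperienced = 1.0)
  bad <- character()
  if (any(composition$n < 0)) bad <- c(bad, "composition$n")
  if (any(eps < 0 | eps > 1) || any(over < 0 | over > 1)) bad <- c(bad, "epsilon")
  if (rho < 0 || rho > 1) bad <- c(bad, "rho")
  if (underscore_rate < 0 || underscore_rate > 1) bad <- c(bad, "underscore_rate")
  if (!all(raters$group %in% names(epsilon_scale))) bad <- c(bad, "epsilon_scale")
  if (length(bad)) {
    stop_piradscde(sprintf("invalid generator configuration field(s): %s",
                           paste(bad, collapse = ", ")), "config_error")
  }
  structure(list(composition = composition, raters = raters,
                 sessions = as.integer(sessions), epsilon = eps,
                 epsilon_overrides = over, epsilon_scale = epsilon_scale,
                 rho = rho, underscore_rate = underscore_rate,
                 confusion = confusion, shape_dialect = shape_dialect,
                 seed = as.integer(seed)),
            class = "generator_config")
}

epsilon_for <- function(config, variable, group) {
  e <- if (variable %in% names(config$epsilon_overrides)) {
    config$epsilon_overrides[[variable]]
  } else {
    cls <- feature_class(variable)
    if (cls %in% names(config$epsilon)) config$epsilon[[cls]] else 0.2
  }
  min(1, e * config$epsilon_scale[[group]])
}

# Zone/significance-conditional prevalences for the latent true profiles.
# Clinically significant lesions are built to satisfy the high-score rule
# predicates most of the time (marked focal ADC/DWI findings, moderate-to-
# marked homogeneous hypointense T2W findings); benign lesions sit mostly in
# the 1-3 range with occasional mimics.
sample_cat <- function(values, prob) sample(values, 1L, prob = prob)

latent_profile <- function(zone, cs, schema) {
  v <- character()
  shapes <- schema$variables$t2w_shape$domain
  shape_prob <- if (cs) {
    ifelse(shapes %in% c("Lenticular", "Water-Drop", "Oval", "Round", "Lobulated", "Irregular"), 3, 1)
  } else {
    ifelse(shapes %in% c("Linear", "Wedge", "Wedge-shaped"), 3, 1)
  }
  margins <- schema$variables$t2w_margin$domain
  margin_prob <- if (cs && zone == "PZ") {
    ifelse(margins %in% c("Well_Defined", "Encapsulated", "Partly_Encapsulated"), 3, 1)
  } else if (cs) {
    ifelse(margins %in% c("Indistinct", "Obscured", "Spiculated", "Erased charcoal sign"), 3, 1)
  } else {
    ifelse(margins %in% c("Well_Defined", "Partly_Encapsulated", "Encapsulated"), 2, 1)
  }
  v["lesion_dim_max"] <- if (cs) sample_cat(c("<5", ">=5", ">=15"), c(.05, .45, .5))
                         else sample_cat(c("<5", ">=5", ">=15"), c(.3, .6, .1))
  v["lesion_location"] <- if (zone == "PZ") "PZ" else "TZ"
  for (mod in c("t2w", "adc", "dwi", "dce")) v[paste0(mod, "_present_and_adequate")] <- "YES"

  t2w_abn <- if (cs) TRUE else stats::runif(1) < 0.75
  v["t2w_abnormality"] <- if (t2w_abn) "YES" else "NO"
  v["t2w_invasive"] <- if (cs) sample_cat(c("YES", "NO"), c(.3, .7)) else sample_cat(c("YES", "NO"), c(.02, .98))
  v["t2w_signal_intensity_type"] <- if (cs) "Hypointense" else sample_cat(c("Hypointense", "Isointense", "Hyperintense"), c(.4, .5, .1))
  v["t2w_signal_intensity"] <- if (cs) sample_cat(c("Mild", "Moderate", "Marked"), c(.1, .5, .4))
                               else sample_cat(c("Mild", "Moderate", "Marked"), c(.6, .3, .1))
  v["t2w_uniformity"] <- if (cs) sample_cat(c("Homogeneous", "Heterogeneous"), c(.85, .15))
                         else sample_cat(c("Homogeneous", "Heterogeneous"), c(.5, .5))
  v["t2w_focality"] <- if (cs) sample_cat(c("YES", "NO"), c(.95, .05)) else sample_cat(c("YES", "NO"), c(.4, .6))
  v["t2w_shape"] <- sample(shapes, 1L, prob = shape_prob)
  v["t2w_shape_category"] <- categorize_shape(v[["t2w_shape"]])
  v["t2w_margin"] <- sample(margins, 1L, prob = margin_prob)
  v["t2w_margin_category"] <- categorize_margin(v[["t2w_margin"]])

  adc_abn <- if (cs) TRUE else stats::runif(1) < 0.6
  v["adc_abnormality"] <- if (adc_abn) "YES" else "NO"
  v["adc_invasive"] <- if (cs) sample_cat(c("YES", "NO"), c(.25, .75)) else "NO"
  v["adc_signal_intensity_type"] <- if (cs) "Hypointense" else sample_cat(c("Hypointense", "Isointense", "Hyperintense"), c(.5, .45, .05))
  v["adc_signal_intensity"] <- if (cs) sample_cat(c("Mild", "Moderate", "Marked"), c(.02, .08, .9))
                               else sample_cat(c("Mild", "Moderate", "Marked"), c(.6, .35, .05))
  v["adc_focality"] <- if (cs) sample_cat(c("YES", "NO"), c(.95, .05)) else sample_cat(c("YES", "NO"), c(.4, .6))
  v["adc_shape"] <- sample(shapes, 1L, prob = shape_prob)
  v["adc_shape_category"] <- categorize_shape(v[["adc_shape"]])

  dwi_abn <- if (cs) TRUE else stats::runif(1) < 0.6
  v["dwi_abnormality"] <- if (dwi_abn) "YES" else "NO"
  v["dwi_invasive"] <- if (cs) sample_cat(c("YES", "NO"), c(.25, .75)) else "NO"
  v["dwi_signal_intensity_type"] <- if (cs) "Hyperintense" else sample_cat(c("Hypointense", "Isointense", "Hyperintense"), c(.1, .5, .4))
  v["dwi_signal_intensity"] <- if (cs) sample_cat(c("Mild", "Moderate", "Marked"), c(.02, .08, .9))
                               else sample_cat(c("Mild", "Moderate", "Marked"), c(.6, .35, .05))
  v["dwi_focality"] <- if (cs) sample_cat(c("YES", "NO"), c(.95, .05)) else sample_cat(c("YES", "NO"), c(.4, .6))
  v["dwi_shape"] <- sample(shapes, 1L, prob = shape_prob)
  v["dwi_shape_category"] <- categorize_shape(v[["dwi_shape"]])

  v["dce_abnormality"] <- if (cs) sample_cat(c("YES", "NO"), c(.9, .1)) else sample_cat(c("YES", "NO"), c(.35, .65))
  v["dce_enhancement"] <- if (cs) sample_cat(c("Positive_DCE", "Negative_DCE"), c(.85, .15))
                          else sample_cat(c("Positive_DCE", "Negative_DCE"), c(.3, .7))
  v["dce_corresponds_to"] <- if (cs) sample_cat(c("T2", "DWI", "Not_Available"), c(.3, .6, .1))
                             else sample_cat(c("T2", "DWI", "Not_Available"), c(.25, .25, .5))
  v["dce_bph_features"] <- if (cs) sample_cat(c("YES", "NO"), c(.2, .8)) else sample_cat(c("YES", "NO"), c(.45, .55))
  v
}

confuse <- function(true_value, domain, epsilon, ordinal_adjacent = FALSE) {
  if (length(domain) < 2L || stats::runif(1) >= epsilon) return(true_value)
  alternatives <- if (ordinal_adjacent) {
    i <- match(true_value, domain)
    idx <- c(i - 1L, i + 1L)
    domain[idx[idx >= 1L & idx <= length(domain)]]
  } else {
    setdiff(domain, true_value)
  }
  sample(alternatives, 1L)
}

#' Generate a synthetic reader study
#'
#' Draws latent true CDE profiles for every lesion in the configured
#' composition, then simulates every rater's session-1 and session-2 reports
#' under the symmetric-confusion / repeat-probability noise model, scores
#' each report with the rule engine, and applies the inexperienced-group
#' score-underestimation mechanism to clinically significant lesions. All
#' generated reports validate strictly against the schema.
#'
#' @param config A [generator_config()].
#' @return A list of class `cde_study`: `manifest` ([lesion_manifest()]),
#'   `profiles` (lesion x variable data frame of latent truths), `reports`
#'   (long report data frame), `scores` (per lesion/rater/session engine
#'   scores, see [score_reports()]), `design` (rater data frame), and
#'   `config`.
#' @examples
#' study <- generate_study(generator_config(seed = 7))
#' nrow(study$manifest)                       # 32
#' with(study$scores, table(overall))
#' @export
generate_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  schema <- load_schema(shape_dialect = config$shape_dialect)
  rules <- default_rules()
  set.seed(config$seed)

  comp <- config$composition[config$composition$n > 0, , drop = FALSE]
  zones <- rep(comp$zone, comp$n)
  cs <- rep(comp$clinically_significant, comp$n)
  n_lesions <- length(zones)
  ids <- sprintf("L%03d", seq_len(n_lesions))
  manifest <- lesion_manifest(ids, zones, cs)

  profiles <- lapply(seq_len(n_lesions), function(i) latent_profile(zones[i], cs[i], schema))
  prof_df <- cbind(data.frame(lesion_id = ids, stringsAsFactors = FALSE),
                   do.call(rbind, lapply(profiles, function(p) as.data.frame(as.list(p)))))

  vars <- names(schema$variables)
  domains <- lapply(vars, function(v) schema$variables[[v]]$domain)
  names(domains) <- vars
  ordinal <- lapply(vars, function(v) {
    config$confusion == "ordinal_adjacent" && isTRUE(schema$variables[[v]]$ordinal)
  })
  names(ordinal) <- vars

  rows <- vector("list", n_lesions * nrow(config$raters) * config$sessions)
  ri <- 0L
  for (i in seq_len(n_lesions)) {
    truth <- profiles[[i]]
    for (r in seq_len(nrow(config$raters))) {
      rid <- config$raters$rater_id[r]
      grp <- config$raters$group[r]
      s1 <- vapply(vars, function(vn) {
        confuse(truth[[vn]], domains[[vn]], epsilon_for(config, vn, grp),
                ordinal[[vn]])
      }, "")
      prev <- s1
      for (s in seq_len(config$sessions)) {
        vals <- if (s == 1L) s1 else vapply(vars, function(vn) {
          if (stats::runif(1) < config$rho) prev[[vn]]
          else confuse(truth[[vn]], domains[[vn]], epsilon_for(config, vn, grp),
                       ordinal[[vn]])
        }, "")
        if (s > 1L) prev <- vals
        ri <- ri + 1L
        rows[[ri]] <- data.frame(lesion_id = ids[i], rater_id = rid,
                                 session = s, variable = vars,
                                 value = unname(vals), stringsAsFactors = FALSE)
      }
    }
  }
  reports <- as_reports(do.call(rbind, rows))

  scores <- score_reports(reports, manifest, rules, schema)
  grp_of <- stats::setNames(config$raters$group, config$raters$rater_id)
  cs_of <- stats::setNames(manifest$clinically_significant, manifest$lesion_id)
  downgrade <- grp_of[scores$rater_id] == "inexperienced" &
    cs_of[scores$lesion_id] &
    stats::runif(nrow(scores)) < config$underscore_rate
  scores$overall <- ifelse(downgrade, pmax(1L, scores$overall - 1L), scores$overall)

  structure(list(manifest = manifest, profiles = prof_df, reports = reports,
                 scores = scores, design = config$raters, config = config),
            class = "cde_study")
}

#' @export
print.cde_study <- function(x, ...) {
  cat(sprintf("<cde_study: %d lesions (%s), %d raters, %d sessions, seed %d>\n",
              nrow(x$manifest),
              paste(sprintf("%d %s", table(x$manifest$zone)[unique(x$manifest$zone)],
                            unique(x$manifest$zone)), collapse = ", "),
              nrow(x$design), x$config$sessions, x$config$seed))
  invisible(x)
}

#' Expected two-rater percent agreement under symmetric confusion
#'
#' Two independent raters each report the truth with probability
#' `1 - epsilon` and otherwise err uniformly over the other `q - 1`
#' categories; they agree when both are right or both err to the same
#' alternative: `(1 - epsilon)^2 + epsilon^2 / (q - 1)`.
#'
#' @param epsilon Confusion rate in `[0, 1]`.
#' @param q Number of categories, `q >= 2`.
#' @export
expected_pairwise_pa <- function(epsilon, q) {
  if (any(q < 2)) stop_piradscde("q must be at least 2", "domain_error")
  if (any(epsilon < 0 | epsilon > 1)) {
    stop_piradscde("epsilon must lie in [0, 1]", "config_error")
  }
  (1 - epsilon)^2 + epsilon^2 / (q - 1)
}
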
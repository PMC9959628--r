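# Reader-study analysis: per-CDE agreement tables stratified by session,
# experience group and zone; PI-RADS category agreement (inter- and
# intra-rater); group score comparison on clinically significant lesions;
# diagnostic accuracy at an ordinal category threshold.

subset_raters <- function(design, group) {
  if (identical(group, "all")) return(design$rater_id)
  out <- design$rater_id[design$group == group]
  if (length(out) == 0L) {
    stop_piradscde(sprintf("no raters in group '%s'", group), "insufficient_data_error")
  }
  out
}

subset_lesions <- function(manifest, zone) {
  if (identical(zone, "all")) return(manifest$lesion_id)
  manifest$lesion_id[manifest$zone == zone]
}

# Build a subjects x raters matrix for one variable. session = 1, 2, or
# "pool" (rows = lesion x session replicates). Values are alias-normalized;
# absent records become NA; the NOT_APPLICABLE sentinel is kept as a
# category of its own.
variable_matrix <- function(reports, variable, lesions, raters, session,
                            schema = default_schema()) {
  sub <- reports[reports$variable == variable & reports$lesion_id %in% lesions &
                 reports$rater_id %in% raters, , drop = FALSE]
  sub$value <- normalize_value(schema, variable, sub$value)
  sessions <- if (identical(session, "pool")) sort(unique(sub$session)) else as.integer(session)
  rows <- as.vector(outer(lesions, sessions, paste, sep = "@s"))
  m <- matrix(NA_character_, nrow = length(rows), ncol = length(raters),
              dimnames = list(rows, raters))
  sub <- sub[sub$session %in% sessions, , drop = FALSE]
  if (nrow(sub)) {
    idx <- cbind(match(paste(sub$lesion_id, sub$session, sep = "@s"), rows),
                 match(sub$rater_id, raters))
    m[idx] <- sub$value
  }
  m
}

variable_categories <- function(schema, variable, m) {
  cats <- schema_domain(schema, variable)
  if (NOT_APPLICABLE %in% m) cats <- c(cats, NOT_APPLICABLE)
  cats
}

#' Per-CDE inter-rater agreement table
#'
#' One row per analyzed CDE with the mean pairwise percent agreement and AC1
#' across all rater pairs in the stratum, a t-based confidence interval from
#' the across-pair dispersion, and the interpretation band — the layout of a
#' reader-study interobserver table, computable for any session, experience
#' group and zone stratum.
#'
#' The chance model of each row's AC1 uses the variable's full value domain
#' as the category set, so rows are comparable across strata regardless of
#' which options the raters happened to use.
#'
#' @param reports Long report data frame.
#' @param design Data frame with columns `rater_id`, `group`.
#' @param manifest A [lesion_manifest()] (needed for zone strata).
#' @param session `1`, `2`, or `"overall"`.
#' @param group `"all"`, `"experienced"`, or `"inexperienced"`.
#' @param zone `"all"`, `"PZ"`, `"TZ"`, or `"AFMS"`.
#' @param pooling How `"overall"` combines the sessions: `"pool"` treats each
#'   lesion-session as an additional replicate pair; `"mean"` averages the
#'   two per-session statistics.
#' @param features CDE names to analyze; default, every schema variable
#'   present in `reports` except the present-and-adequate flags.
#' @param schema A `cde_schema`.
#' @param ci_level Confidence level.
#' @return Data frame with columns `feature`, `modality`, `pa` (percent),
#'   `ac1`, `ci_low`, `ci_high`, `p_value`, `band`, `n_subjects`, `n_pairs`.
#' @export
feature_agreement_table <- function(reports, design, manifest,
                                    session = "overall", group = "all",
                                    zone = "all", pooling = c("pool", "mean"),
                                    features = NULL, schema = default_schema(),
                                    ci_level = 0.95) {
  pooling <- match.arg(pooling)
  reports <- as_reports(reports)
  raters <- subset_raters(design, group)
  lesions <- subset_lesions(manifest, zone)
  if (length(lesions) < 2L) {
    stop_piradscde(sprintf("stratum '%s' has fewer than two lesions", zone),
                   "insufficient_data_error")
  }
  features <- features %||% setdiff(
    intersect(names(schema$variables), unique(reports$variable)),
    grep("_present_and_adequate$", names(schema$variables), value = TRUE)
  )
  one_feature <- function(feature) {
    run <- function(sess) {
      m <- variable_matrix(reports, feature, lesions, raters, sess, schema)
      pairwise_mean_agreement(m, categories = variable_categories(schema, feature, m),
                              ci_level = ci_level)
    }
    if (identical(session, "overall") && pooling == "mean") {
      s1 <- run(1)$summary
      s2 <- run(2)$summary
      s <- data.frame(mean_pa = mean(c(s1$mean_pa, s2$mean_pa)),
                      mean_ac1 = mean(c(s1$mean_ac1, s2$mean_ac1)),
                      ci_low = mean(c(s1$ci_low, s2$ci_low)),
                      ci_high = mean(c(s1$ci_high, s2$ci_high)),
                      p_value = max(s1$p_value, s2$p_value),
                      n_pairs = s1$n_pairs)
      n_subj <- length(lesions)
    } else {
      sess <- if (identical(session, "overall")) "pool" else session
      res <- run(sess)
      s <- res$summary
      n_subj <- if (identical(sess, "pool")) 2L * length(lesions) else length(lesions)
    }
    data.frame(feature = feature,
               modality = schema$variables[[feature]]$group,
               pa = 100 * s$mean_pa, ac1 = s$mean_ac1,
               ci_low = s$ci_low, ci_high = s$ci_high, p_value = s$p_value,
               band = interpret_band(s$mean_ac1),
               n_subjects = n_subj, n_pairs = s$n_pairs,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(features, one_feature))
  rownames(out) <- NULL
  out
}

scores_long <- function(scores) {
  do.call(rbind, lapply(c("t2w_score", "dwi_score", "dce_result", "overall"),
    function(v) {
      data.frame(lesion_id = scores$lesion_id, rater_id = scores$rater_id,
                 session = scores$session,
                 variable = switch(v, t2w_score = "T2W PI-RADS",
                                   dwi_score = "DWI PI-RADS",
                                   dce_result = "DCE PI-RADS",
                                   overall = "OVERALL PI-RADS"),
                 value = as.character(scores[[v]]), stringsAsFactors = FALSE)
    }))
}

.category_domains <- list(
  "T2W PI-RADS" = as.character(1:5), "DWI PI-RADS" = as.character(1:5),
  "DCE PI-RADS" = c("Positive", "Negative", "X"),
  "OVERALL PI-RADS" = as.character(1:5)
)

#' Inter-rater agreement of the PI-RADS category assessments
#'
#' Mean pairwise PA and AC1 for the four category variables (T2W, DWI, DCE,
#' overall), per session and for the sessions combined.
#'
#' @param scores Per-report score table from [score_reports()] (or manual
#'   categories in the same layout).
#' @inheritParams feature_agreement_table
#' @param sessions Sessions to tabulate; default session 1, session 2, and
#'   `"overall"`.
#' @return Data frame with one row per category variable x session.
#' @export
category_agreement_table <- function(scores, design, sessions = c("1", "2", "overall"),
                                     group = "all", pooling = c("pool", "mean"),
                                     ci_level = 0.95) {
  pooling <- match.arg(pooling)
  long <- scores_long(scores)
  raters <- subset_raters(design, group)
  lesions <- unique(long$lesion_id)
  rows <- list()
  for (feature in names(.category_domains)) {
    sub <- long[long$variable == feature, ]
    cats <- .category_domains[[feature]]
    for (sess in sessions) {
      run <- function(s) {
        sessions_used <- if (identical(s, "pool")) sort(unique(sub$session)) else as.integer(s)
        rn <- as.vector(outer(lesions, sessions_used, paste, sep = "@s"))
        m0 <- matrix(NA_character_, nrow = length(rn), ncol = length(raters),
                     dimnames = list(rn, raters))
        ss <- sub[sub$session %in% sessions_used & sub$rater_id %in% raters, ]
        m0[cbind(match(paste(ss$lesion_id, ss$session, sep = "@s"), rn),
                 match(ss$rater_id, raters))] <- ss$value
        pairwise_mean_agreement(m0, categories = cats, ci_level = ci_level)$summary
      }
      s <- if (identical(sess, "overall")) {
        if (pooling == "pool") run("pool") else {
          s1 <- run("1"); s2 <- run("2")
          data.frame(mean_pa = mean(c(s1$mean_pa, s2$mean_pa)),
                     mean_ac1 = mean(c(s1$mean_ac1, s2$mean_ac1)),
                     ci_low = mean(c(s1$ci_low, s2$ci_low)),
                     ci_high = mean(c(s1$ci_high, s2$ci_high)),
                     p_value = max(s1$p_value, s2$p_value), n_pairs = s1$n_pairs)
        }
      } else run(sess)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feature, session = as.character(sess), pa = 100 * s$mean_pa,
        ac1 = s$mean_ac1, ci_low = s$ci_low, ci_high = s$ci_high,
        p_value = s$p_value, band = interpret_band(s$mean_ac1),
        n_pairs = s$n_pairs, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intra-rater agreement of the PI-RADS category assessments
#'
#' Session-1 vs session-2 agreement per rater, summarized per experience
#' group and overall for each category variable.
#'
#' @inheritParams category_agreement_table
#' @return Data frame with one row per category variable x group (including
#'   `"overall"`), columns `pa` (percent), `ac1`, `ci_low`, `ci_high`,
#'   `band`, `n_raters`.
#' @export
intra_category_agreement <- function(scores, design, ci_level = 0.95) {
  long <- scores_long(scores)
  lesions <- sort(unique(long$lesion_id))
  rows <- list()
  for (feature in names(.category_domains)) {
    sub <- long[long$variable == feature, ]
    cats <- .category_domains[[feature]]
    per <- lapply(design$rater_id, function(r) {
      v1 <- sub$value[match(paste(lesions, r, 1), paste(sub$lesion_id, sub$rater_id, sub$session))]
      v2 <- sub$value[match(paste(lesions, r, 2), paste(sub$lesion_id, sub$rater_id, sub$session))]
      res <- gwet_ac1(cbind(s1 = v1, s2 = v2), categories = cats)
      data.frame(rater = r, group = design$group[design$rater_id == r],
                 pa = res$pa, ac1 = res$ac1, stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, per)
    for (g in c(unique(design$group), "overall")) {
      sel <- if (g == "overall") per else per[per$group == g, ]
      mu_pa <- mean(sel$pa); mu_ac1 <- mean(sel$ac1)
      k <- nrow(sel)
      se <- if (k > 1) stats::sd(sel$ac1) / sqrt(k) else 0
      tq <- if (k > 1) stats::qt(1 - (1 - ci_level) / 2, k - 1) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feature, group = g, pa = 100 * mu_pa, ac1 = mu_ac1,
        ci_low = mu_ac1 - tq * se, ci_high = min(1, mu_ac1 + tq * se),
        band = interpret_band(mu_ac1), n_raters = k, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare overall PI-RADS scores between experience groups
#'
#' On the clinically significant lesions, pairs the two groups' per-lesion
#' mean overall categories (raters and sessions averaged within group) and
#' applies the Wilcoxon signed-rank test; also reports each group's raw score
#' mean and standard deviation over those lesions. Identical group
#' distributions are reported as no difference rather than raised as an
#' error.
#'
#' @inheritParams category_agreement_table
#' @param manifest A [lesion_manifest()].
#' @return List with `group_stats` (mean/sd per group), `statistic`,
#'   `p_value`, `n_lesions`, `note`.
#' @export
group_score_comparison <- function(scores, manifest, design) {
  cs_ids <- manifest$lesion_id[manifest$clinically_significant]
  if (length(cs_ids) == 0L) {
    stop_piradscde("no clinically significant lesions in the manifest",
                   "insufficient_data_error")
  }
  sub <- scores[scores$lesion_id %in% cs_ids, ]
  grp_of <- stats::setNames(design$group, design$rater_id)
  sub$group <- grp_of[sub$rater_id]
  groups <- sort(unique(design$group))
  if (length(groups) != 2L) {
    stop_piradscde("exactly two experience groups are required", "domain_error")
  }
  group_stats <- do.call(rbind, lapply(groups, function(g) {
    v <- sub$overall[sub$group == g]
    data.frame(group = g, mean = mean(v), sd = stats::sd(v), n_ratings = length(v),
               stringsAsFactors = FALSE)
  }))
  by_lesion <- function(g) {
    vapply(cs_ids, function(l) mean(sub$overall[sub$group == g & sub$lesion_id == l]),
           numeric(1))
  }
  x <- by_lesion(groups[1]); y <- by_lesion(groups[2])
  res <- tryCatch(wilcoxon_signed_rank(x, y),
                  degenerate_test_error = function(e) NULL)
  list(group_stats = group_stats,
       statistic = if (is.null(res)) NA_real_ else res$statistic,
       p_value = if (is.null(res)) NA_real_ else res$p_value,
       n_lesions = length(cs_ids),
       note = if (is.null(res)) "no difference (all paired differences zero)" else NA_character_)
}

# AUC by the Mann-Whitney rank formulation with midrank tie correction.
auc_rank <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: labels are all one class")
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Diagnostic accuracy of the overall PI-RADS assessment
#'
#' Binarizes each overall category at `>= threshold` (default 3, the
#' referral-for-biopsy cut) against the manifest's clinical-significance
#' labels. Recall (sensitivity), precision, and specificity come from the
#' confusion counts; AUC uses the ordinal 1-5 score directly via the
#' Mann-Whitney rank formulation with tie correction. Computed per rater
#' (sessions pooled as repeated reads), then averaged within experience
#' group; a pooled-ratings alternative treats all reads as one sample.
#'
#' @inheritParams group_score_comparison
#' @param threshold Minimum overall category called positive.
#' @param aggregate `"rater"` (average per-rater metrics within group) or
#'   `"pooled"` (single confusion matrix over all reads).
#' @return List of class `diagnostic_accuracy`: `per_rater`, `per_group`,
#'   `overall` data frames with columns `auc`, `recall`, `precision`,
#'   `specificity`; plus `threshold`.
#' @export
diagnostic_accuracy <- function(scores, manifest, design = NULL, threshold = 3,
                                aggregate = c("rater", "pooled")) {
  aggregate <- match.arg(aggregate)
  lab_of <- stats::setNames(manifest$clinically_significant, manifest$lesion_id)
  bad <- setdiff(unique(scores$lesion_id), names(lab_of))
  if (length(bad)) {
    stop_piradscde(sprintf("scored lesion(s) lack a significance label: %s",
                           paste(bad, collapse = ", ")), "manifest_error")
  }
  metrics <- function(sub) {
    lab <- lab_of[sub$lesion_id]
    pred <- sub$overall >= threshold
    tp <- sum(pred & lab); fp <- sum(pred & !lab)
    fn <- sum(!pred & lab); tn <- sum(!pred & !lab)
    data.frame(
      auc = auc_rank(sub$overall, lab),
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      n_reads = nrow(sub))
  }
  if (aggregate == "pooled") {
    overall <- metrics(scores)
    return(structure(list(per_rater = NULL, per_group = NULL,
                          overall = overall, threshold = threshold),
                     class = "diagnostic_accuracy"))
  }
  raters <- unique(scores$rater_id)
  per_rater <- do.call(rbind, lapply(raters, function(r) {
    cbind(data.frame(rater_id = r, stringsAsFactors = FALSE),
          metrics(scores[scores$rater_id == r, ]))
  }))
  per_group <- NULL
  if (!is.null(design)) {
    grp_of <- stats::setNames(design$group, design$rater_id)
    per_rater$group <- grp_of[per_rater$rater_id]
    per_group <- do.call(rbind, lapply(split(per_rater, per_rater$group), function(g) {
      data.frame(group = g$group[1], auc = mean(g$auc), recall = mean(g$recall),
                 precision = mean(g$precision), specificity = mean(g$specificity),
                 n_raters = nrow(g), stringsAsFactors = FALSE)
    }))
    rownames(per_group) <- NULL
  }
  overall <- data.frame(auc = mean(per_rater$auc), recall = mean(per_rater$recall),
                        precision = mean(per_rater$precision),
                        specificity = mean(per_rater$specificity),
                        n_raters = nrow(per_rater))
  structure(list(per_rater = per_rater, per_group = per_group,
                 overall = overall, threshold = threshold),
            class = "diagnostic_accuracy")
}

#' @export
print.diagnostic_accuracy <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy at overall PI-RADS >= %d:\n", x$threshold))
  if (!is.null(x$per_group)) print(x$per_group, row.names = FALSE)
  cat("Overall:\n")
  print(x$overall, row.names = FALSE)
  invisible(x)
}
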
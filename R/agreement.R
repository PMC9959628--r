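# Chance-corrected agreement for categorical ratings: percent agreement and
# Gwet's first-order agreement coefficient AC1. AC1 corrects observed
# agreement by the chance probability that two raters agree on a category
# they would pick "at random", pe = sum_k pi_k (1 - pi_k) / (q - 1), which
# unlike kappa's chance term stays small under extreme prevalence (the kappa
# paradox). Variance is Gwet's first-order linearization (raters fixed,
# subjects sampled); a delete-one jackknife is provided as a cross-check.

#' Build a subjects x raters rating matrix
#'
#' @param x A matrix or data frame, rows = subjects, columns = raters; values
#'   are categorical labels, `NA` = missing rating. Rows that are entirely
#'   `NA` are dropped.
#' @return A character matrix with subject row names and rater column names.
#' @export
rating_matrix <- function(x) {
  m <- as.matrix(x)
  mode(m) <- "character"
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- paste0("R", seq_len(ncol(m)))
  keep <- rowSums(!is.na(m)) > 0L
  m[keep, , drop = FALSE]
}

category_counts <- function(m, categories) {
  out <- vapply(categories, function(k) rowSums(m == k, na.rm = TRUE),
                numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, categories))
  out
}

#' Percent agreement of a rating matrix
#'
#' The average, over subjects rated by at least two raters, of the proportion
#' of concordant rater pairs: `sum_k r_ik (r_ik - 1) / (r_i (r_i - 1))`. For
#' two raters this is the fraction of subjects receiving identical labels.
#'
#' @inheritParams gwet_ac1
#' @return Observed agreement in `[0, 1]`.
#' @export
percent_agreement <- function(ratings) {
  m <- rating_matrix(ratings)
  cats <- sort(unique(stats::na.omit(as.vector(m))))
  counts <- category_counts(m, cats)
  ri <- rowSums(counts)
  use <- ri >= 2
  if (!any(use)) {
    stop_piradscde("no subject has two or more ratings", "insufficient_data_error")
  }
  pa_i <- rowSums(counts * (counts - 1)) / pmax(ri * (ri - 1), 1)
  mean(pa_i[use])
}

#' Gwet's AC1 agreement coefficient
#'
#' Computes percent agreement `pa`, chance agreement
#' `pe = (1/(q-1)) * sum_k pi_k (1 - pi_k)` with
#' `pi_k = (1/n) sum_i r_ik / r_i`, and `AC1 = (pa - pe) / (1 - pe)`,
#' together with the first-order linearized variance (treating raters as
#' fixed and subjects as sampled), the normal-approximation confidence
#' interval (upper bound truncated at 1), a two-sided p-value for the test of
#' AC1 = 0, and the qualitative interpretation band of the point estimate.
#'
#' @param ratings Subjects x raters matrix (or data frame) of categorical
#'   labels; `NA` = missing. Subjects with fewer than two ratings contribute
#'   to the category prevalences but not to `pa`.
#' @param categories Category labels defining `q`. Default: the labels
#'   observed in `ratings`. Pass the full value domain to fix the chance
#'   model to the response options offered to raters.
#' @param ci_level Confidence level, default 0.95.
#' @return An object of class `agreement_result`: list with `pa`, `pe`,
#'   `ac1`, `variance`, `se`, `ci_low`, `ci_high`, `p_value`, `n_subjects`,
#'   `q`, `band`.
#' @references Gwet, K. L. (2008). Computing inter-rater reliability and its
#'   variance in the presence of high agreement. British Journal of
#'   Mathematical and Statistical Psychology, 61, 29-48.
#' @examples
#' m <- cbind(r1 = c(rep("A", 8), "B", "B"),
#'            r2 = c(rep("A", 6), "B", "B", "B", "A"))
#' gwet_ac1(m)$ac1
#' @export
gwet_ac1 <- function(ratings, categories = NULL, ci_level = 0.95) {
  m <- rating_matrix(ratings)
  cats <- categories %||% sort(unique(stats::na.omit(as.vector(m))))
  q <- length(cats)
  if (q < 2) {
    stop_piradscde("AC1 requires at least two categories (q >= 2)", "domain_error")
  }
  n <- nrow(m)
  if (n < 2) {
    stop_piradscde("AC1 requires at least two subjects", "insufficient_data_error")
  }
  unknown <- setdiff(unique(stats::na.omit(as.vector(m))), cats)
  if (length(unknown)) {
    stop_piradscde(sprintf("rating(s) outside the category set: %s",
                           paste(unknown, collapse = ", ")), "domain_error")
  }
  counts <- category_counts(m, cats)
  ri <- rowSums(counts)
  use <- ri >= 2
  n2 <- sum(use)
  if (n2 == 0L) {
    stop_piradscde("no subject has two or more ratings", "insufficient_data_error")
  }
  pa_i <- rowSums(counts * (counts - 1)) / pmax(ri * (ri - 1), 1)
  pa <- sum(pa_i[use]) / n2
  pi_k <- colMeans(counts / ri)
  pe <- sum(pi_k * (1 - pi_k)) / (q - 1)
  if (1 - pe < .Machine$double.eps^0.5) {
    stop_piradscde("degenerate prevalence: chance agreement is 1", "degenerate_prevalence_error")
  }
  ac1 <- (pa - pe) / (1 - pe)

  # First-order linearized variance (Gwet 2008): subject-level influence of
  # pa through the agreement term and of pe through the prevalence term.
  pe_r2 <- pe * use
  ac1_i <- (n / n2) * (pa_i - pe_r2) / (1 - pe)
  pe_i <- as.vector((counts / ri) %*% (1 - pi_k)) / (q - 1)
  ac1_ix <- ac1_i - 2 * (1 - ac1) * (pe_i - pe) / (1 - pe)
  variance <- sum((ac1_ix - mean(ac1_ix))^2) / (n * (n - 1))
  se <- sqrt(variance)

  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci_low <- ac1 - z * se
  ci_high <- min(1, ac1 + z * se)
  p_value <- if (se > 0) 2 * stats::pnorm(-abs(ac1) / se) else as.numeric(ac1 == 0)

  structure(list(pa = pa, pe = pe, ac1 = ac1, variance = variance, se = se,
                 ci_low = ci_low, ci_high = ci_high, p_value = p_value,
                 n_subjects = n, q = q, categories = cats,
                 ci_level = ci_level, band = interpret_band(ac1)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Gwet AC1 = %.4f (%s), PA = %.1f%%, %d%% CI [%.4f; %.4f], p = %.3g, n = %d, q = %d\n",
              x$ac1, x$band, 100 * x$pa, round(100 * x$ci_level),
              x$ci_low, x$ci_high, x$p_value, x$n_subjects, x$q))
  invisible(x)
}

#' Delete-one jackknife variance of AC1
#'
#' Independent cross-check of the linearized variance in [gwet_ac1()]:
#' recomputes AC1 with each subject removed and returns
#' `((n-1)/n) * sum_i (theta_(i) - mean(theta))^2`.
#' @inheritParams gwet_ac1
#' @export
jackknife_ac1_variance <- function(ratings, categories = NULL) {
  m <- rating_matrix(ratings)
  cats <- categories %||% sort(unique(stats::na.omit(as.vector(m))))
  n <- nrow(m)
  theta <- vapply(seq_len(n), function(i) {
    gwet_ac1(m[-i, , drop = FALSE], categories = cats)$ac1
  }, numeric(1))
  (n - 1) / n * sum((theta - mean(theta))^2)
}

#' Interpretation band for an agreement coefficient
#'
#' Bands: excellent (> 0.80), good (0.61-0.80), moderate (0.41-0.60),
#' fair (0.21-0.40), poor (<= 0.20). Applied to the point estimate only.
#'
#' @param ac1_value Numeric vector of coefficients (each <= 1).
#' @return Character vector of band labels.
#' @export
interpret_band <- function(ac1_value) {
  if (any(ac1_value > 1 + 1e-12, na.rm = TRUE)) {
    stop_piradscde("agreement coefficients cannot exceed 1", "domain_error")
  }
  cut_pts <- c(-Inf, 0.20, 0.40, 0.60, 0.80, 1)
  labels <- c("poor", "fair", "moderate", "good", "excellent")
  as.character(cut(ac1_value, cut_pts, labels, include.lowest = TRUE))
}

all_rater_pairs <- function(raters) {
  utils::combn(raters, 2, simplify = FALSE)
}

#' Mean pairwise agreement across rater pairs
#'
#' Computes two-rater PA and AC1 for each rater pair on the subjects both
#' members rated, then summarizes across pairs: the mean coefficient, a
#' t-based confidence interval from the across-pair dispersion, and a
#' one-sample t-test p-value for mean AC1 = 0. Six raters give the full set
#' of 15 unordered pairs.
#'
#' @inheritParams gwet_ac1
#' @param pairs List of length-2 character vectors of rater (column) names;
#'   default: all unordered pairs. A pair with no co-rated subject is dropped
#'   with a warning.
#' @return List of class `pairwise_agreement`: `pairs` (per-pair data frame)
#'   and `summary` (one-row data frame with `mean_pa`, `mean_ac1`, CI bounds,
#'   `p_value`, `n_pairs`, `band`).
#' @export
pairwise_mean_agreement <- function(ratings, pairs = NULL, categories = NULL,
                                    ci_level = 0.95) {
  m <- rating_matrix(ratings)
  cats <- categories %||% sort(unique(stats::na.omit(as.vector(m))))
  pairs <- pairs %||% all_rater_pairs(colnames(m))
  rows <- list()
  for (p in pairs) {
    if (!all(p %in% colnames(m))) {
      stop_piradscde(sprintf("pair (%s) references unknown rater(s)",
                             paste(p, collapse = ", ")), "domain_error")
    }
    sub <- m[, p, drop = FALSE]
    sub <- sub[rowSums(!is.na(sub)) == 2L, , drop = FALSE]
    if (nrow(sub) < 2L) {
      warning(sprintf("pair (%s) has fewer than two co-rated subjects; excluded",
                      paste(p, collapse = ", ")))
      next
    }
    res <- gwet_ac1(sub, categories = cats, ci_level = ci_level)
    rows[[length(rows) + 1L]] <- data.frame(
      rater1 = p[1], rater2 = p[2], n_subjects = res$n_subjects,
      pa = res$pa, ac1 = res$ac1, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    stop_piradscde("no rater pair has co-rated subjects", "insufficient_data_error")
  }
  per_pair <- do.call(rbind, rows)
  k <- nrow(per_pair)
  summarize <- function(v) {
    mu <- mean(v)
    if (k > 1L && stats::sd(v) > 0) {
      se <- stats::sd(v) / sqrt(k)
      tq <- stats::qt(1 - (1 - ci_level) / 2, df = k - 1)
      c(mu, mu - tq * se, min(1, mu + tq * se),
        2 * stats::pt(-abs(mu / se), df = k - 1))
    } else {
      c(mu, mu, min(1, mu), as.numeric(mu == 0))
    }
  }
  s_ac1 <- summarize(per_pair$ac1)
  structure(list(
    pairs = per_pair,
    summary = data.frame(
      mean_pa = mean(per_pair$pa), mean_ac1 = s_ac1[1],
      ci_low = s_ac1[2], ci_high = s_ac1[3], p_value = s_ac1[4],
      n_pairs = k, band = interpret_band(s_ac1[1]), stringsAsFactors = FALSE
    )
  ), class = "pairwise_agreement")
}

#' @export
print.pairwise_agreement <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Mean over %d rater pairs: PA = %.1f%%, AC1 = %.4f (%s), CI [%.4f; %.4f], p = %.3g\n",
              s$n_pairs, 100 * s$mean_pa, s$mean_ac1, s$band, s$ci_low,
              s$ci_high, s$p_value))
  invisible(x)
}

#' Intra-rater (test-retest) agreement between two sessions
#'
#' For each rater, pairs the session-1 and session-2 ratings of the same
#' subjects into a two-column matrix and computes PA and AC1.
#'
#' @param session1,session2 Subjects x raters matrices with identical subject
#'   row names and rater column names.
#' @inheritParams gwet_ac1
#' @param groups Optional named character vector rater -> group label; when
#'   given, per-group mean PA/AC1 are reported.
#' @return List of class `intra_rater_agreement` with `per_rater` (data
#'   frame) and `group_means` (data frame or `NULL`).
#' @export
intra_rater_agreement <- function(session1, session2, categories = NULL,
                                  groups = NULL, ci_level = 0.95) {
  m1 <- rating_matrix(session1)
  m2 <- rating_matrix(session2)
  if (!identical(dim(m1), dim(m2)) ||
      !setequal(rownames(m1), rownames(m2)) ||
      !identical(colnames(m1), colnames(m2))) {
    mis <- c(setdiff(rownames(m1), rownames(m2)), setdiff(rownames(m2), rownames(m1)))
    stop_piradscde(sprintf("session subject/rater sets differ%s",
                           if (length(mis)) paste0(" (subjects: ", paste(mis, collapse = ", "), ")") else ""),
                   "alignment_error")
  }
  m2 <- m2[rownames(m1), , drop = FALSE]
  cats <- categories %||% sort(unique(stats::na.omit(c(as.vector(m1), as.vector(m2)))))
  per <- lapply(colnames(m1), function(r) {
    res <- gwet_ac1(cbind(s1 = m1[, r], s2 = m2[, r]), categories = cats,
                    ci_level = ci_level)
    data.frame(rater = r, group = if (!is.null(groups)) groups[[r]] else NA_character_,
               n_subjects = res$n_subjects, pa = res$pa, ac1 = res$ac1,
               ci_low = res$ci_low, ci_high = res$ci_high, p_value = res$p_value,
               band = res$band, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  group_means <- NULL
  if (!is.null(groups)) {
    group_means <- do.call(rbind, lapply(split(per, per$group), function(g) {
      data.frame(group = g$group[1], n_raters = nrow(g), mean_pa = mean(g$pa),
                 mean_ac1 = mean(g$ac1), band = interpret_band(mean(g$ac1)),
                 stringsAsFactors = FALSE)
    }))
    rownames(group_means) <- NULL
  }
  structure(list(per_rater = per, group_means = group_means),
            class = "intra_rater_agreement")
}

#' @export
print.intra_rater_agreement <- function(x, ...) {
  cat("Intra-rater agreement (session 1 vs session 2):\n")
  print(x$per_rater, row.names = FALSE)
  if (!is.null(x$group_means)) {
    cat("Group means:\n")
    print(x$group_means, row.names = FALSE)
  }
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences; zero differences are dropped. The
#' exact distribution is used for 25 or fewer non-zero untied pairs, and the
#' normal approximation with tie correction and continuity correction
#' otherwise. The statistic W is the sum of the ranks of the positive
#' differences.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @return List with `statistic` (W), `p_value`, `n` (non-zero pairs), and
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) {
    stop_piradscde("x and y must have equal length", "domain_error")
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop_piradscde("all paired differences are zero", "degenerate_test_error")
  }
  ranks <- rank(abs(d))
  W <- sum(ranks[d > 0])
  ties <- anyDuplicated(ranks) > 0L
  if (n <= 25L && !ties) {
    ht <- stats::wilcox.test(d, exact = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n,
         method = "exact")
  } else if (n <= 16L) {
    # exact null by enumerating the 2^n sign assignments (midranks kept)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% ranks)
    mu <- sum(ranks) / 2
    p <- mean(abs(w_all - mu) >= abs(W - mu) - 1e-9)
    list(statistic = W, p_value = p, n = n, method = "exact")
  } else {
    ht <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n,
         method = "normal approximation with tie correction")
  }
}
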
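# Independent brute-force oracle for the agreement statistics: plain loops
# over subjects and categories, no shared code with the package's vectorized
# implementation.

oracle_agreement <- function(m, categories = NULL) {
  m <- as.matrix(m)
  mode(m) <- "character"
  m <- m[rowSums(!is.na(m)) > 0, , drop = FALSE]
  cats <- if (is.null(categories)) sort(unique(na.omit(as.vector(m)))) else categories
  q <- length(cats)
  n <- nrow(m)
  pa_terms <- c()
  pik_sum <- rep(0, q)
  for (i in seq_len(n)) {
    row <- m[i, ]
    rik <- sapply(cats, function(k) sum(row == k, na.rm = TRUE))
    ri <- sum(rik)
    if (ri >= 2) {
      agree <- 0
      for (k in seq_len(q)) agree <- agree + rik[k] * (rik[k] - 1)
      pa_terms <- c(pa_terms, agree / (ri * (ri - 1)))
    }
    pik_sum <- pik_sum + rik / ri
  }
  pa <- mean(pa_terms)
  pik <- pik_sum / n
  pe <- sum(pik * (1 - pik)) / (q - 1)
  list(pa = pa, pe = pe, ac1 = (pa - pe) / (1 - pe))
}

random_ratings <- function(n, raters, q, prob = NULL, miss = 0) {
  m <- matrix(sample(LETTERS[1:q], n * raters, replace = TRUE, prob = prob),
              n, raters)
  if (miss > 0) m[runif(length(m)) < miss] <- NA
  # keep every subject with at least one rating and at least one pair overall
  m[rowSums(!is.na(m)) > 0, , drop = FALSE]
}

# A fully populated, strictly valid CDE report (deterministic).
complete_report <- function(overrides = c()) {
  base <- c(
    lesion_dim_max = ">=5", lesion_location = "PZ",
    t2w_present_and_adequate = "YES", t2w_abnormality = "YES",
    t2w_invasive = "NO", t2w_signal_intensity_type = "Hypointense",
    t2w_signal_intensity = "Moderate", t2w_uniformity = "Homogeneous",
    t2w_focality = "YES", t2w_shape = "Lenticular",
    t2w_shape_category = "Round", t2w_margin = "Indistinct",
    t2w_margin_category = "Non_Circumscribed",
    adc_present_and_adequate = "YES", adc_abnormality = "YES",
    adc_invasive = "NO", adc_signal_intensity_type = "Hypointense",
    adc_signal_intensity = "Marked", adc_focality = "YES",
    adc_shape = "Lenticular", adc_shape_category = "Round",
    dwi_present_and_adequate = "YES", dwi_abnormality = "YES",
    dwi_invasive = "NO", dwi_signal_intensity_type = "Hyperintense",
    dwi_signal_intensity = "Marked", dwi_focality = "YES",
    dwi_shape = "Lenticular", dwi_shape_category = "Round",
    dce_present_and_adequate = "YES", dce_abnormality = "YES",
    dce_enhancement = "Positive_DCE", dce_corresponds_to = "DWI",
    dce_bph_features = "NO"
  )
  base[names(overrides)] <- overrides
  base
}

# Tiny noise-free study config shared by several tests.
noise_free_config <- function(seed = 11, ...) {
  eps0 <- c(piradscde:::.default_epsilon * 0, dce_abnormality = 0)
  generator_config(epsilon = eps0, rho = 1, underscore_rate = 0,
                   epsilon_scale = c(experienced = 1, inexperienced = 1),
                   seed = seed, ...)
}
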
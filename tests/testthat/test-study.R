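test_that("feature table reports perfect rows when all raters agree", {
  study <- generate_study(noise_free_config(seed = 17))
  ft <- feature_agreement_table(study$reports, study$design, study$manifest)
  expect_true(all(ft$pa == 100))
  expect_true(all(ft$ac1 == 1))
  expect_true(all(ft$band == "excellent"))
  # present-and-adequate flags are constant and excluded by default
  expect_false(any(grepl("present_and_adequate", ft$feature)))
  expect_identical(nrow(ft), 30L)
})

test_that("feature table strata subset raters and lesions", {
  study <- generate_study(generator_config(seed = 18))
  ft_pz <- feature_agreement_table(study$reports, study$design, study$manifest,
                                   zone = "PZ", features = "t2w_focality")
  expect_identical(ft_pz$n_subjects, 28L)  # 14 lesions x 2 pooled sessions
  ft_exp <- feature_agreement_table(study$reports, study$design, study$manifest,
                                    group = "experienced", features = "t2w_focality")
  expect_identical(ft_exp$n_pairs, 3L)     # C(3, 2)
  ft_s1 <- feature_agreement_table(study$reports, study$design, study$manifest,
                                   session = 1, features = "t2w_focality")
  expect_identical(ft_s1$n_subjects, 32L)
  # a stratum with fewer than two lesions is refused
  afms_one <- study$manifest[study$manifest$zone == "PZ" |
                               study$manifest$lesion_id ==
                               study$manifest$lesion_id[study$manifest$zone == "AFMS"][1], ]
  expect_error(
    feature_agreement_table(study$reports, study$design, afms_one, zone = "AFMS"),
    class = "insufficient_data_error")
})

test_that("mean-of-sessions pooling brackets the per-session statistics", {
  study <- generate_study(generator_config(seed = 19))
  f <- "t2w_uniformity"
  s1 <- feature_agreement_table(study$reports, study$design, study$manifest,
                                session = 1, features = f)
  s2 <- feature_agreement_table(study$reports, study$design, study$manifest,
                                session = 2, features = f)
  ov <- feature_agreement_table(study$reports, study$design, study$manifest,
                                session = "overall", pooling = "mean", features = f)
  expect_gte(ov$ac1, min(s1$ac1, s2$ac1) - 1e-12)
  expect_lte(ov$ac1, max(s1$ac1, s2$ac1) + 1e-12)
})

test_that("category tables cover the four PI-RADS variables", {
  study <- generate_study(generator_config(seed = 20))
  ct <- category_agreement_table(study$scores, study$design)
  expect_identical(nrow(ct), 12L)  # 4 variables x {1, 2, overall}
  expect_setequal(unique(ct$feature),
                  c("T2W PI-RADS", "DWI PI-RADS", "DCE PI-RADS", "OVERALL PI-RADS"))
  expect_true(all(ct$n_pairs == 15L))

  intra <- intra_category_agreement(study$scores, study$design)
  expect_identical(nrow(intra), 12L)  # 4 variables x {experienced, inexperienced, overall}
  expect_true(all(intra$n_raters[intra$group == "overall"] == 6L))
})

test_that("intra-rater percent agreement matches the confusion closed form", {
  # a single rater whose session 2 repeats session 1 with 10% confusion
  set.seed(77)
  n <- 500
  s1 <- sample(as.character(1:5), n, TRUE)
  flip <- runif(n) < 0.10
  s2 <- ifelse(flip, vapply(s1, function(v) sample(setdiff(as.character(1:5), v), 1), ""), s1)
  scores <- data.frame(
    lesion_id = rep(sprintf("L%03d", 1:n), 2), rater_id = "R1",
    session = rep(1:2, each = n),
    t2w_score = rep(1L, 2 * n), dwi_score = rep(1L, 2 * n),
    dce_result = "Negative", overall = as.integer(c(s1, s2)))
  design <- data.frame(rater_id = "R1", group = "experienced")
  res <- intra_category_agreement(scores, design)
  pa_overall <- res$pa[res$feature == "OVERALL PI-RADS" & res$group == "overall"]
  se <- 100 * sqrt(0.9 * 0.1 / n)
  expect_lt(abs(pa_overall - 90), 3 * se)
})

test_that("group score comparison pairs lesions and degrades gracefully", {
  study <- generate_study(generator_config(seed = 22))
  cmp <- group_score_comparison(study$scores, study$manifest, study$design)
  expect_identical(cmp$n_lesions, 16L)
  expect_identical(cmp$group_stats$group, c("experienced", "inexperienced"))
  expect_gt(cmp$group_stats$mean[1], cmp$group_stats$mean[2])

  # identical group distributions: reported as no difference, not an error
  sc <- study$scores
  sc$overall <- 3L
  cmp0 <- group_score_comparison(sc, study$manifest, study$design)
  expect_true(is.na(cmp0$p_value))
  expect_match(cmp0$note, "no difference")
})

test_that("a half-category group shift is detected with high power", {
  design <- data.frame(rater_id = c("E1", "I1"),
                       group = c("experienced", "inexperienced"))
  manifest <- lesion_manifest(sprintf("L%02d", 1:16), rep("PZ", 16), rep(TRUE, 16))
  set.seed(55)
  detected <- replicate(500, {
    base <- sample(3:4, 16, TRUE)
    shift <- rbinom(16, 1, 0.5)
    scores <- data.frame(
      lesion_id = rep(manifest$lesion_id, 2),
      rater_id = rep(c("E1", "I1"), each = 16), session = 1L,
      t2w_score = 3L, dwi_score = 3L, dce_result = "Negative",
      overall = as.integer(c(pmin(5, base + shift), base)))
    cmp <- group_score_comparison(scores, manifest, design)
    !is.na(cmp$p_value) && cmp$p_value < 0.05
  })
  expect_gt(mean(detected), 0.8)
})

test_that("diagnostic accuracy matches forced confusion counts", {
  manifest <- lesion_manifest(sprintf("L%02d", 1:32), rep("PZ", 32),
                              rep(c(TRUE, FALSE), each = 16))
  const <- data.frame(lesion_id = manifest$lesion_id, rater_id = "R1",
                      session = 1L, t2w_score = 5L, dwi_score = 5L,
                      dce_result = "Positive", overall = 5L)
  acc <- diagnostic_accuracy(const, manifest)
  expect_equal(acc$overall$recall, 1)
  expect_equal(acc$overall$specificity, 0)
  expect_equal(acc$overall$precision, 0.5)

  sep <- const
  sep$overall <- ifelse(manifest$clinically_significant, 5L, 1L)
  expect_equal(diagnostic_accuracy(sep, manifest)$overall$auc, 1)

  one_class <- lesion_manifest(manifest$lesion_id, manifest$zone, rep(TRUE, 32))
  expect_warning(acc1 <- diagnostic_accuracy(const, one_class), "one class")
  expect_true(is.na(acc1$overall$auc))
  expect_equal(acc1$overall$recall, 1)
})

test_that("AUC centers on 0.5 when scores carry no label information", {
  manifest <- lesion_manifest(sprintf("L%02d", 1:32), rep("PZ", 32),
                              rep(c(TRUE, FALSE), each = 16))
  set.seed(66)
  aucs <- replicate(1000, {
    sc <- data.frame(lesion_id = manifest$lesion_id, rater_id = "R1", session = 1L,
                     t2w_score = 1L, dwi_score = 1L, dce_result = "Negative",
                     overall = sample(1:5, 32, TRUE))
    diagnostic_accuracy(sc, manifest)$overall$auc
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se)
})

test_that("raising the significance threshold trades recall for specificity", {
  study <- generate_study(generator_config(seed = 23))
  a3 <- diagnostic_accuracy(study$scores, study$manifest, study$design, threshold = 3)
  a4 <- diagnostic_accuracy(study$scores, study$manifest, study$design, threshold = 4)
  expect_lte(a4$overall$recall, a3$overall$recall)
  expect_gte(a4$overall$specificity, a3$overall$specificity)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  manifest <- lesion_manifest(sprintf("L%02d", 1:32), rep("PZ", 32),
                              rep(c(TRUE, FALSE), 16))
  set.seed(88)
  sc <- data.frame(lesion_id = manifest$lesion_id, rater_id = "R1", session = 1L,
                   t2w_score = 1L, dwi_score = 1L, dce_result = "Negative",
                   overall = sample(1:5, 32, TRUE))
  a <- diagnostic_accuracy(sc, manifest)$overall$auc
  sc2 <- sc
  sc2$overall <- as.integer(sc$overall^2)  # monotone on 1..5
  expect_equal(diagnostic_accuracy(sc2, manifest)$overall$auc, a)
  # independent cross-check of the rank formulation
  ref <- as.numeric(pROC::auc(pROC::roc(manifest$clinically_significant,
                                        sc$overall, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a, ref, tolerance = 1e-12)
})
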
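# Expected scores below are derived by applying the published PI-RADS v2.1
# sequence-scoring and overall-assessment tables by hand to the CDE encoding.

test_that("T2W scoring follows the zone-specific assessment logic", {
  # TZ: non-circumscribed, homogeneous, moderately hypointense, focal,
  # no lenticular shape, not invasive, >=5 but <15 mm -> 4
  r <- complete_report(c(t2w_shape = "Wedge", t2w_shape_category = "Linear"))
  expect_identical(score_t2w(r, "TZ"), 4L)
  # adding size >= 15 upgrades to 5
  expect_identical(score_t2w(complete_report(c(t2w_shape = "Wedge",
    t2w_shape_category = "Linear", lesion_dim_max = ">=15")), "TZ"), 5L)
  # invasive behavior upgrades to 5 as well
  expect_identical(score_t2w(complete_report(c(t2w_shape = "Wedge",
    t2w_shape_category = "Linear", t2w_invasive = "YES")), "TZ"), 5L)
  # TZ circumscribed hypointense nodule (no lenticular shape) -> 2
  expect_identical(score_t2w(complete_report(c(
    t2w_shape = "Wedge", t2w_shape_category = "Linear",
    t2w_margin = "Partly_Encapsulated", t2w_margin_category = "Circumscribed")),
    "TZ"), 2L)
  # no abnormality -> 1 in any zone
  for (z in c("PZ", "TZ", "AFMS")) {
    expect_identical(score_t2w(complete_report(c(t2w_abnormality = "NO")), z), 1L)
  }
  # PZ: circumscribed homogeneous moderate hypointense focal, <15, non-invasive -> 4
  pz4 <- complete_report(c(t2w_margin = "Well_Defined",
                           t2w_margin_category = "Circumscribed"))
  expect_identical(score_t2w(pz4, "PZ"), 4L)
  # AFMS uses the TZ rule set
  expect_identical(score_t2w(complete_report(c(t2w_shape = "Wedge",
    t2w_shape_category = "Linear")), "AFMS"), 4L)
})

test_that("DWI scoring joins ADC and DWI findings", {
  # no abnormality on either diffusion series -> 1
  expect_identical(score_dwi(complete_report(c(adc_abnormality = "NO",
    dwi_abnormality = "NO")), "PZ"), 1L)
  # linear/wedge-shaped mild hypointense ADC -> 2
  expect_identical(score_dwi(complete_report(c(adc_shape = "Linear",
    adc_shape_category = "Linear", adc_signal_intensity = "Mild",
    dwi_signal_intensity = "Mild", dwi_signal_intensity_type = "Isointense")),
    "PZ"), 2L)
  # marked focal ADC hypo + DWI hyper, <15 mm, non-invasive -> 4
  expect_identical(score_dwi(complete_report(), "PZ"), 4L)
  # same with size >= 15 -> 5
  expect_identical(score_dwi(complete_report(c(lesion_dim_max = ">=15")), "PZ"), 5L)
})

test_that("DCE result has exactly three outcomes", {
  expect_identical(score_dce(complete_report(c(dce_present_and_adequate = "NO",
    dce_abnormality = NOT_APPLICABLE, dce_enhancement = NOT_APPLICABLE,
    dce_corresponds_to = NOT_APPLICABLE, dce_bph_features = NOT_APPLICABLE))), "X")
  expect_identical(score_dce(complete_report()), "Positive")
  # focal enhancement attributable to BPH is not positive
  expect_identical(score_dce(complete_report(c(dce_bph_features = "YES"))), "Negative")
  expect_identical(score_dce(complete_report(c(dce_enhancement = "Negative_DCE"))),
                   "Negative")
  expect_identical(score_dce(complete_report(c(dce_corresponds_to = "Not_Available"))),
                   "Negative")
})

test_that("overall category applies the dominant sequence with its two upgrades", {
  expect_identical(overall_category(2, 3, "Positive", "PZ"), 4L)
  expect_identical(overall_category(2, 3, "X", "PZ"), 3L)
  expect_identical(overall_category(2, 3, "Negative", "PZ"), 3L)
  expect_identical(overall_category(2, 4, "Negative", "TZ"), 3L)
  expect_identical(overall_category(3, 5, "Negative", "TZ"), 4L)
  expect_identical(overall_category(3, 4, "Negative", "TZ"), 3L)
  expect_identical(overall_category(5, 1, "X", "AFMS"), 5L)
  expect_error(overall_category(6, 3, "Negative", "PZ"), class = "domain_error")
  expect_error(overall_category(3, 3, "Maybe", "PZ"), class = "domain_error")
  expect_error(overall_category(3, 3, "Negative", "CZ"), class = "domain_error")
})

test_that("incomplete reports refuse scoring and list the absent CDEs", {
  r <- complete_report()
  r <- r[setdiff(names(r), c("t2w_signal_intensity", "t2w_uniformity"))]
  err <- expect_error(score_t2w(r, "PZ"), class = "incomplete_report_error")
  expect_match(conditionMessage(err), "t2w_signal_intensity")
  expect_match(conditionMessage(err), "t2w_uniformity")
})

test_that("scoring is deterministic and score_reports joins the manifest zones", {
  r <- complete_report()
  s1 <- score_report(r, "TZ")
  s2 <- score_report(r, "TZ")
  expect_identical(s1, s2)
  expect_identical(s1$overall,
                   overall_category(s1$t2w_score, s1$dwi_score, s1$dce_result, "TZ"))

  study <- generate_study(generator_config(seed = 2))
  sc <- score_reports(study$reports, study$manifest)
  expect_identical(nrow(sc), 32L * 6L * 2L)
  expect_true(all(sc$overall %in% 1:5))
  expect_true(all(sc$dce_result %in% c("Positive", "Negative", "X")))
  expect_error(score_reports(study$reports, study$manifest[-1, ]),
               class = "manifest_error")
})

test_that("the shipped rule table is complete and consistent by enumeration", {
  chk <- check_rule_table()
  expect_true(chk$ok)
  for (b in chk$blocks) {
    expect_identical(b$n_gaps, 0L)
    expect_identical(b$n_conflicts, 0L)
  }
  # the mutually exclusive overall tables have no overlaps at all
  expect_identical(chk$blocks[["overall/PZ"]]$n_resolved_overlaps, 0L)
  expect_identical(chk$blocks[["overall/TZ"]]$n_resolved_overlaps, 0L)
})

test_that("rule-table defects are surfaced as gaps", {
  rules <- load_rules()
  # delete the TZ upgrade exception at t2w = 3, dwi = 5
  rules$sequences$overall$TZ <- Filter(function(r) r$id != "tz-ov-3-dwi-upgrade",
                                       rules$sequences$overall$TZ)
  chk <- check_rule_table(rules)
  expect_false(chk$ok)
  expect_gt(chk$blocks[["overall/TZ"]]$n_gaps, 0L)
  expect_identical(unique(chk$blocks[["overall/TZ"]]$gaps$t2w), "3")
  expect_identical(unique(chk$blocks[["overall/TZ"]]$gaps$dwi), "5")

  rules$sequences$overall$TZ <- list()
  chk2 <- check_rule_table(rules)
  expect_false(chk2$ok)
  expect_true(chk2$blocks[["overall/TZ"]]$empty)
})

test_that("scores never decrease when the size bin grows", {
  for (spec in list(c("t2w", "PZ"), c("t2w", "TZ"), c("dwi", "PZ"))) {
    grid <- enumerate_scores(spec[1], spec[2])
    others <- setdiff(names(grid), c("lesion_dim_max", ".rule", ".target"))
    key <- do.call(paste, grid[others])
    s5 <- as.integer(grid$.target[grid$lesion_dim_max == ">=5"])
    s15 <- as.integer(grid$.target[grid$lesion_dim_max == ">=15"])
    names(s5) <- key[grid$lesion_dim_max == ">=5"]
    names(s15) <- key[grid$lesion_dim_max == ">=15"]
    expect_true(all(s15[names(s5)] >= s5))
  }
})

test_that("DCE affects the overall category only in the PZ at DWI 3", {
  for (zone in c("PZ", "TZ")) {
    grid <- enumerate_scores("overall", zone)
    key <- paste(grid$t2w, grid$dwi)
    for (k in unique(key)) {
      targets <- unique(grid$.target[key == k])
      dwi_k <- unique(grid$dwi[key == k])
      if (zone == "PZ" && dwi_k == "3") {
        expect_length(targets, 2L)
      } else {
        expect_length(targets, 1L)
      }
    }
  }
})
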
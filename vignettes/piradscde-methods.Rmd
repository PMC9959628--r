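---
title: "Methods: CDE-based PI-RADS v2.1 reporting, scoring, and reader agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CDE-based PI-RADS v2.1 reporting, scoring, and reader agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piradscde)
```

This vignette is the package's account of its own methods: what is modeled,
which choices were genuinely open, how each was resolved, and what the
synthetic experiments do and do not demonstrate about real reader studies.

## 1. The report schema

PI-RADS v2.1 assessment is decomposed into 34 common data elements (CDEs):
two global variables (the binned maximal lesion diameter `lesion_dim_max`
with ordered levels `<5`, `>=5`, `>=15` mm, and `lesion_location`) and four
modality blocks (T2W, ADC, DWI, DCE), each anchored by a
`*_present_and_adequate` flag. Every variable has a fixed categorical value
domain and, where available, a RadLex term. The schema is shipped as a
versioned JSON document (`inst/extdata/cde_schema.json`), not hard-coded, so
the vocabulary is reviewable and replaceable.

**Applicability.** Modality descriptors apply only when the modality's
present-and-adequate flag is `YES`. The predicate is three-valued: when a
gating variable is itself unpopulated, the dependent variables' applicability
is *unknown* — strict validation then flags the unanswered gate as missing
rather than cascading demands or complaints onto its dependents. A populated
descriptor under a gate explicitly set to `NO` is a violation; the
`NOT_APPLICABLE` sentinel is admissible exactly where the predicate fails.
Missingness (record absent) and explicit non-applicability are distinct
states end to end, so an unavailable DCE sequence is never conflated with a
rater who skipped the question.

**Shape dialects.** Two shape vocabularies circulate: the full lexicon list
(round, oval, lenticular, lobulated, tear-shaped, wedge-shaped, linear,
irregular) and the four-value report-form list (Linear, Wedge, Lenticular,
Water-Drop). Which one a given form used is an empirical fact about that
form, so the schema ships both as selectable dialects
(`load_schema(shape_dialect = )`, default `"table1"`), and the
simplification map `categorize_shape()` is total over the union:
linear/wedge shapes map to **Linear**; round, oval, lenticular, water-drop
and tear-shaped to **Round** (teardrop morphology is a lentiform, rounded
outline); lobulated and irregular to **Irregular**. `categorize_margin()`
groups indistinct, obscured, spiculated and erased-charcoal-sign margins as
**Non_Circumscribed** and encapsulated, partly-encapsulated and well-defined
margins as **Circumscribed**; encapsulated margins are circumscribed by
definition in PI-RADS usage. Both maps are surjective by enumeration test.

**Spelling aliases.** The ADC signal-intensity type accepts the form
spellings "Hypointensitivity" / "Isointensitivity" / "Hyperintensitivity" as
aliases, normalized on input to Hypointense/Isointense/Hyperintense for
uniform downstream handling.

**AFMS.** The manifest assigns each lesion one of three zones (PZ, TZ,
AFMS), while the report-level `lesion_location` CDE has no AFMS level. These
are deliberately distinct fields: anterior-stroma lesions are analyzed as
their own stratum but are *scored* with the TZ rule set (PI-RADS treats
anterior stromal lesions under T2W dominance), and their latent
`lesion_location` truth in the generator is `TZ`.

## 2. The scoring engine

The engine maps a completed report to T2W and DWI scores (1–5), the
three-outcome DCE result (Positive / Negative / X), and the overall category.
Rule content lives in a versioned JSON document
(`inst/extdata/pirads_rules.json`) rather than in code: the guideline
encoding is precisely the part domain experts dispute (the DWI score-2
linear/wedge criterion in the transition zone is a known point of
contention), so it must be reviewable and editable as data.

**Semantics.** Each sequence/zone block is an *ordered decision list*: the
first rule whose predicate holds determines the score. A predicate is a
disjunction of conjunctive variable-in-values clauses; a rule may be flagged
`otherwise` as an explicit catch-all. We chose first-match semantics over
globally mutually exclusive predicates because exclusivity-by-conjunction
would force every rule to carry the negation of all earlier rules — the
score-5 predicate deliberately *refines* the score-4 predicate (adding
size ≥ 15 mm or invasive behavior), and writing that exclusively would
be unreadable as data. The overall-assessment blocks, by contrast, are small
enough to be written exhaustively and mutually exclusively with no
catch-all, and `check_rule_table()` verifies all of this by enumerating the
full product of the referenced variables' domains: zero gaps, zero
conflicting double-matches, and for the overall tables zero overlaps of any
kind. Deleting a rule produces a reported gap; an empty block is flagged.

**Scoring content.** Score 1 requires absence of abnormality; the high-score
predicates encode the published criteria (PZ T2W 4: circumscribed,
homogeneous, moderately/markedly hypointense focal mass; TZ T2W 4:
non-circumscribed or lenticular, homogeneous, hypointense; DWI 4: focal
markedly hypointense ADC *and* markedly hyperintense DWI), with the size bin
`>=15` or invasiveness = `YES` upgrading 4 to 5. The `>=15` bin corresponds
to the guideline's 1.5 cm cut. The DCE result is Positive only for a
positive enhancement pattern corresponding to a T2W or DWI finding and not
attributable to benign prostatic hyperplasia; an absent/inadequate DCE
sequence yields X, which never upgrades. Overall: DWI dominates in the PZ
(DCE upgrades 3 to 4 when Positive); T2W dominates in TZ/AFMS (DWI ≥ 4
upgrades T2W 2 to 3; DWI 5 upgrades T2W 3 to 4). The engine's
size-monotonicity and the locality of the DCE effect (PZ, DWI = 3 only) are
verified over the full enumeration in the test suite.

**Invasiveness.** The `*_invasive` CDEs are read as the score-5 criterion
(definite extraprostatic extension / frankly invasive behavior). Readers
disagree on whether extension into neighboring zones counts; under the
assessment rules the broader reading is the operative one. The engine takes
the CDE at face value and leaves the interpretive dispute to the schema
documentation — it is not resolvable in code.

**Incompleteness.** Scoring refuses incomplete reports with an error listing
the absent CDEs. No imputation: agreement analysis downstream requires the
category to be a deterministic function of the recorded values.

## 3. Agreement statistics

For `n` subjects, `q` categories, `r_ik` raters placing subject `i` in
category `k`, and `r_i = Σ_k r_ik`:

* `pa` — mean over subjects with `r_i ≥ 2` of `Σ_k r_ik(r_ik−1) / (r_i(r_i−1))`;
* `π_k = (1/n) Σ_i r_ik / r_i`, `pe = (1/(q−1)) Σ_k π_k (1−π_k)`;
* `AC1 = (pa − pe)/(1 − pe)`.

Subjects with fewer than two ratings still contribute to the prevalences
`π_k` but not to `pa` — the standard multi-rater treatment of missing cells.
The chance term is bounded by `1/q`, which is what makes AC1 resistant to
the prevalence paradox: for `q = 2`, `pe ≤ 1/2` implies `AC1 ≥ 2·pa − 1`
always (property-tested on 1000 random matrices).

**Variance.** The primary estimator is Gwet's first-order linearization with
raters treated as fixed and subjects as sampled; no finite-population
correction is applied (the lesion sample is treated as drawn from an
effectively infinite case population). A delete-one jackknife is implemented
as an independent cross-check. The two are first-order equivalent: their
relative difference is large on 4–6-subject matrices (as it must be for any
such pair of estimators), typically within a few percent by `n ≈ 20`, and
below 1% by `n ≈ 150`. The test suite asserts exact point-estimate agreement
with a brute-force oracle (1e−12) and tracks the variance against the
jackknife both in aggregate over small random matrices and per-matrix at
moderate `n`. The test of AC1 = 0 uses the normal approximation; its
measured type-I error at `n = 32`, two raters, uniform binary ratings is
within Monte-Carlo error of the nominal 5% (2000 replicates).

**Category set.** `gwet_ac1()` defaults to the categories observed in the
matrix. The study-level tables instead fix the category set to the
variable's full schema domain: the chance model should reflect the options
the form offered, and this keeps rows comparable across strata and avoids
degenerate `q = 1` cells when a stratum happens to be unanimous. With all
mass on one category `pe = 1/q < 1`, so AC1 remains defined and equals 1
exactly when agreement is perfect.

**Intervals and bands.** CIs are `AC1 ± z·se` with the upper bound truncated
at 1; interpretation bands — excellent (> 0.80), good (0.61–0.80), moderate
(0.41–0.60), fair (0.21–0.40), poor (≤ 0.20) — are applied to the point
estimate only. The poor threshold is 0.20 on the coefficient scale.

**Pairwise-mean layout.** Inter-rater tables report the *mean over rater
pairs* of two-rater PA and AC1 (15 pairs for six raters), with a t-based CI
from the across-pair dispersion and a one-sample t-test against zero. This
is a different uncertainty statement than the subject-sampling variance of a
single six-rater AC1 — it describes the spread among reader pairings, which
is the quantity of interest when readers differ systematically. The
"overall" column pools the two sessions as additional replicate pairs by
default (`pooling = "pool"`); `pooling = "mean"` averages the per-session
statistics instead, in which case the overall value is bracketed by the
session values. Both are defensible readings of a sessions-combined column;
the switch makes the choice explicit.

**Wilcoxon signed-rank.** Zero differences are dropped; `W` is the
positive-rank sum. With ≤ 25 untied non-zero pairs the exact signed-rank
distribution is used; with ties and ≤ 16 pairs the exact null is obtained by
enumerating all `2^n` sign assignments on the midranks (the textbook
small-sample recipe, which the large-sample machinery cannot reproduce);
otherwise the normal approximation with tie and continuity correction.

## 4. The synthetic reader study

The generator emulates the reference study design: 32 lesions — 14 PZ
(7 clinically significant + 7 not), 11 TZ (5 + 6), 7 AFMS (4 + 3) — six
raters in two experience groups of three, two sessions. Each lesion gets a
latent true CDE profile drawn from zone- and significance-conditional
prevalences: clinically significant lesions are predominantly ≥ 5 mm
(half ≥ 15 mm), markedly diffusion-restricting, focal and homogeneously
hypointense on T2W; benign lesions sit mostly in the 1–3 score range with
occasional enhancing BPH mimics. These prevalences encode that
histopathology-confirmed significant lesions preselected for a reader study
are predominantly category-4/5 findings.

**Noise model.** A rater's session-1 value of variable `f` equals the truth
with probability `1 − ε_f` and otherwise confuses uniformly over the other
`q − 1` domain values; session 2 repeats the rater's session-1 value with
probability `ρ` (default 0.85) and is otherwise regenerated from the
session-1 mechanism. Under this model two independent raters agree with
probability `(1−ε)² + ε²/(q−1)` (`expected_pairwise_pa()`), the closed form
the parameter-recovery tests target. Symmetric confusion is the default; an
`ordinal_adjacent` mode confuses ordinal variables (signal-intensity scale,
size bin) only with neighboring levels, since misgrading an intensity by two
steps is less plausible than by one.

**Default confusion rates** (per feature class, probability of departing
from truth): abnormality 0.04, signal-intensity type 0.03, BPH features
0.10, enhancement 0.13, DCE abnormality 0.13, corresponds-to 0.15, size bin
0.15, zone 0.12, margin category 0.18, focality and invasiveness 0.20,
uniformity 0.22, shape category 0.30, signal-intensity scale 0.33, raw shape
0.45, raw margin 0.55. The ordering — near-perfect for abnormality detection
and intensity type, poor for raw morphology — mirrors what reader studies of
the PI-RADS lexicon consistently report; the magnitudes are round values
chosen once to land the derived percent agreements in the empirically
typical ranges (90%+ for objective features, 20–35% for raw shape/margin).
Experience enters twice: a per-group multiplier on all confusion rates
(default 1.2 for the experienced group — experienced readers, counter to
intuition, tend to agree *less* on subjective features), and a score
underestimation mechanism by which an inexperienced rater downgrades the
overall category of a clinically significant lesion by one point with
probability 0.5, reproducing the tendency of less experienced readers to
retreat to equivocal categories.

**Category coupling and its limits.** Manual PI-RADS categories are derived
by pushing each rater's noisy CDE values through the rule engine — the same
path a guideline-compliant structured-reporting workflow enforces. This
coupling has a consequence worth stating plainly: because the high-score
predicates are conjunctions of several noisy descriptors, per-feature noise
*attenuates* derived categories toward the middle of the scale, so the
simulated mean category on clinically significant lesions is lower than the
means human readers (who grade holistically, not by recomputing rules from
their own form entries) produce. The generator therefore reproduces the
study's qualitative contrasts — objective features outrank subjective ones
in AC1, experienced readers score significant lesions higher, small strata
give wider intervals, the three-outcome DCE variable shows inflated raw
agreement — but not the absolute magnitudes of human score distributions,
and it does not model inter-feature error correlation, reader drift between
sessions, case-difficulty heterogeneity, or image appearance at all.
Passing tests certify the statistical machinery and the engine, not fidelity
to any particular group of six radiologists.

## 5. Study-level analyses

* `feature_agreement_table()` — one row per CDE (the present-and-adequate
  flags, constant by design, are excluded by default), pairwise-mean PA/AC1
  with CI and band, for any session × experience-group × zone stratum.
  Strata with fewer than two lesions are refused.
* `category_agreement_table()` / `intra_category_agreement()` — the same
  machinery on the four derived category variables (T2W, DWI, DCE, overall),
  inter-rater per session and pooled, and intra-rater (session 1 vs 2) per
  rater with group means.
* `group_score_comparison()` — on the clinically significant subset, the
  two groups' per-lesion mean overall categories are paired by lesion
  (raters are unpaired across groups, lesions are the natural pairing unit)
  and compared by Wilcoxon signed-rank; identical distributions are reported
  as "no difference" rather than raised, since a null difference is a
  finding, not a failure.
* `diagnostic_accuracy()` — predictions are `overall ≥ 3` (the
  referral-for-biopsy cut; the threshold is a parameter). Recall, precision
  and specificity come from confusion counts; AUC uses the ordinal 1–5
  category via the Mann–Whitney rank formulation with midrank tie
  correction, making it invariant under monotone re-scalings of the
  category axis. Metrics are computed per rater (sessions pooled as repeated
  reads) and averaged within experience group — a group summary of
  individual diagnostic performance; `aggregate = "pooled"` gives the
  all-reads-as-one-sample alternative. If the labels are all one class the
  AUC is undefined and returned as `NA` with a warning while the defined
  confusion-count metrics are still reported.

Determinism: every analysis is a pure function of its inputs, and the
generator is a pure function of its config (including the seed), so rerunning
with the same seed reproduces every table cell bit-identically.

## 6. Problem sizes and numerical tolerances

The test suite exercises: oracle agreement on 200 random matrices
(4–12 subjects, 2–4 raters, 2–4 categories) at 1e−12; the binary-rating
lower bound on 1000 matrices; null calibration with 2000 replicates of
32 subjects × 2 raters; parameter recovery at 2000 lesions against the
closed form within three binomial standard errors; full rule-table
enumeration (≈ 76,000 input combinations across blocks); and 200 replicate
studies for the feature-ordering sign test (p < 0.01) and the
small-stratum/wide-interval comparison. These sizes were chosen so Monte
Carlo error is small relative to the effects asserted while the whole suite
stays comfortably fast on a single CPU. `scripts/acceptance.R` recomputes
the headline quantities from scratch at the same sizes.
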
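---
title: "Scoring, accuracy statistics and cohort calibration in siascore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, accuracy statistics and cohort calibration in siascore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siascore)
```

## The scoring rules

Three rule-based classifiers map an expert-scored lesion record to a
benign/suspicious triage call. All are pure functions of the record and a
`weight_config`; every point value, threshold and cut point lives in the
shipped YAML configs, so transcription corrections never require a code
change.

**Moncrieff scoring system (MSS).** Points for the four melanoma-associated
SIAscopic features (dermal melanin, collagen holes, erythematous blush,
blood displacement), a size term and an age term; no gate. Built for
referred populations, it misreads primary-care case mix: seborrhoeic
keratoses frequently show apparent dermal melanin, the highest-weighted
feature.

**Primary Care Scoring Algorithm (PCSA).** First the non-melanocytic gate:
blood lacunes identify haemangioma; white dots on the collagen view or a
cerebriform melanin pattern identify seborrhoeic keratosis. Gated lesions
are benign outright, with the gate recorded in place of a score. The gate
is evaluated lacunes-first: haemangioma has a single pathognomonic feature,
and the order only matters for lesions triggering both gates, whose
classification is benign either way. Ungated lesions are then scored as in
the MSS plus two points for blood vessels.

The default PCSA point values shipped in `pcsa_default.yaml`
(dermal melanin 2, collagen holes 1, erythematous blush 1, blood
displacement 1, blood vessels 2, size term 1, age term 1, threshold 3) are
documented fallback values: the algorithm's published flow diagram is not
machine-readable in all copies, while the two-point blood-vessels term is
stated in the accompanying text. Erythematous blush and blood displacement
are kept as two separately weighted features even though they are often
described jointly; a config edit can merge them by zero-weighting one.

**Size and age terms.** The size term fires for diameters strictly greater
than 6 mm (`size_threshold_mm`), the age term at 50 years and above
(`age_band_edge_years`). The age banding is a single configurable edge
because nothing finer is specified for the algorithm; 50 years splits the
study populations (mean ages ~45 and 50) roughly in half. The 7-point
checklist keeps its conventional, separate ≥ 7 mm diameter item — the two
cut points are deliberately not unified.

**7-point checklist.** Three major items (change in size, irregular shape,
irregular colour) at 2 points, four minor at 1, referral at ≥ 3. Records
whose checklist block was not collected score `NA` and are excluded from
7-point analyses rather than imputed; no imputation rule is defensible for
a referral checklist.

## Accuracy statistics

**Wilson intervals.** All proportion intervals use the Wilson score form,
which keeps good coverage at the small cell counts typical of melanoma
studies and never leaves [0, 1]. The default quantile is
`qnorm(0.975)` = 1.959964 with an explicit override (`z_quantile = 1.96`
reproduces the same published two-decimal cells). At the boundary counts
(0 or n successes) the bounds are set exactly to the estimate's side to
avoid floating-point residue. Statistics with a zero denominator carry an
explicit `undefined` marker, never `NaN`.

**ROC and AUC.** The empirical ROC is computed per distinct score value;
the trapezoidal AUC is assembled from integer cumulative counts, so it
equals the Mann–Whitney pair-count statistic (ties at one half) to machine
identity — the suite checks this against a brute-force pairwise oracle and
against pROC. Lesions removed by the PCSA gate carry no score; `roc_curve`
offers two policies: `exclude` (the gate as a separate triage step) and
`floor` (gated lesions ranked below every scored lesion), the latter used
when two rules must be compared on identical lesion sets.

**Hanley–McNeil.** The closed-form AUC standard error uses
`Q1 = A/(2−A)`, `Q2 = 2A²/(1+A)`; the correlated z-test is
`z = (A₁−A₂)/√(SE₁² + SE₂² − 2r·SE₁SE₂)`. The correlation `r` may be
supplied directly (the original manual method reads it off a coarse
published lookup table) or estimated by the standard working surrogate:
the mean of the within-positives and within-negatives Pearson correlations
of the two score vectors. Two numerical properties matter in practice and
are reflected in the test design. First, the Q1/Q2 moments are exact under
the bi-exponential ROC model; the simulation cross-check therefore draws
exponential scores (agreement within a few percent), whereas under
binormal scores with very unbalanced groups (e.g. 12 positives against 99
negatives) the formula is visibly conservative — a documented property of
the method, not an implementation defect. Second, for the type-I-error
check of the z-test we simulate balanced groups (50/50, true AUC 0.75,
within-class score correlation 0.5), conditions under which the normal
asymptotics hold and the empirical size sits at the nominal 0.05.

**Reconstruction of published confusion matrices.** Published tables print
four statistics at two decimals but rarely the integer cells.
`reconstruct_confusion_matrix` enumerates every candidate matrix
consistent with the stated denominators and checks which reproduce the
printed values under half-up, half-even or truncating rounding (half-up is
the default; a 1e-9 guard protects values sitting epsilon below a `.xx5`
boundary). Two findings from applying it to the published table are worth
recording. The UK validation column (N = 208, 6 suspicious) pins down the
unique matrix {tp 3, fp 32, fn 3, tn 170}. The Australian column
(N = 581, 52 suspicious; 0.44/0.95/0.52/0.95) admits *no* integer matrix
under any rounding rule — the printed PPV forces 21 false positives while
the printed specificity allows at most 505 true negatives of 529, a
contradiction; most plausibly some lesions were excluded from some
denominators. The package reports the empty set rather than guessing.
Relatedly, the development column's NPV is only reproducible under
truncating rounding, which is why all three rules are offered and each
returned matrix records the rule it satisfies.

## The synthetic cohort generator

No patient-level data from the study are deposited, so the generator
stands in for them. It emulates:

* **Case mix** — diagnosis drawn from the published per-cohort counts
  (shipped configs `uk_development` n = 422, `uk_validation` n = 208,
  `australian_2009` n = 581, transcribed from the published distribution
  table and normalised at load).
* **Reference labelling** — a suspicious flag drawn per diagnosis.
  Melanoma, lentigo maligna and basal cell carcinoma are always
  suspicious; the small benign rates (≤ 0.1) are free parameters chosen
  once so the expected suspicious counts match the reported 24, 6 and 52.
  Reference tier is histopathology for the three malignant diagnoses,
  in-person expert review for other suspicious lesions, image review
  otherwise.
* **Features** — each of the eight SIAscopic features and seven checklist
  items is Bernoulli given diagnosis, independently. Conditional
  independence is a deliberate simplification: no joint feature
  distribution is published, and marginal calibration to the published
  operating characteristics is the only testable constraint. The only
  profile value anchored to a published number is
  P(dermal melanin | seborrhoeic keratosis) = 55/101 ≈ 0.545, the reported
  misclassification rate; all other profile entries are free, documented
  parameters in the YAML configs.
* **Covariates** — log-normal diameters per diagnosis (medians ~4.5 mm for
  naevi up to ~10 mm for lentigo maligna), rounded to 0.1 mm as a
  measurement would be; integer ages, normal with the published cohort
  means (44.9 / 50 years, SD 15) truncated at 18 (adult recruitment).

All randomness flows from the single config seed.

## Calibration

Two scalar knobs multiply the melanoma-associated feature probabilities
(the four MSS features plus blood vessels): `suspicious_feature_rate` for
reference-suspicious lesions and `benign_feature_rate` for
reference-benign ones, clamped to [0, 1]. Because the suspicious label is
drawn independently of the knobs, PCSA sensitivity depends only on the
first and specificity only on the second, so calibration is two separable
one-dimensional bisections; each objective is monotone in its knob.

`calibrate_profiles` offers two objective estimators:

* **analytic** (default): the exact expected sensitivity and specificity
  under the generative model, obtained by convolving the weighted
  Bernoulli score distribution within every diagnosis-by-suspicious
  stratum (including the exact gate-escape probability and closed-form
  size/age term probabilities that account for diameter rounding and
  integer ages). This objective is smooth and free of Monte-Carlo error.
* **empirical**: a single common-random-numbers cohort of `n_calibration`
  lesions drawn from the config seed, whose stored uniform draws are
  re-thresholded at each candidate rate — deterministic and monotone in
  the knob, at the cost of the cohort's own sampling error in the
  calibrated knob (~0.024 on sensitivity at n = 5,000).

Bisection stops when the objective is within `tolerance` (default 0.005)
of the target; an unreachable target warns and returns the best value
found, with the full evaluation trace attached as an attribute.

**What recovery can and cannot show.** With the Australian targets
(sensitivity 0.44, specificity 0.95), a calibrated config evaluated on a
fresh 5,000-lesion cohort reproduces specificity to about ±0.006 (the
benign denominator is ~4,500). Sensitivity, however, is estimated from
only ~450 suspicious lesions, a binomial SE of ~0.024: deviations of
0.02–0.05 on a single fresh cohort are ordinary sampling noise, as the
analytic expectation (0.440 after calibration) and a 200,000-lesion check
(0.4375) confirm. Any acceptance band tighter than roughly three times
that SE will fail for a non-trivial fraction of seeds even though the
generator is exactly calibrated in expectation.

## Problem sizes and numerical choices

The test suite uses: 10,000 random records for the dot-product score
oracle; 1,000 random score/label sets (n ≤ 200) for the exact
AUC/Mann–Whitney identity; 2,000 replicates for the z-test size check;
50,000 lesions for prevalence recovery and 20,000 for the
analytic-vs-simulation agreement check — sizes chosen so each check's
Monte-Carlo error is well below the property it asserts, while the whole
suite runs in well under a minute. Tie-breaks and degenerate inputs are
pinned by tests: both-gate lesions resolve to haemangioma; ROC requires at
least one positive and one negative after the gating policy; equal AUCs
short-circuit the z-test to z = 0, p = 1 before the variance term (which
errors if `r` is too large for the supplied SEs); reconstruction returns
an empty, well-formed result for inconsistent inputs.

## Limitations

* Features are independent given diagnosis; real SIAscopic features
  co-occur (e.g. blush with displacement), so the generator should not be
  used to study feature-interaction effects, and passing calibration tests
  demonstrates marginal, not joint, realism.
* Lesions are independent; the real studies had multiple lesions per
  patient.
* The published AUC comparison on the histology subset (0.83 vs 0.61,
  p = 0.02, n = 111) is not reproducible without the undeposited patient
  data; the machinery is instead validated by closed-form collapse points,
  oracle identities and simulation size checks. The published AUC
  confidence intervals are likewise not recomputable from the stated
  group sizes by the Hanley–McNeil formula, and are not used as checks.
* Expert feature scoring is taken as given: the package models decisions
  from features, not inter-rater variability or image reading.
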
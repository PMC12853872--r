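---
title: "The anatomical breast burden model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The anatomical breast burden model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abburden)
```

## The scoring model

The anatomical breast burden (ABB) score quantifies the burden of breast
hypertrophy on a 0–6 scale from three domains: anatomical measurements (up
to 4 points), patient-reported symptoms (1 point), and physical findings
(1 point). Each anatomical criterion is binary and inclusive:

| criterion | cutoff | units | rationale |
|---|---|---|---|
| sternal notch-to-nipple (SN-N) | ≥ 26 | cm | vertical pole / nipple descent surrogate; deliberately lenient because severe ptosis carries its own point |
| nipple-to-inframammary fold (N-IMF) | ≥ 14 | cm | lower-pole length; group means cross the 500 g landmark here |
| base width (BW) | ≥ 16 | cm | horizontal footprint; same transition logic |
| Regnault ptosis grade | = 3 | ordinal 0–3 | only severe ptosis scores, by strict equality |

All four cutoffs and the domain point weights are configurable through
`abb_cutoffs()` for sensitivity analyses; the defaults above are the
rubric's published values. A charted grade "2-3" is represented as the
interpolated 2.5 and — deliberately — does **not** earn the ptosis point,
since the rubric's weighting is binary on grade 3.

Scoring is per patient, not per breast. For bilateral reductions the *index
breast* is the one with the heavier resection weight; averaging the two
weights would understate the burden of asymmetric patients, whose heavier
breast drives symptoms. Equal weights are broken deterministically (left,
then right) — a convention for reproducibility; measured weights in grams
essentially never tie.

The symptom and finding domains support three-valued logic: `TRUE`,
`FALSE`, or unknown (`NA`). By default unknown status is assumed present
(`assume_symptom = TRUE`, `assume_finding = TRUE`), which mirrors how the
rubric is applied to retrospective functional-reduction cohorts, where
every patient underwent surgery for symptomatic hypertrophy but symptom
documentation is inconsistent. An explicit `FALSE` always overrides the
assumption, and disabling the assumption makes unknown status a hard error
rather than a silent zero. The assumption adds two points to every
unknown-status patient, so reports echo these flags prominently.

Scores 0–2 are categorized *mild*, 3–6 *moderate-to-severe*. Per-score
verbal labels ("very severe", "mild-to-moderate") vary across
presentations of such rubrics and are not encoded; the binary
categorization is what the concordance analysis uses.

## The Schnur comparison

Body surface area is always computed from height and weight with the DuBois
formula, `0.007184 · height_cm^0.725 · weight_kg^0.425` — never ingested —
so its provenance is single-sourced. The same applies to BMI.

The sliding scale itself is shipped as *data*
(`inst/extdata/schnur_scale.csv`: BSA 1.35–2.50 m² on a regular 0.05 grid,
thresholds 199–1522 g), because it is an external published table, not part
of this model. Loading validates the schema, the regular strictly
increasing grid, and strictly increasing thresholds, and the test suite
pins eleven landmark threshold values so transcription drift fails loudly.

How a non-grid BSA is matched to a row is not standardized; the package
default is `nearest` (halves round up), with `floor`, `ceil`, and `linear`
interpolation available and recorded in the output. All policies are
monotone non-decreasing, and on exact grid values all four agree. Under
`nearest`, BSA may extend half a grid step below the table's minimum;
anything outside the resolvable range is a hard error naming the range,
not a clamp — silent extrapolation of an insurance threshold would be
worse than failure.

The mismatch weight is `actual resection − threshold`; eligibility is
`mismatch ≥ 0`. A mismatch of exactly zero counts as eligible (the
threshold is framed as a minimum to be met) and is reported via message
when it occurs. Bilateral eligibility uses the index breast, consistent
with the scoring rule; `resection = "average"` is exposed for sensitivity
analyses.

## Cutoff derivation

`cutoff_scan()` reproduces the procedure that produced the anatomical
cutoffs: for each integer candidate `c` from `floor(min) + 1` to
`ceiling(max)` of the observed metric, the cohort is partitioned into
`{value < c}` and `{value ≥ c}` on the index breast and each group's mean
resection weight and mean ptosis grade computed. Empty groups yield `NA`
means with an explicit defined-flag rather than being dropped, so the scan
output always spans the full candidate grid.

The published selection logic is narrative; `select_cutoff()` formalizes it
as a smallest-candidate rule with every constant exposed: select the
smallest candidate whose below-group mean weight is under the landmark
(default 500 g), whose above-group mean is at or over it, and whose
above-group mean ptosis has entered the moderate-to-severe band (default
≥ 2.5; the 2.5–3.0 band's upper anchor is carried for reporting). The
ptosis condition is tested on the above-group only, which is the group the
narrative describes as reaching severity. For SN-N a lenient variant
substitutes a reduced landmark (default 350 g): SN-N doubles as a ptosis
surrogate and severe ptosis already carries a point, so a strict SN-N
cutoff would double-count nipple descent. When several candidates qualify
the smallest wins (leniency again); when none does, a structured
no-transition result is returned instead of a silent default. Where the
weight and ptosis transitions genuinely conflict, the conjunction rule is
one faithful reading of the published procedure; the constants are
configurable precisely so that judgment call is auditable.

## The synthetic cohort generator

No patient-level data from the derivation cohort are available, so the
generator emulates its statistical structure:

- **Marginals.** Age, height, weight, SN-N, N-IMF and BW are truncated
  normals with targets (mean, sd, min, max) taken from the cohort's
  printed summaries (e.g. SN-N 30.5 ± 4.04 cm on [22.5, 40]). The
  underlying normal parameters are *moment-matched* numerically
  (`optim` on the truncated-moment equations) so the truncated mean and sd
  hit the targets despite truncation.
- **Dependence.** A Gaussian copula links the six variables plus a latent
  ptosis-severity score. Pairwise correlations among the raw measurements
  are not published — only each variable's correlation with the two scores
  — so the default latent correlations (0.4–0.6 among breast metrics, 0.6
  between SN-N and severity, weaker links to body size) are calibration
  choices that produce a correlation panel qualitatively ordered like the
  published one. They are explicitly not reproductions.
- **Ptosis.** The grade is cut from the severity latent at the exact
  category probabilities (2% grade 1, 31% grade 2, 10% grade 2.5, 57%
  grade 3), so the marginal frequencies are honoured while ptosis
  co-varies positively with the measurements — which is what makes the
  scan's ptosis-transition pattern reproducible in synthetic data.
- **Resection weight.** Linear in (SN-N, N-IMF, BW, ptosis) plus Gaussian
  noise, floored at 50 g. Slopes (12, 30, 25 g/cm and 80 g/grade) were set
  once from the scale of the published between-group weight differences;
  the intercept (−932.5 g) and noise sd (123 g) were then calibrated with
  one large Monte-Carlo draw so the per-breast weight comes out near
  452 ± 211 g, and frozen. The floor binds for roughly 3% of breasts and
  shifts the mean by about +2 g, inside the calibration tolerance.
- **Asymmetry and laterality.** Per-breast values are the patient-level
  value plus Gaussian asymmetry noise (0.3 cm for lengths, 40 g for
  weights), clamped to the marginal bounds; 5% of patients are unilateral
  (a realistic minority share; the source cohort's split is not printed).
  Symptom and finding flags are generated `TRUE`, matching the assumption
  under which such cohorts are scored.
- **BMI** emerges from height and weight rather than being enforced; a
  warning fires if a generated cohort strays grossly outside the 18.8–40.4
  reference range.

`planted_cutoff_spec()` swaps the weight model for a step function:
expected weight `base_weight` (350 g) below the planted cutoff `k` and
`base_weight + gap` (550 g) at or above it, noise sd 50 g, so the group
expectations straddle the 500 g landmark by construction and the derivation
should recover `k`. Two numerical subtleties matter here. First, the
derivation scans the *index* breast, and the maximum of two independently
noisy per-breast weights sits above the patient-level expectation by about
`asym_sd/√π`; planted specs therefore zero the weight asymmetry so the
step expectations hold exactly for the scanned quantity. Second, the
smallest-candidate rule means a long plateau of qualifying candidates would
bias recovery low, so the planted step is sharp (the above-group mean
crosses 500 g only within a grid step of `k`). Degenerate plants (a gap
that never reaches the landmark, or small relative to the noise) warn that
recovery is not guaranteed.

**What passing tests do and do not show.** The generator reproduces
marginal summaries, category frequencies, and a plausible dependence
structure. It does not model measurement rounding by surgeons, multi-site
or multi-surgeon heterogeneity, missing-data mechanisms, or symptom
heterogeneity by age. Pipeline results on synthetic cohorts therefore
validate the *code* and the *procedure* (e.g. planted-parameter recovery),
not the clinical performance of the rubric on real patients.

## Statistical conventions

- Spearman correlations use average-rank tie handling; two-tailed p-values
  use the t approximation on n − 2 degrees of freedom, a standard choice
  at cohort sizes in the tens to hundreds (the method behind published
  panels of this kind is rarely stated). Constant variables yield an
  `NA` rho with a defined-flag rather than an error.
- Sensitivity is `TP/(TP+FN)` and specificity `TN/(TN+FP)` with
  moderate-to-severe ABB as the condition and Schnur eligibility as the
  test; degenerate margins flag the statistic undefined instead of
  dividing by zero.
- Stratified summaries report the sample (n − 1) standard deviation, the
  conventional descriptive choice; single-patient strata have `NA` SD and
  empty strata are emitted with n = 0.
- Percentages are exact fractions internally; display rounding (one
  decimal for rates, integers for grams) happens only at the formatting
  layer.

## Problem sizes and reproducibility

The validation suite exercises brute-force oracle equivalence of the scan
and the correlation panel on 200 random cohorts of up to 30 patients,
planted-cutoff recovery on 100 seeded cohorts of n = 84 (50 each for N-IMF
k = 14 and BW k = 16, requiring ≥ 90% recovery within ±1 cm), and marginal
fidelity on an n = 5000 cohort within three standard errors of every
target. The generator is deterministic given its spec: it seeds a local
RNG stream and restores the caller's state, and `write_cohort()` output is
byte-identical across repeated runs — these properties are tested, not
assumed.

## Known limitations

- The interpolated ptosis grade 2.5 is not part of the formal Regnault
  system; it exists to represent real-world charting ("Grade 2-3") without
  discarding records.
- Whether a grade-0-ptosis breast can plausibly meet the other cutoffs is
  untested territory (derivation cohorts contain none); no extra validation
  is imposed.
- The rubric is a burden-quantification tool, not a diagnostic instrument
  for macromastia or gigantomastia, and encodes no surgical-technique or
  nipple-position logic.
- Patients who meet no measurement cutoff yet have large resections and
  severe symptoms exist; a 0–6 rubric cannot resolve such cases and they
  require individual adjudication.
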
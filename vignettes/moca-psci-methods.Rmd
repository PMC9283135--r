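---
title: "Methods: demographically adjusted MoCA and prediction of post-stroke cognitive impairment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographically adjusted MoCA and PSCI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocapsci)
```

## The problem

After an acute stroke or TIA, a large fraction of patients develop persistent
post-stroke cognitive impairment (PSCI), defined at 6–9 months by an
extensive neuropsychological battery (MCI if there is at least one impaired
test, dementia if cognitively driven functional dependence is added). A
bedside screening instrument administered during the stroke-unit stay should
identify the patients at risk. The MoCA is the usual candidate, but its raw
total confounds cognitive status with age and education, and the available
Italian normative datasets disagree both in their adjustment equations and in
their impairment thresholds. `mocapsci` implements the comparison of those
normative systems as predictors of PSCI and the derivation of a purpose-built
predictive cut-off.

## Demographic adjustment and classification

Each normative dataset contributes an additive correction of the raw total
(0–30) in age and education; the three equations are reproduced verbatim in
`?moca_norms` and stored as a JSON resource so the constants are auditable.
All three have the same structure, raw + a·(f(age) − c_age) + b·(g(edu) −
c_edu), so each returns exactly the raw score at its centering demographics;
the test suite asserts those fixed points to 1e−9 and equivalence with
independently written one-line evaluations to 1e−12.

Classification is *impaired* iff the adjusted value lies **strictly below**
the ES = 0 cut-off (a score below the outer tolerance limit of the normal
population's 5th centile). Ties at the cut-off are normal: the cut-off is the
last value still compatible with normality. Only the impaired/normal
dichotomy is implemented — the ES 1–4 band boundaries are not published with
the equations, so a full five-level equivalent-score grading is not
reproducible from the available constants.

Numerical edge cases are clamped rather than rejected, with a flag and a
warning, because the cohort inclusion criteria admit demographics where the
equations are undefined:

* education < 1 year → clamped to `min_education` (default 1 year; `1/edu`
  and `ln(edu)` are undefined at 0). The clamp is applied uniformly across
  datasets so classifications stay comparable.
* age ≥ 100 → clamped to 99 for the Santangelo equation
  (`log10(100 − age)`).
* ages outside a dataset's normative range (notably < 60 for Conti, whose
  norms cover ages 60–80) are evaluated anyway but flagged `extrapolated`;
  applying the equations across the full adult age span is exactly how the
  norms are used in acute-stroke practice, and the flag surfaces the caveat.

Adjusted values are deliberately **not** truncated to [0, 30]: the
corrections are additive, and truncation would create artificial ties that
distort downstream ROC ordering. Reports render adjusted scores at two
decimals; full precision is kept internally.

## Outcome adjudication

`adjudicate_psci()` encodes the diagnostic algorithm: no impaired test →
`none`; at least one impaired test plus ADL **or** IADL dependence not
attributable to motor/sensory sequelae (or other non-cognitive disease) →
`dementia`; any other cognitively impaired patient → `mci`. The package
consumes pre-computed per-test impairment booleans and dependence booleans —
the instrument-level thresholds that define "dependent" on the ADL/IADL
scales, and the per-test norming, are upstream of this package and are not
graded more finely than a boolean because no finer granularity is defined for
them here. The modified Rankin scale is carried as descriptive metadata only.
Patients with no usable test results are excluded from the analyzable set
with a message.

## Diagnostic accuracy and the risk model

Accuracy of a normative threshold is evaluated on the followed-up patients by
the 2×2 table of baseline impaired/normal against PSCI. Indices with a zero
denominator are reported as undefined (`NA`), never coerced to 0 or 1.
Percentages are rendered with **half-up rounding** (`round_half_up()`), which
is the convention that reproduces published accuracy cells from their counts
(e.g. 46.75 → 47, 97.56 → 98); base R's banker's rounding does not.

Association tests are Pearson chi-square **without** continuity correction
(the correction is selectable; uncorrected matches the common default at
these sample sizes), and group comparisons of continuous baselines use the
pooled-variance Student t-test (Welch selectable — the choice is
inconsequential at the cohort's variance ratios but pooled is the
conventional default in this literature).

The risk model is a univariate logistic regression of PSCI on the adjusted
score, fitted by Fisher-scoring IRLS (`glm`, tolerance 1e−8, ≤ 100
iterations). Because lower scores mean higher risk, the coefficient β (per
point gained) is reported as OR = exp(−β) per point **lost**, with the Wald
95% CI transformed the same way; storing β and exposing the inversion avoids
sign confusion. Complete separation is detected directly — in a univariate
model the MLE diverges exactly when the two classes' score ranges do not
overlap — and additionally by |β| > 50 or IRLS non-convergence; such fits are
flagged `converged = FALSE` rather than silently reported. The test suite
cross-checks the fit against a zooming grid-search maximiser of the
log-likelihood on small datasets (agreement to 1e−4).

## ROC analysis and cut-off selection

Candidate thresholds are the midpoints between consecutive distinct observed
adjusted values, plus sentinels one point below the minimum and above the
maximum, so every curve contains the degenerate (Se = 1, Sp = 0) and (Se = 0,
Sp = 1) endpoints. Midpoints are why optimal cut-offs are typically
non-observable values landing between two patients' scores. The test-positive
orientation is `adjusted < threshold`. The AUC is the trapezoid over
(1 − Sp, Se), which for this construction is exactly the Mann–Whitney
concordance P(score_case < score_control) + ½·P(tie); the suite asserts the
identity to 1e−12 on a thousand random instances and against an independent
ROC implementation (`pROC`).

The optimal predictive cut-off maximises Youden's J = Se + Sp − 1 **subject
to** the screening adequacy rule Se ≥ 0.80 and Sp ≥ 0.60. Constrained
maximisation is a design choice — the adequacy rule is the stated requirement
for an acute-stroke screening tool, and an unconstrained Youden maximum can
satisfy neither bound. Ties in J are broken towards higher sensitivity
(missing PSCI is the costlier error in screening) and then towards the lower
threshold. If no threshold is adequate, the global Youden maximiser is
returned with `adequate = FALSE` so the caller sees both the best achievable
trade-off and the failure of the adequacy criterion. No bootstrap CI is
attached to the AUC by default; a seeded percentile bootstrap is available
(`auc_bootstrap_ci()`).

## What the synthetic cohort emulates

Since the motivating cohort is not publicly released, `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes, with
defaults fixed at the cohort's published description: n = 207; age 76 ± 9.6
years (truncated to [45, 95]); education 9.1 ± 4.5 years (truncated [1, 21],
integer); 34% female; event mix 6% TIA / 84% ischemic / 10% hemorrhagic;
NIHSS 2.1 ± 3.1; raw MoCA 17.1 ± 6.9 (truncated [0, 30], integer); 57%
follow-up at 7.4 ± 1.7 months; 65% PSCI prevalence among the followed-up with
P(dementia | PSCI) = 22/77; and an odds ratio of 1.39 per adjusted point
lost. Truncated normals are drawn by rejection sampling; rounding to integers
happens after truncation. The RNG algorithm is pinned in the config metadata
(Mersenne-Twister) so seed determinism is auditable.

Structure: a single latent cognitive ability links demographics to the raw
MoCA (loadings −0.35 on standardised age and +0.25 on standardised education
— the cohort's age/education–MoCA correlations are not published, so a
moderate value was fixed once and documented as unanchored). Drop-out is a
logistic model in age and raw MoCA (−0.035 log-odds per year, +0.05 per
point, sized so the retained/dropped gaps approximate the published 3-year
and 2.3-point selection gaps), and PSCI is a logistic model in the
Aiello-adjusted baseline score with slope −ln(1.39). Both intercepts are
calibrated by bisection on the realized cohort (tolerance 1e−4 on the
expected proportion), so the marginal rates hit their targets regardless of
the covariate draws. Per-test impairment flags are thresholded noisy copies
of the latent ability, coerced consistent with the drawn PSCI status, so
adjudication round-trips the generated labels exactly; a share of MCI
patients (default 0.15) carries dependence marked as motor/sensory, which
adjudication must not count as dementia. Follow-up intervals are truncated to
[3, 15] months.

What the generator does **not** emulate: lesion location and stroke-subtype
effects on cognition, centre effects beyond a label, per-domain impairment
profiles, measurement error in the baseline MoCA itself, and any
non-logistic dose–response of risk in the score. Passing tests therefore
show that the pipeline is correct and well calibrated under a plausible
generative model — not that the published patient-level values (group means,
AUCs of 0.80–0.83, the 22.82 cut-off) are recovered, which would require the
unreleased data. The published quantities that *are* exactly reproducible —
the printed contingency tables, their accuracy cells, and the cohort
proportions — are reproduced cell-for-cell from their counts.

## Problem sizes and numerical tolerances in the test suite

Property tests run at n = 10⁴ random inputs for equation–oracle equivalence
(1e−12), 1000 random ROC instances at n ≤ 50 for the AUC–concordance
identity (1e−12), 100 seeded replicates at n = 2000 for Wald coverage of the
generative odds ratio (≥ 90/100 required), and a single n = 4000 cohort for
the qualitative accuracy pattern (normative thresholds: high specificity, low
sensitivity; ROC cut-off: adequate). These sizes give stable Monte-Carlo
verdicts while keeping the default suite fast.

## Known limitations

* Only the ES = 0 dichotomy is implemented; borderline (ES = 1) rates cannot
  be derived from the published constants.
* The per-test norming of the follow-up battery and the ADL/IADL dependence
  thresholds are consumed as booleans, not computed.
* The choice "maximise Youden subject to adequacy" is a reasoned
  reconstruction of how optimal rows are flagged in threshold tables of this
  kind; other optimality criteria (e.g. cost-weighted) are out of scope.
* The logistic risk model is univariate by design; confounder-adjusted risk
  modelling is not implemented.
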
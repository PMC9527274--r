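---
title: "Methods: ECG criteria for outflow-tract PVC origin and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG criteria for outflow-tract PVC origin and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvcorigin)
```

## The clinical problem

Idiopathic premature ventricular contractions (PVCs) most often arise in
the ventricular outflow tracts. When the V1 complex shows a
left-bundle-branch-block (LBBB) pattern with tall R waves in II, III and
aVF, the differential is essentially between the septal right ventricular
outflow tract (s-RVOT) and the aortic sinus cusp region of the left
ventricular outflow tract (LVOT-ASC) — anatomically adjacent structures
with nearly identical surface ECGs but different ablation access routes.
The package computes amplitude-based discrimination criteria from measured
Q/R/S wave amplitudes of one PVC beat (and optionally one paired sinus
beat) per patient, and evaluates them with ROC methodology.

It deliberately consumes *measured amplitudes*, not waveforms: no QRS
detection or delineation is attempted, matching how such measurements are
made in practice (calipers on a standard 25 mm/s recording).

## Measurement conventions

* **Units.** Amplitudes are stored as dimensionless "au", the unit of the
  shipped calibration tables. Values such as an R wave of 17 in lead II
  are physiologically consistent with 0.1 mV units (millimetres at
  10 mm/mV), not whole millivolts; because every cutoff (20.9, 15.7, 1.44,
  …) is expressed in the same unit, the system is internally consistent
  whichever physical reading is correct.
* **Magnitudes, not signed voltages.** Q, R and S amplitudes are
  non-negative; polarity is carried by the field. A monophasic negative
  (QS) complex is recorded entirely under `s_amp` with `q_amp = r_amp = 0`
  — this matches calibration tables in which V1 Q medians are 0 while S
  amplitudes are large, and it keeps "S-wave" indices (V1S in the R-S
  difference index) well defined for QS complexes.
* **Missing sinus beats** are permitted; the two sinus-dependent indices
  return a "not computable" value rather than failing the cohort.
* **Transition lead**: first of V1..V6 with R/S > 1, strict at a tie;
  a monophasic R (S = 0, R > 0) counts as past transition; flat leads are
  skipped. These choices are required for the calibration-table median
  beats to land on the expected modal transitions (V4 for s-RVOT, V3 for
  LVOT-ASC).

## Criterion evaluation

Each criterion applies its printed inequality exactly: strict `>` for
"greater" criteria, inclusive `≤` for "less-or-equal" ones, with the
boundary on the non-positive side. ROC curves sweep the cutoff over the
observed score values (plus infinite anchors) under the same strict-`>`
rule, so the reported Youden-optimal cutoff is always an observed score
and the operating point it reports is exactly the one its decision rule
realizes on the data — the package treats this consistency as
non-negotiable, and resolves the classic ambiguity between "≥ observed
value" and "> observed value" ROC conventions in favour of the printed
`>` semantics. A midpoint reporting convention
(`cutoff_mode = "midpoint"`) is available; it shifts the reported number
into the open interval between adjacent observed scores without changing
any classification.

Youden ties (equal J) are broken toward **higher specificity**, then the
lower cutoff. Clinically this favours avoiding a false LVOT-ASC call,
i.e. unnecessary retrograde arterial access. AUC is computed three
mutually checking ways in the test suite — midrank statistic, trapezoid
under the empirical curve, brute-force pair counting — and the first two
are the production paths (`auc_mann_whitney()`, `roc_curve()`).

The "joint model" of the four R-S amplitudes is reported in both readings
because the phrase is genuinely ambiguous: (a) the fixed-weight index
`V2R + V3R + V4R − V1S` (weights +1, +1, +1, −1), and (b) a logistic
regression of origin on the four amplitudes fitted by IRLS
(`stats::glm.fit`), ROC-evaluated through its linear predictor. Complete
separation is detected (fitted probabilities collapsing to 0/1) and
flagged as non-convergence; rank-deficient designs are rejected outright.

Group statistics follow reporting style: median (quartiles) with the
Mann-Whitney rank-sum test for skewed measurements, mean ± SD with the
t-test for approximately normal covariates, Pearson chi-square (df = 1,
no Yates correction — the gender-table conclusion is unchanged either
way) for counts. The rank-sum test enumerates the exact null only for
combined samples of at most 12 without ties, otherwise it uses the
normal approximation with tie-corrected variance and continuity
correction. Quartiles use linear interpolation between order statistics
(type 7), the common package default; the original tables' convention is
unstated, which is one reason tests compare distributions by tolerance
rather than digit-for-digit. No multiple-testing adjustment is applied
anywhere, matching the descriptive use of these p-values.

## The synthetic cohort generator

Patient-level data for this discrimination problem are not publicly
available; the package therefore ships a generator whose *marginal*
amplitude distributions are calibrated to the published per-lead
median (Q1, Q3) tables for the two groups (n = 183 s-RVOT, n = 76
LVOT-ASC), stored as plain CSV in `inst/extdata/`.

**Family.** Each (group, lead, wave) amplitude is zero-inflated
log-normal (ZILN): a point mass at zero with probability `pi_zero`, else
log-normal(mu, sigma). The family is the simplest one that expresses the
three dominant features of these columns — non-negativity, strong right
skew (medians well below Q3), and exact zeros wherever a wave is
structurally absent in part of the cohort.

**Fitting from three quartiles** (`fit_ziln_from_quartiles()`) branches
on the zero pattern:

* all quartiles positive: `pi_zero = 0`, `mu = log(q50)` (median matched
  *exactly*), `sigma` the average of the two one-sided estimates
  `log(q75/q50)/z` and `log(q50/q25)/z`, `z = qnorm(0.75)`. A
  two-parameter log-normal cannot match an asymmetric log-scale triple;
  the averaged sigma is the least-squares compromise, and for the most
  asymmetric cell (V3 R in LVOT-ASC: 9.53/12.55/19.53) it places the
  model's outer quartiles about 8% inside the printed ones. Medians are
  always exact, which is why the acceptance checks target medians.
* `q25 = 0 < q50`: the zero mass is only known to lie in [0.25, 0.5);
  fixed at `pi_zero = 0.3` (interior, configurable by editing the
  parameter table), and mu, sigma solved exactly from the two positive
  quantile equations after rescaling to the positive part.
* `q50 = 0 < q75`: `pi_zero = 0.6`, `sigma = 0.5` by convention, mu from
  the single positive quantile.
* all zero: a trace-wave model, `pi_zero = 0.95`, median ~0.1 au — small
  deflections at the measurement floor rather than a hard structural
  zero.

**Dependence.** The tables publish only marginals. Records are drawn by
pushing a latent standard-normal vector with *exchangeable* correlation
`rho` (default 0.3, configurable in [0, 0.9]) through each feature's
quantile function — a Gaussian copula, so marginals are exact for any
`rho`. Real inter-lead dependence is certainly not exchangeable, and this
is the main reason the generator's discrimination performance (e.g. an
R-S index AUC near 0.94 at `rho = 0.3`) should not be read as an estimate
of the real-data AUC (reported near 0.87): the synthetic cohorts are a
test bed for the *machinery*, calibrated per lead, not a model of joint
ECG physiology. Passing tests show the indices, statistics and ROC code
are correct and that the marginal calibration is faithful — not that the
package reproduces clinical operating characteristics.

**Sinus template.** No sinus-beat measurement table was published. The
shipped sinus model (`sinus_template_synthetic.csv`, flagged synthetic in
the filename) is a textbook normal-conduction precordial progression so
that the two sinus-dependent transition-ratio indices are exercisable;
conclusions about those two indices on synthetic data inherit this
convention.

**Durations** are quantile-matched normals rounded to a 4 ms grid (the
granularity of common ECG sampling), floored at 0. **Gender** is
Bernoulli at the published group proportions (54/183, 41/76 male).
**Seeding**: one integer seed; the stream is split per record (and group)
with fixed per-record draw order, so enlarging one group never reshuffles
the records of either group, and identical configurations reproduce
byte-identical cohort files.

## Problem sizes in the tests

The suite exercises full-cohort runs at the study sizes (183 + 76),
marginal-recovery checks at 200,000 draws per amplitude cell (all 72
cells), and oracle comparisons on a few hundred randomized small datasets
(n ≤ 200) per property — sizes chosen so the whole suite completes in
well under a minute of compute per module while keeping Monte-Carlo
tolerances (2–3% on medians) comfortably tight.

## Known limitations

* The generator matches printed Q1/Q3 only in the least-squares sense
  (medians exactly); heavier-tailed or multimodal amplitude columns are
  not representable.
* Exchangeable copula dependence is a convenience, not physiology; AUCs
  on synthetic cohorts are internally consistent but not clinical
  estimates.
* The V1 morphology classifier covers {rS, QS, qrS, Rs, R}; genuinely
  notched or polyphasic complexes fall into `other` rather than being
  guessed.
* Criteria are evaluated in-sample (no cross-validation), matching how
  such cutoffs are reported in the source literature.
* Only gender is simulated among clinical covariates; laboratory and
  echocardiographic variables are summarized when present in real tables
  but not generated.
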
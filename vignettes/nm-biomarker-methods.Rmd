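---
title: "Quantifying substantia-nigra neuromelanin MRI: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying substantia-nigra neuromelanin MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmsn)
```

## The measurement model

Neuromelanin-sensitive T1 turbo-spin-echo imaging shows the substantia
nigra pars compacta (SNpc) as a bilateral hyperintense blob in the midbrain;
loss of dopaminergic neurons in Parkinson's disease (PD) shrinks and dims
it. `nmsn` computes four scalar measurements from a midbrain image plus
manually traced (or simulated) SN and background ROIs:

- **Vol** — SN voxel count on the three most inferior contiguous slices in
  which the SN is visible, times the voxel volume (mm³). Restricting to a
  fixed three-slice window standardizes the measurement against variable
  superior coverage of the slab.
- **C_vol** — Vol divided by total intracranial volume (TIV) in cm³. With
  TIV near 1.4&nbsp;L this puts C_vol on the ~0.2 scale. A fully
  dimensionless ratio would sit near 2×10⁻⁴; the mm³/cm³ convention is the
  one under which the healthy-volunteer values of ~0.19 arise, and is what
  `compute_cvol()` implements.
- **SNR** — mean over the three slices of (mean SN signal / mean background
  signal) × 100. The value 100 is the no-contrast floor, so the
  neuromelanin signal proper is the *excess* SNR − 100 (≈ 12 in healthy
  volunteers on a PRISMA-class acquisition).
- **CNR** — mean over slices of (mean SN − mean background) / background
  SD.

"Visible" means at least `min_voxels` (default 1) SN voxels on the slice;
the inferior end of the slice axis is declared by an `orientation` field
(`"IS"`: index 1 most inferior), never guessed from headers. The background
SD uses the sample (n − 1) estimator by default — conventional for ROI
statistics — with the population form available.

### Percent changes and annualized rates

Group differences and visit-to-visit changes are plain relative changes for
Vol, C_vol and CNR. For SNR they are referenced to the excess:
(SNR₁ − SNR₀)/(SNR₀ − 100) × 100. A raw-ratio SNR change of 2 points on a
base of 112 would read as −1.9% and wildly understate the loss of the
~12-point neuromelanin excess (−17%); the background-referenced convention
is therefore the default, with the raw form behind `snr_referenced = FALSE`.
Annualized rates divide each subject's percent change by their own
inter-visit delay, and the cohort value is the mean of per-subject rates
(not a ratio of group means — either reading is defensible; per-subject
averaging matches how the rates are tested downstream).

## The synthetic cohort generator

No patient data ship with the package; every analysis stage runs against
`generate_cohort()`, whose defaults emulate two study conditions:

- **cohort1** (early PD): 99 PD / 41 HV at baseline, follow-up of both
  groups after 2.0 ± 0.2 years with ~20% dropout; HV volume 273.2 ± 48.4
  mm³, PD deficit 11.2%; HV SNR 112.1 ± 1.6 with the PD deficit (17.4%)
  applied on the excess scale; HV CNR 1.56 ± 0.23, PD deficit ~20%; annual
  rates −5.8 (Vol), +1.5 (SNR excess), +1.9 (CNR) %/yr in PD versus 0.4,
  0.8, 3.9 in HV; male fractions 66/99 and 17/41.
- **cohort2** (progressing PD): 41 PD / 23 HV, PD-only follow-up after
  2.4 ± 0.5 years; volume deficit 38.4%; rates −10.2 (Vol), −3.7 (SNR),
  −3.0 (CNR) %/yr.

Sex-specific TIV (women ~1370, men ~1510 cm³) makes C_vol larger in women
at equal Vol, reproducing the observed sex effect without touching the
volume distributions. C_vol itself is never generated: it is Vol/TIV by
construction, which is why its deficits and rates track Vol. Motor severity
(MDS-UPDRS-III OFF, 30.3 ± 7.9 in early PD) is built against the
standardized baseline C_vol by the bivariate-normal construction
`u = μ + σ(ρ z + √(1−ρ²) ε)` with ρ = −0.4 by default, so the programmed
correlation is exact in population; LEDD is drawn independently of all
imaging variables as a negative control.

Between-subject variability of the annualized rates (`rate_sd`, per
measure) is 4 (Vol), 2.5 (SNR), 3 (CNR) %/yr. These are calibrated so that
the per-arm trial sizes implied by the standard two-arm formula land on the
reported scale for this class of study — on the order of 10² patients per
arm for volume endpoints and 10²–10³ for signal-intensity endpoints at a
30% effect — rather than chosen freely; they are the single most
consequential generator constants for the power stage.

The phantom (`generate_phantom()`) is deliberately minimal: Gaussian noise
on a uniform tegmentum-like background, two blob-shaped SN regions built by
taking exact per-slice voxel counts nearest an anteroposteriorly elongated
centre (so the realized volume matches its target to within one voxel), a
rectangular dorsal background ROI disjoint by construction, and SN
intensity `bnd_mean × SNR/100`. Gaussian (not Rician) noise keeps every
estimator analytic and is accurate for high-SNR magnitude images; the
default 96×96×12 grid is a reduced field of view at the true
0.4 × 0.4 × 3 mm voxel size. What the phantom does **not** emulate —
B0/B1 inhomogeneity, partial-volume gradients at the SN border, motion,
slice cross-talk, anatomy — bounds what passing tests show: they validate
the measurement and statistical machinery, not robustness to real-scanner
artefacts. Rater variability is emulated by toggling boundary voxels
(6-connectivity) with a set probability, which by construction lowers Dice
monotonically while leaving interior voxels alone.

## The statistical program

All factorial models use Type-III sums of squares with sum-to-zero factor
coding and a centred age covariate — the conventional reporting choice with
unbalanced cells; the multivariate family (the four measures) is fitted as
per-measure univariate models.

The two-visit mixed design is computed by the exact decomposition available
when the within factor has two levels: between-subject terms are tested on
subject means across visits, visit and its interactions on the V2 − V1
differences (the visit main effect is the intercept test of the difference
stratum, which is why the covariate must be centred). This reproduces the
classical mixed-ANOVA F tests exactly on balanced data — the test suite
checks it against `aov(y ~ ... + Error(subject))` on a balanced 2×2×2 toy
— and keeps every null distribution exact, which the type-I-error
calibration suite verifies at α = 0.05.

Other choices worth stating:

- **ICC**: form ICC(2,1) — two-way random effects, absolute agreement,
  single rater — so systematic offsets between examiners count against
  agreement; ICC(3,1) is behind a flag. Computed from the two-way mean
  squares directly.
- **ROC**: midrank (Mann-Whitney) AUC; because PD lowers SN measurements,
  scores are auto-flipped to keep AUC ≥ 0.5 with the flip disclosed.
- **Permutation correction**: for each clinical variable, the four
  measurement correlations form one family; clinical values are permuted
  jointly across the family and the max-|r| per permutation builds the
  null, with the add-one estimator (1 + #{max ≥ |r|})/(1 + B). Corrected
  p ≥ raw p holds by construction. Whether the family should instead span
  all clinical variables at once is genuinely open; the per-variable family
  is the more conservative reading of a "measurement family" and is what
  the exhaustive-enumeration oracle tests.
- **Degenerate inputs** error loudly rather than silently: empty background
  on a measurement slice, zero background SD (noiseless CNR), TIV ≤ 0, SNR
  reference at the 100 floor, zero between-subject variance (ICC warns and
  returns ≤ 0), aliased factorial terms.

## Trial sizing

`sample_size_analytic()` implements
n = ⌈2σ²(z₁₋α/₂ + z_power)²/Δ²⌉ per arm for a two-arm comparison of 1-year
changes, with Δ = effect_fraction × the predicted change and σ the SD of
the 1-year change, both calibrated from a cohort via
`calibrate_power_inputs()`. Two Δ references are exposed: the PD − HV rate
difference, and the PD rate alone (`delta_ref = "pd_only"`). The analysis
scripts and acceptance suite use the PD-only reference: for
signal-intensity measures the PD and HV rates are nearly equal, so
difference-referencing makes the detectable effect vanish and the required
arms diverge — whereas the reported magnitudes for this class of endpoint
(hundreds per arm) arise exactly when the effect is a fraction of the
patient change itself. `sample_size_simulated()` is the package's own
oracle: bisection on the Monte-Carlo rejection rate of the pooled t test;
the z-formula ignores the t-distribution correction, so the two agree
within a few percent at moderate n and the suite requires ±15% across the
full grid. Sizing always rounds up.

## Problem sizes used by the tests

The suite favours sizes that make Monte-Carlo error negligible relative to
the tested tolerance while staying lightweight: rate recovery at 500
patients (SE ≈ 0.2 %/yr against a ±0.3 band), interaction detection at the
79/32 follow-up sizes over 100 replicates, type-I calibration at 200
replicates per model family, correlation targets at n = 2000, and
exhaustive permutation enumeration at n = 6 (720 permutations).

## Known limitations

Measurement noise in the fast path (`measure_cohort()`) is additive
Gaussian per measure rather than arising from re-traced masks, so it cannot
model spatially correlated tracing bias. The generator draws baseline Vol,
SNR and CNR independently within subject, although real measurements
correlate through the underlying pathology. Slice selection is performed
per visit independently; matched-slice longitudinal measurement is not
implemented. None of the simulated conditions establish performance on real
multi-site data.
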
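---
title: "Methods: fingerprint, chemometric and single-marker quality control of mugwort leaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint, chemometric and single-marker quality control of mugwort leaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbqc)
```

## The problem

*Artemisiae argyi* Folium (AAF), dried mugwort leaf, is a medicinal and
edible material whose active constituents — chiefly phenylpropanoids
(caffeoylquinic acids, CQAs) and flavonoids — vary with production
region. `herbqc` implements a complete quality-control workflow for such
material:

1. **MS2 annotation** (`annotate()` and friends): rule-based structure
   assignment of CQAs and flavonoids from high-resolution tandem
   spectra.
2. **HPLC-UV fingerprinting** (`detect_peaks()`, `match_peaks()`,
   `similarity()`): an 18-batch x 18-common-peak area matrix built by
   relative-retention-time (RRT) matching against an internal reference
   peak, with cosine similarity as the batch-consistency score.
3. **Chemometric marker screening** (`pca_fit()`, `oplsda()`, `vip()`,
   `s_plot()`, `permutation_test()`, `select_markers()`): which peaks
   drive the regional difference.
4. **QAMS quantification** (`correction_factor()`, `quantify_qams()`,
   `quantify_esm()`): quantify several analytes from one inexpensive
   internal standard via pre-established relative correction factors,
   validated against per-analyte external-standard calibration (ESM).

No raw chromatograms or spectra are publicly deposited for this
material, so the package carries (a) the printed reference tables as
machine-readable fixtures (`aaf_correction_factors()`,
`aaf_relative_retention()`, `aaf_batch_quantification()`) and (b) a
synthetic-data module that generates every input the pipeline needs.

## MS2 fragmentation rules

All mass arithmetic is exact-monoisotopic over CHNOS
(`monoisotopic_mass()`), with singly charged quasi-molecular ions at
M ± 1.007276 Da and a default matching tolerance of 10 ppm —
Orbitrap-class accuracy; the worst deviation among the published
fragment masses we pin in the tests is about 9 ppm.

**CQAs** (negative mode only; ester-bond cleavages are uninformative in
positive mode): the caffeoylation degree n ∈ {1, 2, 3} is established by
the neutral-loss chain `[M-H]⁻ → … → quinate (m/z 191.0561)` through
successive 162.03169 Da caffeoyl losses, with at least one support ion
(caffeate 179.0350, dehydrated quinate 173.0455, or decarboxylated
caffeate 135.0452). Positional isomers are then discriminated by base
peak and relative abundance:

* degree 1 — base peak 173 → cryptochlorogenic acid; base peak 191 with
  the 179 ion at ≥ 20 % → neochlorogenic acid, ≤ 10 % → chlorogenic
  acid (the published worked values are 52.54 % and 1.09 %);
* degree 2 — base peak 191 → 1,5-di-*O*-caffeoylquinic acid; base peak
  353 with the 173 ion at ≥ 35 % → isomer B (44.28 %), 10–35 % →
  isomer C (29.35 %), ≤ 5 % → isomer A (1.26 %);
* degree 3 — one isomer in scope (3,4,5-tricaffeoylquinic acid).

The thresholds are guard-banded around the single published worked
values (at least two-fold separation); an abundance falling into a gap
returns `"ambiguous"` rather than a guess. Nominal anchors ("m/z 179")
are resolved to exact masses with ±0.01 Da windows before abundance
comparison.

**Flavonoids**: *O*-glycosides lose the glycosyl intact (hexosyl
162.0528, deoxyhexosyl 146.0579, rutinosyl 308.1107) and the resulting
aglycone shows retro Diels–Alder (RDA) A-ring ions; *C*-glycosides show
≥ 2 of the 60/90/120 Da sugar cross-ring cleavages (or sums thereof)
and no aglycone RDA reaction; bare aglycones show only RDA ions. The
RDA ion inventory is stored per aglycone class in the rule library
(quercetin-type 1,2A⁻ 178.9986 and its −CO ion; luteolin/apigenin-type
1,3A⁻/0,2A⁻/0,4A⁻) — it is not derived from arbitrary substitution
patterns, so generality beyond these aglycones is out of scope.
Contradictory evidence (both an intact glycosyl loss with RDA support
and ≥ 2 ring cleavages) returns both hypotheses flagged ambiguous.
Positive-mode spectra carry neither RDA nor ring-cleavage ions, so they
are scored against the same full evidence inventory and always score
strictly lower; the annotation score is the fraction of the compound's
negative-mode diagnostic ions matched, with ties broken by mean |ppm|.

One published fragment mass (107.01257, the 0,4A⁻ ion of
luteolin/apigenin) deviates −12 ppm from the only plausible CHNO
composition (C6H4O2 − H, 107.01385); the rule library stores the
theoretical mass and that observation is excluded from the pinned
concordance set.

## Fingerprints

Peak detection assumes the flat baseline the generator guarantees
(estimated as the median intensity): local maxima above a height and a
prominence threshold, bounds at the flanking valley or the 0.1 %-height
baseline crossing, trapezoidal integration on the native grid
(`pracma::trapz`), times in minutes and areas in intensity·min.
Asymmetry is measured as b/a at 10 % height — the pharmacopoeial
convention, consistent with the published 0.98–1.15 range. Resolution is
`2Δt/(w₁+w₂)` with baseline widths 4σ estimated from the half-height
width (σ = FWHM/2.355, Gaussian assumption).

Matching uses RRT against isochlorogenic acid C (peak 11), identified
per batch as the largest-area peak within ±5 % of its expected absolute
retention time (it is abundant in every batch). Each template entry
takes the peak minimising |RRT_obs − RRT_template|, accepted within a
2 % relative tolerance — about twice the largest published RRT
between-condition RSD (1.258 %) — with equidistant ties broken towards
the larger area. Because RRT is a ratio, a uniform retention shift
cancels exactly; this is a tested property.

Similarity is the cosine (congruence) coefficient of common-peak area
vectors against the per-peak mean profile; the national evaluation
system the field uses is unpublished, so cosine is the default with
Pearson correlation as an alternative. No acceptance threshold is
enforced — scores are reported. Note that with genuine regional
contrasts the two region profiles differ, so even noise-free batches sit
at ~0.98 against the *grand* mean while within-region similarity is
exactly 1.

## Chemometrics

Default scaling is autoscaling (centre, unit variance), the common
chemometric default; mean-centring and Pareto are available. PCA is by
SVD with explained fractions σ²ₐ/Σσ² and a 95 % Hotelling T² ellipse for
score plots; it is verified in the tests against a covariance
eigendecomposition oracle at rtol 1e−8.

OPLS-DA fits one predictive component plus `n_orthogonal` (default 1)
orthogonal components: the PLS1 weight vector w ∝ X'y is computed, the
orthogonal part of the loading is split off, its component removed from
X, and the predictive component fitted on the deflated matrix. The
class vector is coded +1/−1 (alphabetically first level +1; for the
region labels this codes HB = +1, HN = −1, which fixes the sign
convention of S-plot covariances) and centred. With zero orthogonal
components the model is *exactly* a one-component PLS1 — verified
against an independent implementation in the tests. R²X and R²Y come
from fitted sums of squares; Q² = 1 − PRESS/TSS uses stratified 7-fold
cross-validation with deterministic fold cycling within each class, so
fits are reproducible without a seed.

VIP over the predictive component is √p·|w| (mean VIP² = 1 exactly, an
algebraic identity we assert at 1e−9). The S-plot pairs each peak's
covariance and correlation with the predictive scores. The permutation
test refits the model on label permutations (default 200), regresses
R²Y and Q² on |cor(y, y_perm)| including the unpermuted point at 1, and
reports the intercepts; a valid model has all permuted Q² below the
original.

Markers are peaks with VIP > 1 **and** two-sided Welch t-test p < 0.05
on the raw (unscaled) areas between regions. p-values are reported raw
— mirroring the usual practice of quoting unadjusted p < 0.05 in this
setting — with Benjamini–Hochberg behind a flag. Whether the original
study's p-values came from a t-test or from proprietary software
internals is unknowable; Welch is the defensible default for unequal
variances.

## QAMS

The relative correction factor is f = (A_s/C_s)/(A_i/C_i); content
conversion uses the extraction stoichiometry (0.2 g in 25 mL, solvent
loss compensated), so mg/g = C(mg/mL) × 125. QAMS concentration is
C_i = f·C_s·A_i/A_s with C_s from the internal standard's own
calibration; `correction_factor()` and `quantify_qams()` are exact
mutual inverses (tested property), and when f is estimated from the
same noise-free calibration used by ESM the two methods agree to
machine precision.

The relative deviation between methods is RD% = |ΔC|/(C_ESM + C_QAMS) ×
100. The defining formula is never stated in the source material; this
form was reverse-engineered from the printed per-batch values (e.g.
0.556/0.559 → 0.269 vs printed 0.270; totals 6.975/6.960 → 0.108 vs
printed 0.112), whereas the conventional |ΔC|/C_ESM × 100 gives values
twice the printed ones. The conventional form is available via
`relative_deviation(..., method = "reference")`. Per-batch totals sum
the seven analytes and exclude the internal standard (verified: the
HN2 total equals the sum of its seven ESM values exactly). Note one
recomputation caveat: the printed concentrations carry three decimals,
which quantises a recomputed RD in steps of 100·0.001/(sum) — for the
smallest caffeic-acid pairs (~0.03 mg/g) that step is ~1.5 %, so
recomputed RDs can exceed the sub-1 % level that the unrounded data
support.

ESM calibration is ordinary least squares with free intercept; inverse
prediction clips negative concentrations to zero with a warning and
warns outside the calibrated response range. Condition aggregation
(mean and 100·sd/mean with n−1) reproduces the printed 19-condition
average rows exactly at three decimals for the columns we assert
(neochlorogenic 1.222, caffeic 0.667, RRT 0.219); the eupatilin column
re-averages to 1.052 against a printed 1.053, a rounding slip in the
printed table itself.

## The synthetic-data generator

The generator defines the study conditions under which everything else
is tested.

* **Design**: 18 batches (9 per region, labels HN/HB), 18 common peaks,
  reference peak 11 at 12.0 min, RRT template from the published
  per-condition averages where available and interpolated along the
  elution order otherwise; Gaussian peaks of σ = 0.05 min (the published
  asymmetry range 0.98–1.15 is near-symmetric, so a Gaussian with an
  optional tailing parameter suffices) on a flat baseline, sampled at
  σ/10 with a σ/5 resolution guard.
* **Contents**: per-batch true contents are lognormal around region
  means. Means come from the published 18-batch table where it shows a
  usable contrast (chlorogenic acid 2.20/1.23, isochlorogenic acid C
  3.44/2.69, eupatilin 1.053/1.997 mg/g HN/HB). The published group
  means for isochlorogenic acid B are nearly equal (1.83 vs 1.77)
  although that peak was a selected marker on the raw areas, and no
  per-region data exist for the 1,5-diacyl, isomer-A and triacyl
  peaks; those four markers get invented contrasts at the same scale
  (2.20/1.35, 1.10/0.65, 1.60/0.90, 0.50/1.00). Non-marker peaks,
  including neochlorogenic acid, get equal region means, so exactly
  seven differential peaks (2, 8, 9, 10, 11, 12, 17) are planted.
* **Response factors** are fixed per compound and chosen so the
  downstream correction factors land at the published magnitudes
  (0.6–1.3); areas are content × (0.2 g / 25 mL) × response factor.
* **Noise**: multiplicative lognormal with unit mean (contents are
  positive and CVs are the natural error scale) — a between-batch
  biological CV of 0.08 and an analytic area CV of 0.05 (the published
  instrument-robustness RSDs are all below 3 %, so analytic noise is
  not the limiting term). The biological CV is a deliberate
  idealisation: the printed batch spread is nearer 30 %, but at that
  heterogeneity an 18-sample design cannot reliably detect the weakest
  printed contrast (isochlorogenic acid C, 1.28-fold). The CV was
  calibrated once, on seeds disjoint from every test seed, to the
  operating point the marker-recovery experiment is designed around
  (~99 % per-marker detection power) and then frozen.
* **MS2 spectra** emit the rule library's diagnostic ions at reference
  abundances (the published worked values where they exist) with
  lognormal abundance noise, at theoretical m/z; calibration series are
  linear with lognormal noise. Every `simulate_*` function is
  deterministic given its seed.

**What passing tests do and do not show.** The generator produces flat
baselines, symmetric (or mildly tailing) Gaussian peaks, no retention
drift beyond what RRT cancels, no co-elution, no missing peaks, and
noise without batch effects or heteroscedasticity beyond the lognormal
CV. Passing the closed-loop tests therefore demonstrates the *methods*
are implemented correctly and internally consistent, not that they
would perform identically on real instrument data with drift, baseline
curvature and genuine 30 % batch heterogeneity.

**A structural limit worth knowing.** With 11 null peaks, 9 + 9
samples and the VIP > 1 ∧ p < 0.05 conjunction, a null peak reaches
VIP > 1 whenever its chance correlation with the class exceeds ~0.6,
which happens for at least one null peak in roughly 7 % of datasets; a
further small fraction loses the weakest marker to VIP sampling
variance. Exact recovery of all seven planted markers therefore
plateaus near 92–93 % per dataset regardless of noise settings — about
18.5 of 20 seeds in expectation — and a particular 20-seed draw can
land at 17. The acceptance suite reports the honest count. This mirrors
a real property of VIP-based selection at n = 18, not an implementation
defect.

## Problem sizes

The shipped analyses and tests use the study-scale design throughout:
18 × 18 matrices, 7-fold cross-validation, 200 permutations, 20-seed
recovery experiments, 1000 noisy-annotation trials, and ~3,900-point
chromatograms — each individual fit takes milliseconds, the whole suite
a few minutes.

## Known limitations

* Peak detection has no smoothing; heavy additive detector noise can
  truncate the valley walk. The generator's noise is multiplicative on
  areas, so this does not bite in-scope, but real traces would want a
  Savitzky–Golay pass first (out of scope, as are baseline-drift
  correction and retention alignment).
* The rule library covers the worked-out compound set (eight CQAs,
  two flavone aglycones, two flavonol *O*-glycosides, two
  *C*-glycosides), not a general natural-product space.
* Q² uses one deterministic stratified fold assignment rather than
  averaging over many random splits; with 18 samples the difference is
  small and reproducibility is worth more.
* Calibration is unweighted OLS; heteroscedastic weighting, LOD/LOQ and
  uncertainty propagation on f are out of scope.
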
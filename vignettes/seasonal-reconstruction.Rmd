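---
title: "Methods: seasonal temperature reconstruction and variance attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal temperature reconstruction and variance attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoseason)
```

# The problem

Terrestrial mollusk assemblages in surface soils track seasonal
temperatures: species differ in their thermal optima, activity seasons
and hibernation behaviour, so the composition of an assemblage carries a
multivariate imprint of spring, summer, autumn and winter temperature.
`paleoseason` turns a modern calibration set (site-by-taxon percentages
plus measured climate) into inverse models for each seasonal temperature
and for mean annual temperature (MAT), applies them to fossil sequences
from loess–palaeosol archives, and then asks the question the whole
exercise exists for: *which season's variability drives the variability
of MAT through time?*

The chain rests on three assumptions, each of which is checked rather
than presumed:

* **Unimodal species responses.** Species abundances follow
  single-peaked curves along the temperature gradients. The check is the
  DCA gradient length: compositional turnover beyond ~2 SD units
  justifies unimodal (CCA/WA-family) methods over linear ones.
* **Analogue coverage.** Fossil assemblages must resemble some part of
  the modern cloud. The check is the minimum-dissimilarity
  classification: a fossil sample whose nearest modern neighbour is
  farther than the 10th percentile of modern inter-site dissimilarities
  is a *no-analogue* sample and its reconstruction is suspect.
* **Specific signal.** A reconstruction must explain more of the fossil
  assemblage variance than a model trained on a meaningless variable.
  The check is the random-reconstruction significance test.

# Data model

A `taxon_table` is a dense sites × taxa matrix of non-negative counts or
percentages (sites are rows; the matrices here are at most a few hundred
by a few tens, so sparsity buys nothing). Percentage rows must sum to
100: deviations up to 0.5 — the rounding typically seen in published
tables — are renormalised exactly, anything worse is rejected. Fossil
tables carry calibrated ages (cal yr BP, larger = older) that must be
strictly monotone so that row order matches depth order. An `env_table`
aligns per-site environmental variables (°C, mm) one-to-one with the
sites. CSV I/O is UTF-8 with "," and "." as defaults and a ";" / ","
locale switch; an optional metadata list records choices such as whether
fossil percentages were computed over all individuals or only those
identifiable to species — the package accepts either and merely records
which.

Two dissimilarities are used with distinct roles: **Bray–Curtis** for
ordination (PCoA, NMDS), and **squared-chord** — the community standard
for percentage data, emphasising proportional composition — as the
default analogue and locality metric for MAT, the locally-weighted
models and the goodness-of-fit classification. The source study names
Bray–Curtis only for its ordinations and is silent on the analogue
metric, so the latter is an explicit, configurable default
(`metric = "sqchord"` vs `"bray"`).

# Ordination screening

Standard engines are delegated to `vegan`/`stats` behind this package's
interfaces: classical scaling (`stats::cmdscale`) for PCoA,
`vegan::decorana` for DCA, `vegan::cca` for CCA, `vegan::metaMDS` for
NMDS. Numerical choices:

* **PCoA negative eigenvalues.** Bray–Curtis is non-Euclidean, so the
  double-centred matrix can have negative eigenvalues. The Cailliez
  additive correction is applied automatically when any eigenvalue falls
  below −10⁻⁸ times the largest; Euclidean-embeddable input is
  decomposed raw.
* **DCA.** Detrending by segments with nonlinear rescaling (the Hill &
  Gauch procedure, 26 segments), rare-species downweighting off by
  default. Gradient length is the range of the first-axis site scores in
  SD units. One caveat worth knowing: the rescaled axis measures
  turnover along a *continuous* gradient. A continuous full turnover
  spans > 4 SD, but two fully disjoint site clusters sit exactly 2 SD
  apart under Hill's rescaling — a cluster pair has no internal
  gradient to stretch. Degenerate inputs are handled explicitly:
  compositionally identical sites return length 0.
* **VIF filtering.** Collinear predictors are removed iteratively: the
  variable with the highest variance inflation factor is dropped until
  all VIFs are at or below the threshold (default 20 — the study this
  emulates says only that VIFs were made "low"; 20 is the usual
  conservative cut). Ties are deterministic (first candidate wins).
* **Permutation tests.** The test statistic is the constrained-inertia
  fraction of a CCA on the (square-root-transformed) percentages. The
  p-value is (1 + #{permuted ≥ observed}) / (n_perm + 1), so the
  attainable minimum is 1/(n_perm+1); 999 permutations are conventional.
  The *forward-conditional* mode tests a candidate's additional
  contribution by permuting its residuals on the already-selected
  variables. Forward selection measures each candidate's gain as the
  joint constrained fraction minus the already-selected fraction — an
  exact duplicate therefore adds exactly zero and can never be selected.
* **NMDS.** Kruskal stress-1, best of 50 random starts, fossil samples
  placed *passively*: each is positioned by metric least squares against
  the fixed modern configuration, with a free scale factor because an
  NMDS configuration carries an arbitrary scale relative to the input
  dissimilarities. The modern ordination is never influenced by fossil
  points.
* **Seeding.** One master seed; every randomised sub-step derives a
  deterministic child seed from it (`derive_seed`), so per-variable
  tests are reproducible independently of each other.

# Transfer functions

The calibration family is implemented in the package (it is the heart of
the method, and its algebra is what the tests pin down):

* **WA.** Taxon optima are abundance-weighted means of the environmental
  variable; raw site predictions are abundance-weighted means of the
  optima. Because weighted averaging is applied twice, raw predictions
  are compressed towards the mean; a deshrinking regression corrects
  this. *Inverse* deshrinking (default) regresses the observed variable
  on the raw predictions; *classical* regresses raw on observed and
  inverts. Both regressions are weighted by site abundance totals —
  for percentage data all weights are equal, so this matches the
  textbook unweighted regression, while making the WA-PLS identity below
  exact for any input.
* **WA-PLS.** The ter Braak–Juggins algorithm: component 1 is the WA
  structure; each further component weighted-averages the *residual*
  environmental signal, is orthogonalised (site-total weights) against
  earlier components, standardised, and enters a weighted regression.
  Component 1 with inverse deshrinking reproduces WA exactly — an
  algebraic identity the test suite asserts to 10⁻¹⁰, alongside
  agreement with an independent loop-and-WLS implementation. Components
  are capped at min(n_taxa, n_sites − 1); the cross-validated
  component count is chosen as the smallest whose RMSEP is within 5% of
  the minimum (parsimony over marginal gains).
* **MAT.** Prediction is the 1/d-weighted mean of the k nearest training
  sites (default k = 10); a zero-distance analogue short-circuits the
  weights and returns its value exactly. Ties among equidistant
  analogues break stably by site id.
* **LW-WA / LW-WAPLS.** For each fossil sample the m_local nearest
  training sites (default min(100, 30% of the training set) — the source
  study is silent on neighbourhood size) form a local calibration set on
  which the base model is refitted. With the full neighbourhood this is
  exactly the global model. A local subset with fewer than two distinct
  environmental values cannot support a regression; such samples fall
  back to MAT and are flagged, and each sample's local subset is
  recorded.

Calibration operates on raw percentages; the square-root transform is an
ordination convention here (the study states it only for ordination),
though a flag enables it for calibration as well.

**Bootstrap validation** resamples sites with replacement, fits on the
bag and predicts the out-of-bag sites. RMSEP is the root of the mean
(over sites) of each site's mean squared out-of-bag error; R² is between
observations and mean out-of-bag predictions; average bias is the mean
residual; maximum bias is the largest absolute mean residual over 10
equal-width segments of the gradient (note max bias is a segment-level
quantity and need not exceed |average bias|). Sample-specific fossil
errors are √(s₁² + s₂²), s₁ the standard deviation of a sample's
bootstrap predictions, s₂ the RMSEP. Default n_boot is 1000; identical
seeds give bit-identical statistics.

# Assessment

Analogue thresholds are the empirical 5th and 10th percentiles
(type-7, linear interpolation — stated because class boundaries depend
on the convention) of the strict upper triangle of the training-set
dissimilarity matrix; fossil data never enter the thresholds. Minimum
distance below the 5th percentile → *good*; above the 10th →
*no-analogue*; between → *fair* (the interval reading of "fair", which
the source implies but never defines).

The significance test fixes the reconstruction method first, computes
the fraction of variance of the square-root-transformed, column-centred
fossil percentage matrix explained by the reconstruction
(single-predictor redundancy analysis, implemented as a closed-form
projection and cross-checked against `vegan::rda`), then repeats the
whole train-and-reconstruct cycle for variables drawn i.i.d. uniform
over the observed range of the real one (a Gaussian alternative sits
behind a config switch; the source does not state its null
distribution). Whether the RDA response should use square-root or raw
percentages is likewise unstated; square-root is used to mirror the
ordination transform.

# Seasonal variance attribution

MAT is the arithmetic mean of the four seasonal temperatures, per
sample. Series are linearly interpolated — linear cannot overshoot,
which matters for bounded palaeo series — onto a uniform grid from
⌈min age⌉ to ⌊max age⌋ in 100-yr steps, with no extrapolation. In each
1000-yr window (±500 yr, inclusive bounds — on the 100-yr grid that is
up to 11 points, matching the "~10 samples" the source describes) each
season's sample variance Vᵢ (divisor n − 1) is computed; the season's
percentage contribution is 100·Vᵢ/ΣVⱼ. Windows slide every 100 yr;
edge windows use the available points and are flagged *partial*;
windows with fewer than 2 points or zero total variance are flagged
undefined and propagate as nulls, never as zeros. Whether the original
windows were taken on the grid or on raw samples is ambiguous in the
source; the grid reading is the default and `window_variance` accepts
any centre/halfwidth for the raw-sample reading. Frequency
distributions bin the contributions over [0, 100]%; trends use LOWESS
(tricube-weighted local linear regression, robustifying iterations
configurable) with spans of 0.1 for reconstruction-style curves and 0.3
for contribution trends — the source names the smoother but no span.

# The synthetic generator

Because the real calibration and fossil data live in an external
repository, the package generates study-shaped data with known truth:

* **Training sets** (default 382 sites, 40 species, 500 individuals per
  sample) draw seasonal temperatures from a Gaussian copula with
  equicorrelation 0.8 — mid-latitude seasonal temperatures covary
  strongly, and this is the feature that makes per-season calibration
  genuinely hard — over ranges matching the emulated gradient (winter
  −23…5.9 °C, summer 10.9…27.9 °C). Each species responds unimodally to
  one designated driver season (optima spread evenly with jitter,
  tolerances 2.5–5 °C) times a weak broad Gaussian term in MAT, giving
  realistic collinearity while keeping the truth recoverable. Counting
  noise is multinomial; optional lognormal site effects are off by
  default.
* **Temperature histories** run 20,000 → 0 cal yr BP: a cold glacial
  state, a smooth deglacial ramp (15–9 ka), a warm plateau (9–4 ka), a
  linear late-Holocene cooling (30% of the amplitude), plus stationary
  AR(1) noise (SD 0.3 °C, φ = 0.6). Default amplitudes are winter
  5.5 °C (the largest, matching the ~5–6 °C deglacial winter warming the
  emulated region shows), spring 4.5, autumn 3.5, summer 3.0.
* **Fossil sequences** sample the history every 250 yr (emulating
  ~200–300 yr per sample), evaluate the same response model at the true
  temperatures, and draw multinomial counts; the truth table travels
  with the output. `inject_no_analogue` plants known outliers (a novel
  taxon at 80%, or a monospecific extreme) for testing the classifier.

What the generator does *not* emulate: taphonomic loss and
fragmentation, age-model uncertainty (synthetic ages are exact),
non-Gaussian or skewed response shapes, spatial autocorrelation among
modern sites, and secular changes in species pools. Passing tests
therefore demonstrate that the chain recovers truth *under its own
assumptions*; they do not validate those assumptions for field data.

One behaviour of the defaults deserves emphasis: with seasons correlated
at 0.8, a transfer function trained on a *random* variable still partly
reconstructs the common climate axis, so per-season
random-reconstruction significance is systematically weaker in the
synthetic world than the clean separations reported from field data —
the MAT test separates sharply, the per-season tests less so. This is a
property of strongly covarying gradients, not of the test
implementation, and it is the reason the significance test's null
calibration (rejection rate ≈ 5% under independence) is checked
separately in the test suite.

# Problem sizes and determinism

The test suite runs the full default study (382 × 40 training set, 81
fossil samples) for the end-to-end recovery checks, null calibrations
with 100–150 replicates at 99 permutations/randoms on small matrices,
and 999-permutation/999-random single runs where the attainable-minimum
p-value is asserted; the whole suite completes in about a minute on one
CPU, and `scripts/acceptance.R` in under half a minute. Every stochastic
step takes a seed, and every compound analysis derives child seeds
deterministically, so identical configurations are bit-identical on
re-run.

# Known limitations

* WA-family methods compress extremes; deshrinking mitigates but cannot
  remove edge bias, visible as deglacial amplitudes slightly below
  truth.
* The locally-weighted bootstrap refits the local model per out-of-bag
  site, which is the expensive corner of the package; n_boot below ~100
  gives noticeably noisy sample-specific errors.
* h-block / spatially aware cross-validation and
  autocorrelation-corrected significance variants are out of scope, as
  are Gaussian-logit response modelling and Bayesian transfer functions.
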
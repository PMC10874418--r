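---
title: "Models and methods behind somperturb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind somperturb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somperturb)
```

somperturb analyses age-structured case/control expression cohorts in
which controls span the whole lifespan but cases are sampled only after
clinical onset. This vignette documents the models, the parameters that
matter, the numerical choices, and the design decisions that were
genuinely open — including several places where simulation forced us away
from a first, simpler design.

## Preprocessing

Nuisance covariates are removed per gene by ordinary least squares:
expression is regressed on an intercept plus the nuisance design
(categorical covariates effect-coded, continuous covariates mean-centered)
and only the fitted nuisance component is subtracted, preserving each
gene's grand mean. This matches the behaviour of the standard
batch-removal tools used for multi-study harmonization; the test suite
cross-checks it against `limma::removeBatchEffect`. Rank-deficient designs
fail loudly with the collinear columns named, because silently dropping
columns would leave part of a batch effect in place.

Gene centering subtracts each gene's mean across all samples. The result
is a signed log fold change relative to the gene's cohort average (the
*value minus mean* convention: overexpression is positive). The nine age
bins — (0-1], (1-5], (5-10], (10-18], (18-35], (35-50], (50-65], (65-85],
(85-100] years — follow the stages of prefrontal-cortex development and
aging; membership is left-exclusive/right-inclusive, so an age equal to a
bin's upper edge stays in the lower-labelled bin (age 18 is in (10-18]).
Continuous age is retained alongside the bin label: all perturbation-time
computation uses continuous age, and bins exist for portraits and
differential-expression tabulation only.

## The self-organizing map

The SOM is trained in batch mode on gene profiles (rows of the centered
matrix) with Euclidean distance. Weights are initialized linearly: grid
coordinates are mapped affinely onto ±2 standard deviations along the
first two principal axes of the gene profiles, which makes training
deterministic and seeds the map's topology. Each epoch assigns every gene
to its best-matching unit (ties to the lowest metagene index, for
determinism) and replaces every metagene weight by the
neighborhood-weighted mean of its assigned genes, with a Gaussian
neighborhood whose radius decays linearly from `k/2` to 0.5 grid units
over 40 epochs (all configurable). Batch updates were chosen over online
updates because they are deterministic given the initialization and admit
a useful limit: with the final radius driven towards zero the update is
exactly Lloyd's k-means step, so occupied metagene weights converge to
member centroids — the oracle used in the tests.

A note on the training loss: batch SOM minimizes the
neighborhood-weighted distortion *at the current radius*, not the
quantization error itself, so the mean gene-to-BMU distance may rise
during the coarse phase while the map unfolds. It decreases monotonically
through the fine-tuning half of the schedule, which is what the tests
assert.

The default grid is 50 × 50 for full-size cohorts; tests and the bundled
synthetic runs use k = 20 and below, which keeps a full pipeline run
under a minute on one CPU while leaving about 5 genes per metagene at the
default 2,000-gene cohort.

## Summary maps and spot segmentation

The variance map holds each metagene's variance (unbiased, n−1) across
all sample portraits; the overexpression map holds the per-metagene
maximum over group-mean portraits. Two refinements matter in practice:

* **Empty metagenes are masked.** Units with no assigned genes are
  interpolating units: their weights are neighborhood mixtures of nearby
  occupied territories and summarize no genes. Left unmasked, they form
  high-variance bridges that fuse unrelated modules into one spot; in
  simulations with five planted modules this merged a pair of modules in
  every seed tried.
* **Adjacency is gated by profile coherence.** Spots are modules of
  co-expressed genes, so two adjacent foreground metagenes are joined
  only if their weight profiles correlate (Pearson r > 0.5 by default).
  Without the gate, two distinct modules whose territories happen to
  touch on the grid are inseparable no matter the threshold — raising the
  threshold erodes the weaker module before it splits the bridge.

Both behaviours can be disabled (`mask_empty = FALSE`, `r_min = NULL`),
and segmentation of a raw map without a model uses pure 4- or
8-neighborhood semantics. Defaults: variance map, 0.90 quantile
threshold (strictly above), minimum 3 metagenes, 8-adjacency; surviving
components are labelled A, B, C, … by decreasing size with ties broken by
the smallest row-major index. Which summary map and criterion best
dissects a real landscape is data-dependent; both maps sit behind the
same interface.

## Annotation and differential expression

The Gene Set Z-score of set *S* in sample *s* is the standardized mean
shift `(mean of centered expression over S − mean over all genes) /
(sd over all genes / sqrt(|S|))`, with the sample (n−1) standard
deviation and |S| counted over genes present in the matrix. It is
invariant under positive rescaling of the matrix. Overrepresentation of a
set in a spot's gene list is the hypergeometric upper tail (one-tailed
Fisher exact test in the enrichment direction) over the universe of all
genes on the map — the most conservative self-contained universe —
with Benjamini–Hochberg adjustment across sets within each spot.

Gene-level differential expression within an age group is the ordinary
two-group linear model (pooled-variance t), with BH adjustment across
genes and the call criterion logFC ≠ 0 and adjusted p < 0.05. Variance
moderation is deliberately out of scope; with it, desk-scale power
figures would not be comparable to the plain model the tests calibrate.
Genes with zero pooled variance but non-zero mean difference are reported
at the smallest positive representable p and flagged rather than crashing
on degenerate synthetic input. Spot-level disease effects are
`expression ~ diagnosis + age` over the union of one disease's and the
control samples, reported per disease across all ages; per-age-group
variants are available by filtering the input.

## The branch-point Gaussian process

For one spot and one disease we observe control points
(t<sub>i</sub>, y<sub>i</sub>) and disease points (s<sub>j</sub>,
z<sub>j</sub>) over age. The control trajectory is a draw
`f ~ GP(0, k)` with squared-exponential
`k(t,t') = sigma_f^2 exp(-(t-t')^2 / (2 l^2))`; the disease trajectory is
`g(t) = f(t) + d(t)` with a deviation that is identically zero up to the
branch age τ and, after it, a GP *pinned to zero at τ*:

> Cov(d(s), d(t)) = sigma_d² · ( r(s,t) − r(s,τ) r(τ,t) ),  s, t > τ,

with `r` a unit-variance RBF with its own lengthscale. The pinned term is
a Schur complement, hence positive semidefinite, and vanishes at
s = t = τ, so the disease variance is continuous at the branch.
Observation noise sigma_n² sits on the diagonal. Because the arms share
`f` exactly before τ, a branch far below the youngest case remains
identifiable from how the arms differ where they *are* both observed —
the property that lets adult-onset cohorts support inferred perturbation
ages in infancy.

The likelihood of all observations is evaluated on a grid of 50 τ values
spanning the control age range (inclusive); the posterior over τ uses a
uniform grid prior, normalized by log-sum-exp; MAP ties break towards the
smaller τ. The likelihood ratio reported is the Bayes factor

> LR = mean over the τ grid of L(τ) / L(shared),

i.e. the branch model with τ marginalized against the shared
(no-perturbation, τ = ∞) model, with LR > 1 the soft cut-off for a
time-perturbed module. The profile variant (max over τ) is kept in the
fit object as `lr_profile`.

### Why these estimation choices

Three protocol decisions came out of simulation at the package's own
study conditions (60 control ages on 0–85, 40 disease ages on 18–85,
divergence amplitude three times the noise standard deviation):

* **Base hyperparameters are fitted under the independent-arms model**
  (each arm its own GP with shared hyperparameters), not under the pooled
  shared model. Pooled fitting folds any true divergence into the noise
  estimate (fitted sigma_n² roughly doubled in our simulations) and
  biases the MAP branch age decades early; the independent fit coincides
  with the shared fit when nothing is perturbed and stays uncontaminated
  otherwise. A `model = "shared"` mode is retained.
* **The deviation's scale and smoothness are marginalized, not
  point-fitted.** sigma_d has a half-normal prior with scale twice the
  pooled data standard deviation; the deviation lengthscale is
  log-uniform on [1, 20] years; both are integrated by equal-weight
  quantile-midpoint quadrature (10 × 6 nodes). Point-fitting these two
  parameters overfits unperturbed courses (likelihood ratios approaching
  10 under the null), while tying the deviation to the base kernel's
  scale makes real divergence of several noise standard deviations
  unrepresentable and again drags τ early. The 20-year cap encodes the
  model's purpose — detecting *localized* onsets; deviations slower than
  that are indistinguishable from a different baseline.
* **The LR marginalizes τ rather than maximizing it.** The maximum over
  50 grid values inflates the ratio on null data by selection; averaging
  under the uniform prior keeps null courses at LR ≈ 0.3–1 while real
  perturbations still exceed 1 by many orders of magnitude.

With these choices, at the conditions above the MAP lands within ±7.5
years of the planted branch in 17/20 (τ = 30) and 16/20 (τ = 60) seeded
replicates, every perturbed course has LR > 1, and 12/12 null courses
fall at or below 1.05. Perturbations planted at τ = 5, below the youngest
case, are located to within a few years *when the divergence persists
into the sampled range*; a transient divergence that vanishes before age
18 is — correctly — not localized, and the posterior stays flat below 18.

### Numerics

All likelihoods are computed in log space via Cholesky factorization with
escalating jitter (0, then 1e-10·sigma_f² up to 1e-6·sigma_f²); failure
beyond that range raises an error, since the construction is positive
semidefinite by Schur complement and a larger defect signals a bug.
Hyperparameter optimization is L-BFGS-B over log-parameterized
(sigma_f², l, sigma_n²) with a heuristic start (half the pooled variance,
a quarter of the age span, a quarter of the pooled variance) plus four
seeded random restarts inside data-derived bounds; the bounds scale with
the pooled variance and age span, so rescaling the expression values
rescales the fitted variances and leaves the lengthscale invariant.

## eQTL enrichment

Spot gene lists are tested against binary gene × tissue cis-eQTL flags
with the same one-tailed Fisher machinery, Bonferroni-corrected with the
family equal to the number of tissues per spot (the family size is a
parameter: correcting per spot across tissues is the reading adopted; a
global family is obtained by passing `family = n_spots * n_tissues`).
Spots passing LR > 1 are joined with their enriched tissues and the sign
of the age-adjusted disease coefficient into a timeline report.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not any particular dataset: control ages drawn from a
nine-bin lifespan mixture weighted like a real post-mortem control arm,
disease ages uniform on [18, 85] (no pre-onset cases), planted modules
whose genes share a smooth baseline trajectory (logistic rise, logistic
decline, or Gaussian peak in age), disease divergence that is exactly
zero until τ and then follows a half-sigmoid ramp with a 5-year rise
scale (so the branch model's continuity assumption holds by
construction), round-robin batches, Bernoulli sex, Gaussian pH
(6.5 ± 0.25), uniform post-mortem interval (5–40 h), and i.i.d. Gaussian
noise. Defaults: 2,000 genes, 5 modules of 50 genes, 60 controls and 30
cases per disease arm (150 samples), noise sd 0.5 log2 units, divergence
amplitude 1.5 (three times noise, the regime in which branch ages are
recoverable but not trivial), nuisance effects of 0.2–0.3 log2 units.
The noise magnitude and inter-individual variance of real cohorts are not
estimated from any study; they are free parameters exposed in the
configuration.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: per-gene loading heterogeneity within a
module, non-Gaussian and heteroscedastic noise, correlated nuisance
structure (batch confounded with diagnosis), probe-level artefacts, and
modules that overlap in membership. Real landscapes also contain many
more, smaller, partially overlapping modules than the five planted here.

## Problem sizes

The test suite and the acceptance script run entirely at desk scale, by
choice: 20 × 20 maps on 2,000-gene, 150-sample cohorts for end-to-end
runs; 100-observation time courses for the GP; 200 simulations for null
calibration; exhaustive Fisher-oracle sweeps over 2×2 tables with margins
up to 50. A full suite run takes about two minutes on one CPU.

## Known limitations

* The branch model assumes a single branch per spot × disease; a module
  that diverges, reverts, and diverges again is summarized by one τ and
  its posterior will be multimodal.
* Hyperparameters are held fixed across the τ grid (fitted once); τ and
  the kernel are not jointly inferred, which is cheap and keeps the
  profile comparable across the grid but understates posterior width.
* The deviation-lengthscale prior caps at 20 years; genuinely slower
  drifts are attributed to late, weaker branches.
* Spot segmentation inherits the map's resolution: modules smaller than
  about three metagenes at the chosen k are not separable.
* The gene-level test is unmoderated; for very small arms per age group,
  variance-moderated tests would be more powerful.
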
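# somperturb

Tools for asking *when* a disease transcriptome starts to differ from the
healthy one. The package targets age-structured case/control expression
cohorts — the motivating setting is post-mortem prefrontal cortex in
schizophrenia, bipolar disorder and major depressive disorder, where
controls span the whole lifespan (0–100 years) but cases are only sampled
after clinical onset (≥ 18 years) — and provides, in one pipeline:

1. **Harmonization**: per-gene least-squares removal of nuisance covariates
   (batch, sex, pH, post-mortem interval) and gene centering, turning log
   expression into log fold change relative to each gene's cohort mean,
   with samples stratified into nine lifespan age bins.
2. **SOM portraits**: a batch self-organizing map clusters the N genes
   into a k × k grid of *metagenes* by profile similarity; each sample's
   metagene vector, reshaped onto the grid, is its expression *portrait*.
   Gene placement is shared by all samples, so portraits are directly
   comparable and can be averaged per group.
3. **Spot segmentation**: the per-metagene variance (or overexpression)
   summary map is thresholded at a quantile and split into connected,
   profile-coherent components — *spots*, treated as co-expressed gene
   modules with per-sample expression.
4. **Annotation**: Gene Set Z-scores per sample, one-tailed Fisher
   overrepresentation of gene sets in spot gene lists (BH-adjusted per
   spot), and correlation of cell-type signature scores with spot
   expression (links at r > 0.5).
5. **Differential expression**: per-age-group disease vs control gene
   tests (BH-adjusted; a DEG has logFC ≠ 0 and adjusted p < 0.05) and
   spot-level regression adjusted for age.
6. **Perturbation time (the core)**: a Gaussian-process branch-point model
   per spot × disease. Control expression over age is a draw
   `f ~ GP(0, k_RBF)`; disease expression is `g = f + d`, where the
   deviation `d` is zero up to an unknown branch age τ and afterwards a GP
   pinned to zero at τ (a Schur-complement construction, so `g` is
   continuous at the branch). The marginal likelihood is evaluated on a
   50-point τ grid spanning the control age range, the deviation's scale
   and smoothness are marginalized over a fixed weakly-informative prior,
   and the result is a posterior over τ, its MAP, and a Bayes-factor style
   likelihood ratio LR of the branch model against the shared
   (no-perturbation) model. LR > 1 flags a time-perturbed module. Because
   the arms are assumed identical *before* τ, branch ages far below the
   youngest case (even in infancy) remain identifiable.
7. **eQTL enrichment**: one-tailed Fisher tests of spot gene lists against
   binary gene × tissue cis-eQTL flags, Bonferroni-corrected across the
   tissue family, joined with the perturbation results into a timeline of
   time-perturbed, eQTL-enriched modules.

A synthetic-cohort generator (`cohort_config()` / `generate_cohort()`)
plants co-expressed modules with smooth logistic/peak age trajectories,
per-disease divergence ramps after known perturbation times, nuisance
effects and Gaussian noise — plus matching gene sets and eQTL flags — so
every stage is testable offline against known ground truth.

## Worked example

Infer the perturbation time of one module time-course (planted branch at
age 30, divergence amplitude 3× the noise standard deviation):

```r
library(somperturb)

tc  <- simulate_timecourse(tau = 30, amplitude = 1.5, noise_sd = 0.5, seed = 3)
fit <- perturbation_fit(tc$ctrl_age, tc$ctrl_y, tc$dis_age, tc$dis_y, seed = 3)
fit
#> Branch-point GP fit
#>   MAP perturbation age: 30.14 years
#>   likelihood ratio (branch vs shared): 4.153e+18  [time-perturbed]
#>   hyperparameters: sigma_f2 = 0.301, lengthscale = 26.7 y, sigma_n2 = 0.22
summary(fit)
#> MAP tau: 30.14 years; 95% credible interval [2.999, 35.23]
#> LR: 4.153e+18; posterior entropy: 2.794
```

The MAP branch age lands on the planted value; the enormous likelihood
ratio says the branch model explains the two arms vastly better than a
shared trajectory. `plot(fit)` draws both arms' points, the fitted GP
means with 95% credible bands, and the τ posterior. On an unperturbed
course the same call returns LR ≤ 1 (the marginalized branch model is
penalized for unused flexibility).

The full pipeline on a synthetic cohort (2,000 genes, 5 planted modules,
150 samples, 20 × 20 map):

```r
res <- run_pipeline(pipeline_config(
  synthetic = cohort_config(seed = 1), som_k = 20, seed = 1
))
res$spots                 # segmented modules with member genes
res$perturbation$table    # spot x disease MAP tau and LR
res$timeline$timeline     # time-perturbed spots with enriched eQTL tissues
```

All artifacts (expression, spot tables, perturbation posteriors, timeline,
manifest) are written as tab-separated text and JSON under the run
directory; identical configurations reproduce them bit-identically.

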
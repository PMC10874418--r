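test_that("zero-noise cohort without perturbations puts cases on the control trajectory", {
  cfg <- clean_config(perturbations = empty_perturbations())
  ch <- generate_cohort(cfg)
  for (m in seq_len(cfg$n_modules)) {
    expected <- module_trajectory(cfg$trajectories[[m]], ch$meta$age)
    for (g in ch$truth$modules[[m]]) {
      expect_equal(unname(ch$expr[g, ]), expected, tolerance = 1e-12)
    }
  }
  # background genes are flat zero
  expect_true(all(ch$expr[ch$truth$background, ] == 0))
  # disease sample value equals the control trajectory at the same age
  dis <- which(ch$meta$diagnosis != "CNTRL")[1]
  g1 <- ch$truth$modules[[1]][1]
  expect_identical(
    ch$expr[g1, dis],
    module_trajectory(cfg$trajectories[[1]], ch$meta$age[dis])
  )
})

test_that("generation is deterministic in the seed", {
  cfg <- cohort_config(n_genes = 200, n_modules = 2, genes_per_module = 10,
    n_control = 15, n_disease = c(SCZ = 8), seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$meta, b$meta)
  cfg2 <- cohort_config(n_genes = 200, n_modules = 2, genes_per_module = 10,
    n_control = 15, n_disease = c(SCZ = 8), seed = 8)
  expect_false(identical(generate_cohort(cfg2)$expr, a$expr))
})

test_that("planted divergence follows the closed-form half-sigmoid ramp", {
  pt <- data.frame(module = 1, disease = "SCZ", tau = 30, amplitude = -1)
  cfg <- clean_config(
    n_modules = 1, genes_per_module = 5, perturbations = pt,
    trajectories = list(list(family = "constant", level = 0))
  )
  ch <- generate_cohort(cfg)
  g <- ch$truth$modules[[1]][1]
  dis <- ch$meta$diagnosis == "SCZ"
  # control side of the branch: flat zero
  expect_true(all(ch$expr[g, !dis] == 0))
  # direct evaluation of the stated ramp formula, written out independently
  ramp <- function(a) {
    ifelse(a > 30, -1 * (2 / (1 + exp(-(a - 30) / 5)) - 1), 0)
  }
  expect_equal(unname(ch$expr[g, dis]), ramp(ch$meta$age[dis]),
    tolerance = 1e-12)
  # and the packaged evaluator agrees with the formula at age 50
  expect_equal(
    divergence_ramp(50, 30, -1),
    -(2 / (1 + exp(-4)) - 1),
    tolerance = 1e-15
  )
})

test_that("divergence is exactly zero at and before tau on a dense age grid", {
  ages <- seq(0, 100, by = 0.25)
  for (tau in c(0, 5, 30.5, 60, 99)) {
    d <- divergence_ramp(ages, tau, amplitude = 2)
    expect_true(all(d[ages <= tau] == 0))
    expect_true(all(d[ages > tau] != 0))
  }
})

test_that("module genes correlate more within than with the background", {
  ch <- generate_cohort(cohort_config(seed = 5))
  X <- center_genes(ch$expr)
  mod <- ch$truth$modules[[1]]
  bg <- sample(ch$truth$background, 50)
  within_r <- mean(cor(t(X[mod, ]))[upper.tri(diag(length(mod)))])
  background_r <- mean(cor(t(X[bg, ]))[upper.tri(diag(length(bg)))])
  expect_gt(within_r, background_r)
  expect_gt(within_r, 0.3)
})

test_that("cohort config validates its invariants", {
  expect_error(
    cohort_config(n_genes = 10, n_modules = 2, genes_per_module = 10),
    "exceeds"
  )
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(
    cohort_config(perturbations = data.frame(
      module = 1, disease = "SCZ", tau = 120, amplitude = 1
    )),
    "tau"
  )
  expect_error(
    cohort_config(perturbations = data.frame(
      module = 99, disease = "SCZ", tau = 10, amplitude = 1
    )),
    "unknown module"
  )
})

test_that("generated gene sets mirror the planted modules plus seeded decoys", {
  ch <- generate_cohort(clean_config())
  sets0 <- generate_genesets(ch$truth, extra_random_sets = 0)
  expect_length(sets0, length(ch$truth$modules))
  for (m in names(ch$truth$modules)) {
    a <- sets0[[paste0("module_", m)]]
    b <- ch$truth$modules[[m]]
    expect_equal(length(intersect(a, b)) / length(union(a, b)), 1)
  }
  s1 <- generate_genesets(ch$truth, extra_random_sets = 3, seed = 9)
  s2 <- generate_genesets(ch$truth, extra_random_sets = 3, seed = 9)
  expect_identical(s1, s2)
  expect_length(s1, length(ch$truth$modules) + 3)
  expect_error(
    generate_genesets(ch$truth, decoy_size = 1e6),
    "background"
  )
})

test_that("eQTL flag table honours degenerate rates", {
  ch <- generate_cohort(clean_config())
  genes <- rownames(ch$expr)
  t0 <- generate_eqtl_table(ch$truth, genes,
    baseline_rate = 0, enriched_pairs = NULL)
  expect_true(all(t0 == 0))
  t1 <- generate_eqtl_table(ch$truth, genes,
    baseline_rate = 1, enriched_pairs = NULL)
  expect_true(all(t1 == 1))
  expect_error(
    generate_eqtl_table(ch$truth, genes,
      enriched_pairs = data.frame(module = "nope", tissue = 1)),
    "unknown module"
  )
})

test_that("planted eQTL enrichment is detectable by an independent Fisher oracle", {
  # 100-gene module in a 1000-gene universe, flagged at 0.9 vs baseline 0.1
  truth <- list(
    modules = list(M1 = sprintf("G%04d", 1:100)),
    background = sprintf("G%04d", 101:1000)
  )
  universe <- sprintf("G%04d", 1:1000)
  hits <- 0
  for (s in 1:100) {
    tab <- generate_eqtl_table(truth, universe,
      n_tissues = 1,
      enriched_pairs = data.frame(module = "M1", tissue = 1),
      baseline_rate = 0.1, enriched_rate = 0.9, seed = s
    )
    flag <- tab[, 1]
    in_mod <- universe %in% truth$modules$M1
    p <- fisher.test(
      table(factor(in_mod, c(TRUE, FALSE)), factor(flag == 1, c(TRUE, FALSE))),
      alternative = "greater"
    )$p.value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("simulated time courses respect arm age supports and the planted branch", {
  tc <- simulate_timecourse(tau = 30, amplitude = 2, noise_sd = 0, seed = 4)
  expect_true(all(tc$dis_age >= 18))
  expect_true(all(tc$ctrl_age >= 0 & tc$ctrl_age <= 85))
  base <- list(
    family = "logistic-decline", midpoint = 35, scale = 15,
    low = -1, high = 1
  )
  expect_equal(tc$ctrl_y, module_trajectory(base, tc$ctrl_age))
  pre <- tc$dis_age <= 30
  expect_equal(tc$dis_y[pre], module_trajectory(base, tc$dis_age[pre]))
  expect_true(all(
    tc$dis_y[!pre] != module_trajectory(base, tc$dis_age[!pre])
  ))
})
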
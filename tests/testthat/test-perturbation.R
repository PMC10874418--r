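test_that("the RBF kernel has the stated closed form and symmetry", {
  p <- gp_params(1, 10, 0.1)
  expect_equal(rbf_kernel(3, 3, p)[1, 1], 1)
  expect_equal(rbf_kernel(0, 10, p)[1, 1], exp(-0.5), tolerance = 1e-12)
  p2 <- gp_params(2.5, 7, 0.1)
  expect_equal(rbf_kernel(4, 4, p2)[1, 1], 2.5)
  set.seed(1)
  t1 <- runif(6, 0, 80)
  K <- rbf_kernel(t1, t1, p2)
  expect_equal(K, t(K))
  expect_error(gp_params(0, 10, 0.1), "positive")
  expect_error(gp_params(1, 10, -1), "positive")
})

test_that("the branch never opens beyond the oldest observation", {
  p <- gp_params(1.3, 15, 0.2)
  set.seed(2)
  ca <- sort(runif(12, 0, 80))
  da <- sort(runif(8, 18, 80))
  shared <- build_joint_covariance(ca, da, Inf, p)
  late <- build_joint_covariance(ca, da, max(c(ca, da)), p)
  expect_equal(late, shared)
  # pooled shared covariance is just the RBF kernel plus noise
  expect_equal(
    shared,
    rbf_kernel(c(ca, da), c(ca, da), p) + diag(0.2, 20)
  )
})

test_that("the disease variance is continuous at the branch point", {
  p <- gp_params(2, 12, 0.1)
  tau <- 40
  eps <- 1e-9
  K <- build_joint_covariance(numeric(0), c(tau + eps, 60), tau, p,
    noise = FALSE)
  # pinned term at the branch point itself is zero by construction
  expect_lt(abs(K[1, 1] - p$sigma_f2), 1e-12)
  # and grows smoothly after it
  K10 <- build_joint_covariance(numeric(0), c(tau + 10, 60), tau, p,
    noise = FALSE)
  expect_gt(K10[1, 1], p$sigma_f2)
  expect_lt(K10[1, 1], 2 * p$sigma_f2 + 1e-12)
})

test_that("random branch covariances are positive semidefinite before jitter", {
  set.seed(11)
  worst <- Inf
  for (i in 1:60) {
    p <- gp_params(10^runif(1, -1, 1), runif(1, 2, 60), 0.1)
    ca <- sort(runif(sample(5:25, 1), 0, 90))
    da <- sort(runif(sample(5:25, 1), 10, 90))
    tau <- runif(1, 0, 90)
    K <- build_joint_covariance(ca, da, tau, p,
      noise = FALSE,
      sigma_d2 = 10^runif(1, -1, 1), lengthscale_d = runif(1, 1, 40)
    )
    worst <- min(worst, min(eigen(K, symmetric = TRUE,
      only.values = TRUE)$values))
  }
  expect_gte(worst, -1e-8)
})

test_that("the Cholesky likelihood matches a dense multivariate-normal oracle", {
  set.seed(5)
  p <- gp_params(1.2, 18, 0.3)
  ca <- sort(runif(15, 0, 80))
  da <- sort(runif(10, 18, 80))
  y <- rnorm(25)
  for (tau in c(-5, 10, 41.3, 79, Inf)) {
    K <- build_joint_covariance(ca, da, tau, p)
    expect_equal(
      somperturb:::gp_loglik(y, K, p$sigma_f2),
      mvn_logdensity_oracle(y, K),
      tolerance = 1e-6
    )
  }
})

test_that("shared-model hyperparameter fitting recovers a known lengthscale", {
  truth <- gp_params(1, 20, 0.01)
  ok <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    t_all <- sort(runif(120, 0, 100))
    K <- rbf_kernel(t_all, t_all, truth) + diag(truth$sigma_n2, 120)
    y <- drop(rnorm(120) %*% chol(K + diag(1e-10, 120)))
    fit <- fit_hyperparameters(t_all, y, numeric(0), numeric(0),
      model = "shared", restarts = 2, seed = s)
    if (fit$lengthscale > 10 && fit$lengthscale < 40) ok <- ok + 1
  }
  expect_gte(ok, 16) # within a factor of 2 in >= 80% of replicates
})

test_that("pure noise drives the signal-to-noise ratio down", {
  set.seed(3)
  t_all <- sort(runif(100, 0, 80))
  y <- rnorm(100)
  fit <- fit_hyperparameters(t_all, y, numeric(0), numeric(0),
    model = "shared", restarts = 2)
  expect_lt(fit$sigma_f2 / fit$sigma_n2, 0.5)
})

test_that("hyperparameter fits are scale-equivariant", {
  tc <- simulate_timecourse(tau = 30, amplitude = 1.5, noise_sd = 0.4,
    seed = 6)
  f1 <- fit_hyperparameters(tc$ctrl_age, tc$ctrl_y, tc$dis_age, tc$dis_y,
    restarts = 2, seed = 1)
  f2 <- fit_hyperparameters(tc$ctrl_age, 2 * tc$ctrl_y, tc$dis_age,
    2 * tc$dis_y, restarts = 2, seed = 1)
  expect_equal(f2$sigma_f2 / f1$sigma_f2, 4, tolerance = 0.1)
  expect_equal(f2$sigma_n2 / f1$sigma_n2, 4, tolerance = 0.1)
  expect_equal(f2$lengthscale, f1$lengthscale, tolerance = 0.15)
})

test_that("the fit object is well-formed and the posterior sums to one", {
  tc <- simulate_timecourse(tau = 30, amplitude = 1.5, noise_sd = 0.5,
    seed = 3)
  fit <- perturbation_fit(tc$ctrl_age, tc$ctrl_y, tc$dis_age, tc$dis_y,
    seed = 3)
  expect_s3_class(fit, "perturbation_fit")
  expect_equal(sum(fit$posterior), 1, tolerance = 1e-12)
  expect_true(fit$map_tau %in% fit$tau_grid)
  expect_equal(
    fit$map_tau,
    fit$tau_grid[which.max(fit$posterior)]
  )
  expect_gte(fit$lr, 0)
  expect_gte(fit$lr_profile, fit$lr)
  expect_length(fit$tau_grid, 50)
  expect_equal(min(fit$tau_grid), min(tc$ctrl_age))
  expect_equal(max(fit$tau_grid), max(tc$ctrl_age))
  s <- summary(fit)
  expect_lte(s$credible["lower"], fit$map_tau)
  expect_output(print(fit), "MAP perturbation age")
  pred <- predict(fit, ages = c(10, 30, 50))
  expect_equal(nrow(pred), 3)
  expect_true(all(pred$ctrl_sd >= 0))
})

test_that("a branch beyond all data reproduces the shared likelihood", {
  tc <- simulate_timecourse(tau = 30, amplitude = 1.5, noise_sd = 0.5,
    seed = 8)
  p <- gp_params(1, 15, 0.25)
  y <- c(tc$ctrl_y, tc$dis_y)
  K_far <- build_joint_covariance(tc$ctrl_age, tc$dis_age, 200, p)
  K_shared <- build_joint_covariance(tc$ctrl_age, tc$dis_age, Inf, p)
  expect_equal(
    somperturb:::gp_loglik(y, K_far, p$sigma_f2),
    somperturb:::gp_loglik(y, K_shared, p$sigma_f2),
    tolerance = 1e-9
  )
})

test_that("an identical disease arm gives no evidence for perturbation", {
  set.seed(12)
  ages <- sort(runif(40, 0, 85))
  base <- list(family = "logistic-decline", midpoint = 35, scale = 15,
    low = -1, high = 1)
  y <- module_trajectory(base, ages) + rnorm(40, 0, 0.4)
  fit <- perturbation_fit(ages, y, ages, y, seed = 2)
  expect_lte(fit$lr, 1 + 1e-6)
  # no sharp early peak: the posterior does not concentrate below the
  # median age
  expect_lt(sum(fit$posterior[fit$tau_grid < median(ages)]), 0.5)
})

test_that("planted perturbation times are recovered with decisive likelihood ratios", {
  maps <- numeric(0)
  lrs <- numeric(0)
  for (s in 1:6) {
    tc <- simulate_timecourse(tau = 30, amplitude = 1.5, noise_sd = 0.5,
      seed = 20 + s)
    fit <- perturbation_fit(tc$ctrl_age, tc$ctrl_y, tc$dis_age, tc$dis_y,
      seed = s)
    maps <- c(maps, fit$map_tau)
    lrs <- c(lrs, fit$lr)
  }
  expect_gte(sum(abs(maps - 30) <= 7.5), 5)
  expect_true(all(lrs > 1))
})

test_that("recovery error shrinks as the divergence amplitude grows", {
  med_err <- vapply(c(1, 3), function(mult) {
    errs <- vapply(1:6, function(s) {
      tc <- simulate_timecourse(tau = 30, amplitude = mult * 0.5,
        noise_sd = 0.5, seed = 40 + s)
      fit <- perturbation_fit(tc$ctrl_age, tc$ctrl_y, tc$dis_age,
        tc$dis_y, seed = s)
      abs(fit$map_tau - 30)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_lte(med_err[2], med_err[1])
})

test_that("early perturbations are located only while divergence persists", {
  # persistent early divergence: MAP well below the youngest case
  tc <- simulate_timecourse(tau = 5, amplitude = 1.5, noise_sd = 0.5,
    seed = 2)
  fit <- perturbation_fit(tc$ctrl_age, tc$ctrl_y, tc$dis_age, tc$dis_y,
    seed = 2)
  expect_lte(abs(fit$map_tau - 5), 10)
  expect_gt(fit$lr, 1)
  # divergence that vanishes before the first sampled case: flat posterior
  # below 18, no spurious sharp peak
  set.seed(33)
  base <- list(family = "logistic-decline", midpoint = 35, scale = 15,
    low = -1, high = 1)
  ctrl_age <- sort(runif(60, 0, 85))
  dis_age <- sort(runif(40, 18, 85))
  bump <- function(a) 1.5 * exp(-(a - 10)^2 / 8) * (a > 5)
  y_c <- module_trajectory(base, ctrl_age) + rnorm(60, 0, 0.5)
  y_d <- module_trajectory(base, dis_age) + bump(dis_age) +
    rnorm(40, 0, 0.5)
  fit2 <- perturbation_fit(ctrl_age, y_c, dis_age, y_d, seed = 3)
  early <- fit2$tau_grid < 18
  expect_lt(max(fit2$posterior[early]), 0.1)
})

test_that("the scan table covers every spot x disease pair", {
  ch <- generate_cohort(cohort_config(
    n_genes = 200, n_modules = 1, genes_per_module = 20,
    n_control = 25, n_disease = c(SCZ = 12, BD = 12),
    perturbations = data.frame(
      module = 1, disease = "SCZ", tau = 30, amplitude = 1.5
    ),
    seed = 4
  ))
  X <- center_genes(ch$expr)
  expr <- rbind(
    M = colMeans(X[ch$truth$modules[[1]], ]),
    bg = colMeans(X[ch$truth$background[1:20], ])
  )
  scan <- perturbation_scan(expr, ch$meta, grid_size = 30, restarts = 2)
  expect_equal(nrow(scan$table), 4)
  expect_setequal(
    paste(scan$table$spot, scan$table$disease),
    c("M SCZ", "M BD", "bg SCZ", "bg BD")
  )
  expect_gt(
    scan$table$lr[scan$table$spot == "M" & scan$table$disease == "SCZ"], 1
  )
})
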
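# Shared fixtures, all generated in code at test time.

# Tiny clean cohort: no nuisance effects, known planted structure.
clean_config <- function(n_genes = 120, n_modules = 2, genes_per_module = 15,
                         n_control = 20, n_disease = c(SCZ = 10),
                         noise_sd = 0, perturbations = NULL, seed = 1L,
                         ...) {
  cohort_config(
    n_genes = n_genes, n_modules = n_modules,
    genes_per_module = genes_per_module,
    n_control = n_control, n_disease = n_disease,
    noise_sd = noise_sd,
    perturbations = perturbations,
    batch_effect = 0, sex_effect = 0, ph_effect = 0, pmi_effect = 0,
    seed = seed, ...
  )
}

empty_perturbations <- function() {
  data.frame(
    module = integer(0), disease = character(0),
    tau = numeric(0), amplitude = numeric(0)
  )
}

# Two well-separated gene clusters for SOM oracle tests.
two_cluster_profiles <- function(n_per = 40, m = 12, sep = 4, sd = 0.3,
                                 seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n_per * m, sep / 2, sd), n_per),
    matrix(rnorm(n_per * m, -sep / 2, sd), n_per)
  )
  rownames(X) <- sprintf("g%03d", seq_len(2 * n_per))
  colnames(X) <- sprintf("s%02d", seq_len(m))
  attr(X, "cluster") <- rep(1:2, each = n_per)
  X
}

# Independent dense multivariate-normal log-density (generic solve and
# log-determinant; deliberately avoids the Cholesky path under test).
mvn_logdensity_oracle <- function(y, K) {
  n <- length(y)
  -0.5 * drop(t(y) %*% solve(K, y)) -
    0.5 * as.numeric(determinant(K, logarithm = TRUE)$modulus) -
    n / 2 * log(2 * pi)
}

# Brute-force one-tailed hypergeometric upper tail via binomial coefficients.
hyper_tail_oracle <- function(overlap, set_size, spot_size, universe_size) {
  xs <- overlap:min(set_size, spot_size)
  num <- choose(set_size, xs) *
    choose(universe_size - set_size, spot_size - xs)
  sum(num) / choose(universe_size, spot_size)
}

# Grid adjacency test for metagene indices (1-based row-major on k x k).
cells_adjacent <- function(i, j, k) {
  ri <- (i - 1) %/% k
  ci <- (i - 1) %% k
  rj <- (j - 1) %/% k
  cj <- (j - 1) %% k
  max(abs(ri - rj), abs(ci - cj)) == 1
}
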
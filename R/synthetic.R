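#' Configure a synthetic age-structured cohort
#'
#' Builds the configuration for [generate_cohort()]: planted co-expressed
#' modules with smooth age trajectories, per-disease perturbation times,
#' nuisance covariate effects and Gaussian noise. Defaults emulate a
#' post-mortem brain cohort: control ages span (0, 100] years drawn from a
#' mixture mirroring the published per-age-group counts, disease ages are
#' uniform on [18, 85] (cases are never sampled before the age of onset),
#' and planted divergence amplitudes are three times the noise standard
#' deviation.
#'
#' @param n_genes Total genes (modules plus constant background).
#' @param n_modules Number of planted co-expressed modules.
#' @param genes_per_module Genes per planted module.
#' @param n_control Control samples.
#' @param n_disease Named integer vector of samples per disease arm.
#' @param trajectories List of length `n_modules`; each element a list with
#'   `family` in `c("constant", "logistic-decline", "logistic-rise", "peak")`
#'   and family parameters (`midpoint`, `scale`, `low`, `high`, `amplitude`,
#'   `width`, `level`). `NULL` picks a default rotation of families.
#' @param perturbations Data frame with columns `module`, `disease`, `tau`
#'   (years, in \[0, 100\]), `amplitude` (signed log2 divergence). `NULL`
#'   plants one perturbation per module cycling over diseases and
#'   early/mid/late `tau`; pass a zero-row data frame for no perturbations.
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @param rise_scale Years over which the divergence half-sigmoid rises.
#' @param n_batches Number of batch levels (assigned round-robin).
#' @param batch_effect,sex_effect,ph_effect,pmi_effect Nuisance effect sizes
#'   (log2 units per level, per pH unit, per PMI hour).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 2000,
                          n_modules = 5,
                          genes_per_module = 50,
                          n_control = 60,
                          n_disease = c(SCZ = 30, BD = 30, MDD = 30),
                          trajectories = NULL,
                          perturbations = NULL,
                          noise_sd = 0.5,
                          rise_scale = 5,
                          n_batches = 4,
                          batch_effect = 0.3,
                          sex_effect = 0.2,
                          ph_effect = 0.3,
                          pmi_effect = 0.01,
                          seed = 1L) {
  if (n_modules * genes_per_module > n_genes) {
    stop("n_modules * genes_per_module exceeds n_genes")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(names(n_disease)) || any(names(n_disease) == "")) {
    stop("n_disease must be a named vector of disease arms")
  }
  if (is.null(trajectories)) {
    fams <- rep(
      c("logistic-decline", "logistic-rise", "peak"),
      length.out = n_modules
    )
    trajectories <- lapply(seq_len(n_modules), function(m) {
      list(
        family = fams[m],
        midpoint = 20 + 10 * ((m - 1) %% 4), scale = 12,
        low = -1, high = 1, amplitude = 1.5, width = 15
      )
    })
  }
  if (length(trajectories) != n_modules) {
    stop("trajectories must have one entry per module")
  }
  if (is.null(perturbations)) {
    dx <- rep(names(n_disease), length.out = n_modules)
    taus <- rep(c(5, 30, 60), length.out = n_modules)
    perturbations <- data.frame(
      module = seq_len(n_modules),
      disease = dx,
      tau = taus,
      amplitude = 3 * noise_sd * rep_len(c(1, -1), n_modules),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(perturbations) > 0) {
    if (any(perturbations$tau < 0 | perturbations$tau > 100)) {
      stop("perturbation tau outside [0, 100] years")
    }
    if (any(!perturbations$module %in% seq_len(n_modules))) {
      stop("perturbation table references unknown module")
    }
    if (any(!perturbations$disease %in% names(n_disease))) {
      stop("perturbation table references unknown disease arm")
    }
    if (anyDuplicated(perturbations[, c("module", "disease")])) {
      stop("duplicated (module, disease) rows in perturbation table")
    }
  }
  structure(
    list(
      n_genes = n_genes, n_modules = n_modules,
      genes_per_module = genes_per_module,
      n_control = n_control, n_disease = n_disease,
      trajectories = trajectories, perturbations = perturbations,
      noise_sd = noise_sd, rise_scale = rise_scale,
      n_batches = n_batches, batch_effect = batch_effect,
      sex_effect = sex_effect, ph_effect = ph_effect,
      pmi_effect = pmi_effect, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Evaluate a module's baseline age trajectory
#'
#' @param traj Trajectory spec (see [cohort_config()]).
#' @param age Ages in years.
#' @return Baseline log2 expression at each age.
#' @export
module_trajectory <- function(traj, age) {
  switch(traj$family,
    "constant" = rep((traj$level %||% 0), length(age)),
    "logistic-decline" = traj$high + (traj$low - traj$high) *
      stats::plogis((age - traj$midpoint) / traj$scale),
    "logistic-rise" = traj$low + (traj$high - traj$low) *
      stats::plogis((age - traj$midpoint) / traj$scale),
    "peak" = traj$amplitude *
      exp(-(age - traj$midpoint)^2 / (2 * traj$width^2)),
    stop("unknown trajectory family: ", traj$family)
  )
}

#' Divergence ramp of a perturbed module
#'
#' The planted disease-minus-control difference: exactly zero for ages at or
#' below the perturbation time `tau`, then a smooth half-sigmoid
#' `amplitude * (2 * plogis((age - tau) / rise_scale) - 1)` rising from 0
#' towards `amplitude`. Continuity at `tau` matches the branch-point model's
#' assumption that trajectories coincide before the perturbation.
#'
#' @param age Ages in years.
#' @param tau Perturbation time in years.
#' @param amplitude Signed asymptotic divergence (log2 units).
#' @param rise_scale Rise scale in years.
#' @return Divergence at each age.
#' @export
divergence_ramp <- function(age, tau, amplitude, rise_scale = 5) {
  ifelse(
    age > tau,
    amplitude * (2 * stats::plogis((age - tau) / rise_scale) - 1),
    0
  )
}

# Control ages: bin mixture weighted by the published control counts, uniform
# within each bin. Disease ages: uniform on [18, 85].
sample_control_ages <- function(n) {
  bins <- age_bins()
  w <- c(26, 12, 15, 37, 59, 6, 56, 33, 9)
  idx <- sample.int(nrow(bins), n, replace = TRUE, prob = w / sum(w))
  stats::runif(n, bins$lower[idx], bins$upper[idx])
}

#' Generate a synthetic expression cohort with planted structure
#'
#' Simulates a gene-by-sample log2 expression matrix in which each planted
#' module's genes share a smooth baseline age trajectory; samples from a
#' perturbed (module, disease) pair additionally follow the divergence ramp
#' of [divergence_ramp()] after the planted perturbation time. Per-sample
#' nuisance offsets (batch, sex, pH, post-mortem interval) and i.i.d.
#' Gaussian noise are added on top; background genes have constant (zero)
#' baseline.
#'
#' @param config A [cohort_config()].
#' @return List with elements `expr` (genes x samples matrix), `meta`
#'   (sample metadata data frame with `sample`, `diagnosis`, `age`, `sex`,
#'   `pH`, `PMI`, `batch`), and `truth` (planted modules, perturbation table,
#'   trajectories and per-sample nuisance offsets).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_genes = 200, n_modules = 2,
#'   genes_per_module = 20, n_control = 20, n_disease = c(SCZ = 10)
#' ))
#' dim(cohort$expr)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n_dis <- sum(config$n_disease)
    n_samples <- config$n_control + n_dis
    diagnosis <- c(
      rep("CNTRL", config$n_control),
      rep(names(config$n_disease), config$n_disease)
    )
    age <- c(
      sample_control_ages(config$n_control),
      stats::runif(n_dis, 18, 85)
    )
    meta <- data.frame(
      sample = sprintf("S%04d", seq_len(n_samples)),
      diagnosis = diagnosis,
      age = age,
      sex = sample(c("M", "F"), n_samples, replace = TRUE),
      pH = stats::rnorm(n_samples, 6.5, 0.25),
      PMI = stats::runif(n_samples, 5, 40),
      batch = sprintf(
        "B%d", ((seq_len(n_samples) - 1) %% config$n_batches) + 1
      ),
      stringsAsFactors = FALSE
    )

    batch_levels <- sprintf("B%d", seq_len(config$n_batches))
    batch_offsets <- if (config$n_batches > 1) {
      seq(-config$batch_effect, config$batch_effect,
        length.out = config$n_batches
      )
    } else {
      0
    }
    names(batch_offsets) <- batch_levels
    nuisance <- batch_offsets[meta$batch] +
      config$sex_effect * ifelse(meta$sex == "M", 0.5, -0.5) +
      config$ph_effect * (meta$pH - 6.5) +
      config$pmi_effect * (meta$PMI - 22.5)
    nuisance <- as.numeric(nuisance)

    genes <- sprintf("G%05d", seq_len(config$n_genes))
    modules <- lapply(seq_len(config$n_modules), function(m) {
      genes[((m - 1) * config$genes_per_module + 1):
      (m * config$genes_per_module)]
    })
    names(modules) <- sprintf("M%d", seq_len(config$n_modules))

    # Per-sample signal for each module: baseline trajectory plus (for
    # perturbed arms) the post-tau divergence ramp.
    signal <- matrix(0, config$n_modules, n_samples)
    for (m in seq_len(config$n_modules)) {
      signal[m, ] <- module_trajectory(config$trajectories[[m]], meta$age)
    }
    pt <- config$perturbations
    if (nrow(pt) > 0) {
      for (r in seq_len(nrow(pt))) {
        hit <- meta$diagnosis == pt$disease[r]
        signal[pt$module[r], hit] <- signal[pt$module[r], hit] +
          divergence_ramp(
            meta$age[hit], pt$tau[r], pt$amplitude[r], config$rise_scale
          )
      }
    }

    expr <- matrix(0, config$n_genes, n_samples,
      dimnames = list(genes, meta$sample)
    )
    for (m in seq_len(config$n_modules)) {
      rows <- match(modules[[m]], genes)
      expr[rows, ] <- matrix(signal[m, ],
        length(rows), n_samples,
        byrow = TRUE
      )
    }
    expr <- sweep(expr, 2, nuisance, "+")
    if (config$noise_sd > 0) {
      expr <- expr + matrix(
        stats::rnorm(length(expr), 0, config$noise_sd),
        nrow(expr), ncol(expr)
      )
    }

    truth <- list(
      modules = modules,
      perturbations = pt,
      trajectories = config$trajectories,
      nuisance = stats::setNames(nuisance, meta$sample),
      background = setdiff(genes, unlist(modules))
    )
    list(expr = expr, meta = meta, truth = truth)
  })
}

#' Gene sets matching a synthetic cohort's planted modules
#'
#' One gene set per planted module (identical to the module's gene list) plus
#' random decoy sets drawn from the background genes, mimicking a curated
#' functional-category collection for overrepresentation tests.
#'
#' @param truth `truth` element of [generate_cohort()] output.
#' @param extra_random_sets Number of decoy sets.
#' @param decoy_size Genes per decoy set.
#' @param seed Integer seed.
#' @return Named list of gene-id vectors (a GMT-serializable collection).
#' @export
generate_genesets <- function(truth, extra_random_sets = 10,
                              decoy_size = 50, seed = 1L) {
  if (length(truth$modules) == 0) stop("truth has no planted modules")
  if (decoy_size > length(truth$background)) {
    stop("decoy_size exceeds the number of background genes")
  }
  sets <- truth$modules
  names(sets) <- paste0("module_", names(truth$modules))
  with_seed(seed, {
    for (i in seq_len(extra_random_sets)) {
      sets[[sprintf("decoy_%02d", i)]] <-
        sample(truth$background, decoy_size)
    }
  })
  sets
}

#' Binary eQTL flag table for a synthetic cohort
#'
#' Flags each gene as carrying a cis-eQTL in each tissue, with genes of
#' enriched (module, tissue) pairs flagged at `enriched_rate` and all other
#' gene/tissue combinations at `baseline_rate`.
#'
#' @param truth `truth` element of [generate_cohort()] output.
#' @param universe Character vector of all gene ids (rows of the table).
#' @param n_tissues Number of tissues.
#' @param enriched_pairs Data frame with columns `module` (name in
#'   `truth$modules`) and `tissue` (index or `T<i>` name).
#' @param baseline_rate,enriched_rate Flag probabilities in \[0, 1\].
#' @param seed Integer seed.
#' @return Integer 0/1 matrix, genes x tissues.
#' @export
generate_eqtl_table <- function(truth, universe,
                                n_tissues = 5,
                                enriched_pairs = data.frame(
                                  module = names(truth$modules)[1],
                                  tissue = 1
                                ),
                                baseline_rate = 0.1,
                                enriched_rate = 0.9,
                                seed = 1L) {
  if (baseline_rate < 0 || baseline_rate > 1 ||
    enriched_rate < 0 || enriched_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  tissues <- sprintf("T%d", seq_len(n_tissues))
  with_seed(seed, {
    flags <- matrix(
      stats::rbinom(length(universe) * n_tissues, 1, baseline_rate),
      length(universe), n_tissues,
      dimnames = list(universe, tissues)
    )
    if (!is.null(enriched_pairs) && nrow(enriched_pairs) > 0) {
      for (r in seq_len(nrow(enriched_pairs))) {
        mod <- as.character(enriched_pairs$module[r])
        if (!mod %in% names(truth$modules)) {
          stop("unknown module id: ", mod)
        }
        tis <- enriched_pairs$tissue[r]
        tis <- if (is.numeric(tis)) tissues[tis] else as.character(tis)
        rows <- match(truth$modules[[mod]], universe)
        if (anyNA(rows)) stop("module genes missing from universe")
        flags[rows, tis] <- stats::rbinom(length(rows), 1, enriched_rate)
      }
    }
    flags
  })
}

#' Simulate one spot time-course pair
#'
#' Control and disease (age, expression) points for a single module: a smooth
#' logistic baseline shared by both arms, plus the divergence ramp after
#' `tau` in the disease arm, plus Gaussian noise. Disease sampling starts at
#' 18 years (post-onset sampling), controls span the full age range.
#'
#' @param tau Perturbation time in years, or `NA` for a null (no-divergence)
#'   course.
#' @param amplitude Signed divergence amplitude.
#' @param noise_sd Noise standard deviation.
#' @param n_control,n_disease Points per arm.
#' @param age_range Control age range (years).
#' @param disease_min_age Youngest disease age (years).
#' @param rise_scale Ramp rise scale in years.
#' @param baseline Trajectory spec for the shared baseline.
#' @param seed Integer seed.
#' @return List with `ctrl_age`, `ctrl_y`, `dis_age`, `dis_y`, `tau`,
#'   `amplitude`.
#' @export
simulate_timecourse <- function(tau, amplitude = 1.5, noise_sd = 0.5,
                                n_control = 60, n_disease = 40,
                                age_range = c(0, 85), disease_min_age = 18,
                                rise_scale = 5,
                                baseline = list(
                                  family = "logistic-decline",
                                  midpoint = 35, scale = 15,
                                  low = -1, high = 1
                                ),
                                seed = 1L) {
  with_seed(seed, {
    ctrl_age <- sort(stats::runif(n_control, age_range[1], age_range[2]))
    dis_age <- sort(stats::runif(n_disease, disease_min_age, age_range[2]))
    ctrl_y <- module_trajectory(baseline, ctrl_age) +
      stats::rnorm(n_control, 0, noise_sd)
    dis_y <- module_trajectory(baseline, dis_age) +
      stats::rnorm(n_disease, 0, noise_sd)
    if (!is.na(tau)) {
      dis_y <- dis_y + divergence_ramp(dis_age, tau, amplitude, rise_scale)
    }
    list(
      ctrl_age = ctrl_age, ctrl_y = ctrl_y,
      dis_age = dis_age, dis_y = dis_y,
      tau = tau, amplitude = amplitude
    )
  })
}
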
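#' Configure an end-to-end pipeline run
#'
#' Exactly one of `synthetic` (a [cohort_config()]) or the pair
#' `expr_path` / `meta_path` must be supplied.
#'
#' @param synthetic Optional [cohort_config()] for a simulated cohort.
#' @param expr_path,meta_path Optional paths to a tab-separated expression
#'   matrix and metadata table.
#' @param gmt_path Optional GMT gene-set collection for spot annotation.
#' @param eqtl_path Optional gene x tissue eQTL flag table.
#' @param nuisance Metadata columns residualized out before centering.
#' @param som_k SOM grid side.
#' @param som_epochs SOM training epochs.
#' @param spot_quantile,spot_min_size,adjacency Spot segmentation settings.
#' @param tau_grid_size Perturbation-time grid size.
#' @param lr_cutoff Likelihood-ratio cut-off for the timeline report.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for run artifacts.
#' @param write_figures Render PNG portraits and perturbation plots.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL,
                            expr_path = NULL, meta_path = NULL,
                            gmt_path = NULL, eqtl_path = NULL,
                            nuisance = c("batch", "sex", "pH", "PMI"),
                            som_k = 20, som_epochs = 40,
                            spot_quantile = 0.9, spot_min_size = 3,
                            adjacency = 8,
                            tau_grid_size = 50, lr_cutoff = 1,
                            seed = 1L, out_dir = tempfile("somperturb_run_"),
                            write_figures = FALSE) {
  has_real <- !is.null(expr_path) || !is.null(meta_path)
  if (!is.null(synthetic) && has_real) {
    stop("provide either a synthetic cohort config or real input paths, ",
      "not both")
  }
  if (is.null(synthetic) && !(!is.null(expr_path) && !is.null(meta_path))) {
    stop("real inputs need both expr_path and meta_path")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "cohort_config"))
  if (som_k < 1 || som_epochs < 1) stop("som_k and som_epochs must be >= 1")
  if (spot_quantile <= 0 || spot_quantile >= 1) {
    stop("spot_quantile must be in (0, 1)")
  }
  if (tau_grid_size < 2) stop("tau_grid_size must be >= 2")
  structure(
    list(
      synthetic = synthetic, expr_path = expr_path, meta_path = meta_path,
      gmt_path = gmt_path, eqtl_path = eqtl_path, nuisance = nuisance,
      som_k = som_k, som_epochs = som_epochs,
      spot_quantile = spot_quantile, spot_min_size = spot_min_size,
      adjacency = adjacency, tau_grid_size = tau_grid_size,
      lr_cutoff = lr_cutoff, seed = as.integer(seed),
      out_dir = out_dir, write_figures = write_figures
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — cohort generation or loading, covariate
#' adjustment, gene centering, SOM training, summary maps, spot
#' segmentation, gene-set annotation, differential expression,
#' perturbation-time inference, eQTL enrichment, timeline report — writing
#' each artifact as tab-separated text or JSON under the configured output
#' directory, together with a manifest (inputs, settings, seed, package
#' version). Re-running with an identical configuration reproduces all
#' non-image outputs bit-identically; a stage failure aborts with the stage
#' name after persisting the partial manifest.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run directory and all in-memory stage
#'   results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "somperturb",
    version = as.character(utils::packageVersion("somperturb")),
    seed = config$seed,
    settings = config[c(
      "nuisance", "som_k", "som_epochs", "spot_quantile",
      "spot_min_size", "adjacency", "tau_grid_size", "lr_cutoff"
    )],
    input = if (is.null(config$synthetic)) {
      list(expr = config$expr_path, meta = config$meta_path)
    } else {
      list(synthetic = unclass(
        config$synthetic[setdiff(
          names(config$synthetic), c("trajectories", "perturbations")
        )]
      ))
    },
    stages = character(0)
  )
  save_manifest <- function() {
    jsonlite::write_json(
      manifest, file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
    )
  }
  stage <- function(name, expr) {
    message(sprintf("[%s] stage: %s", format(Sys.time(), "%H:%M:%S"), name))
    out <- tryCatch(expr, error = function(e) {
      save_manifest()
      stop("pipeline failed in stage '", name, "': ",
        conditionMessage(e),
        call. = FALSE
      )
    })
    manifest$stages <<- c(manifest$stages, name)
    out
  }
  tsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }

  # --- input -------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$synthetic)) {
    cohort <- stage("simulate", generate_cohort(config$synthetic))
    expr <- cohort$expr
    meta <- cohort$meta
    truth <- cohort$truth
    write_matrix(expr, file.path(config$out_dir, "expression.tsv"))
    write_metadata(meta, file.path(config$out_dir, "metadata.tsv"))
  } else {
    expr <- stage("read", read_matrix(config$expr_path))
    meta <- read_metadata(config$meta_path)
    if (!all(meta$sample == colnames(expr))) {
      stop("metadata samples do not match expression columns")
    }
  }
  genesets <- if (!is.null(config$gmt_path)) {
    read_gmt(config$gmt_path)
  } else if (!is.null(truth)) {
    generate_genesets(truth, seed = config$seed + 101L)
  }
  eqtl <- if (!is.null(config$eqtl_path)) {
    read_eqtl(config$eqtl_path)
  } else if (!is.null(truth)) {
    generate_eqtl_table(truth, rownames(expr), seed = config$seed + 202L)
  }

  # --- preprocess --------------------------------------------------------
  centered <- stage("preprocess", {
    adjusted <- adjust_covariates(
      expr, meta, intersect(config$nuisance, names(meta))
    )
    center_genes(adjusted)
  })
  meta$age_group <- as.character(assign_age_groups(meta$age))
  write_metadata(meta, file.path(config$out_dir, "metadata.tsv"))

  # --- SOM ---------------------------------------------------------------
  som <- stage("som", som_fit(
    centered, config$som_k,
    epochs = config$som_epochs, seed = config$seed + 303L
  ))
  write_matrix(
    som$weights,
    file.path(config$out_dir, "metagene_weights.tsv"),
    id_col = "metagene"
  )

  # --- spots -------------------------------------------------------------
  maps <- stage("spots", summary_maps(som, meta$diagnosis))
  spots <- segment_spots(
    maps$variance, config$spot_quantile, config$spot_min_size,
    config$adjacency,
    model = som
  )
  spot_expr <- spot_profiles(spots, som)
  tsv(
    data.frame(
      spot = vapply(spots, `[[`, "", "label"),
      n_metagenes = vapply(spots, function(s) length(s$metagenes), 0L),
      metagenes = vapply(
        spots, function(s) paste(s$metagenes, collapse = ","), ""
      ),
      genes = vapply(spots, function(s) paste(s$genes, collapse = ","), "")
    ),
    "spots.tsv"
  )
  write_matrix(
    spot_expr, file.path(config$out_dir, "spot_expression.tsv"),
    id_col = "spot"
  )

  # --- annotation --------------------------------------------------------
  annot <- NULL
  if (!is.null(genesets) && length(spots) > 0) {
    annot <- stage("annotate", {
      a <- annotate_spots(spots, genesets, rownames(centered))
      z <- t(vapply(
        genesets, function(set) geneset_zscore(centered, set),
        numeric(ncol(centered))
      ))
      links <- correlate_celltypes(spot_expr, z)
      tsv(a, "spot_enrichment.tsv")
      tsv(links$edges, "celltype_links.tsv")
      list(enrichment = a, zscores = z, links = links)
    })
  }

  # --- differential expression ------------------------------------------
  diseases <- setdiff(unique(meta$diagnosis), "CNTRL")
  de <- stage("diffexp", {
    counts <- deg_counts(centered, meta, diseases)
    sd_rows <- do.call(rbind, lapply(diseases, function(dx) {
      spot_diff(spot_expr, meta, dx)
    }))
    tsv(counts, "deg_counts.tsv")
    if (!is.null(sd_rows)) tsv(sd_rows, "spot_diff.tsv")
    list(deg_counts = counts, spot_diff = sd_rows)
  })

  # --- perturbation time -------------------------------------------------
  scan <- stage("perturb", perturbation_scan(
    spot_expr, meta, diseases,
    grid_size = config$tau_grid_size, seed = config$seed + 404L
  ))
  tsv(scan$table, "perturbation.tsv")
  jsonlite::write_json(
    lapply(scan$fits, function(f) {
      list(tau_grid = f$tau_grid, posterior = f$posterior)
    }),
    file.path(config$out_dir, "perturbation_posteriors.json"),
    digits = NA
  )

  # --- eQTL enrichment and timeline -------------------------------------
  timeline <- NULL
  if (!is.null(eqtl) && length(spots) > 0) {
    timeline <- stage("enrich", {
      enr <- eqtl_enrichment(spots, eqtl, rownames(centered))
      tl <- select_perturbed_enriched(
        scan$table, enr, de$spot_diff,
        lr_cutoff = config$lr_cutoff
      )
      tsv(enr, "eqtl_enrichment.tsv")
      tsv(tl, "timeline.tsv")
      list(enrichment = enr, timeline = tl)
    })
  }

  # --- figures -----------------------------------------------------------
  if (config$write_figures) {
    stage("figures", {
      grDevices::png(
        file.path(config$out_dir, "group_portraits.png"),
        width = 300 * length(unique(meta$diagnosis)), height = 320
      )
      graphics::par(mfrow = c(1, length(unique(meta$diagnosis))))
      for (g in unique(meta$diagnosis)) {
        ps <- lapply(
          meta$sample[meta$diagnosis == g],
          function(s) sample_portrait(som, s)
        )
        plot(group_portrait(ps, label = g))
      }
      grDevices::dev.off()
      grDevices::png(file.path(config$out_dir, "variance_map.png"),
        width = 320, height = 320
      )
      plot(maps$variance)
      grDevices::dev.off()
      for (nm in names(scan$fits)) {
        grDevices::png(
          file.path(config$out_dir, paste0("perturbation_", nm, ".png")),
          width = 480, height = 480
        )
        plot(scan$fits[[nm]], main = nm)
        grDevices::dev.off()
      }
      invisible(NULL)
    })
  }

  save_manifest()
  invisible(list(
    out_dir = config$out_dir,
    expr = centered, meta = meta, truth = truth,
    som = som, maps = maps, spots = spots, spot_expr = spot_expr,
    annotation = annot, diffexp = de, perturbation = scan,
    timeline = timeline
  ))
}
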
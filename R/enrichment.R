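#' eQTL tissue enrichment of spot gene lists
#'
#' For every spot x tissue pair, tests whether the spot's genes are enriched
#' for eQTL-flagged genes in that tissue with a one-tailed Fisher exact test
#' (hypergeometric upper tail) on the 2x2 table of spot membership by eQTL
#' flag over the gene universe. P-values are Bonferroni-corrected across the
#' tissue family per spot; a pair is enriched iff the adjusted p < `alpha`.
#'
#' @param spots A [segment_spots()] result with member genes.
#' @param eqtl Binary gene x tissue flag matrix (rownames = gene ids).
#' @param universe Gene universe; defaults to the rows of `eqtl`.
#' @param family Bonferroni family size; defaults to the number of tissues.
#' @param alpha Significance level on the adjusted p.
#' @return Data frame: `spot`, `tissue`, 2x2 counts, `odds_ratio`, `p`,
#'   `p_adj`, `enriched`.
#' @export
eqtl_enrichment <- function(spots, eqtl, universe = rownames(eqtl),
                            family = ncol(eqtl), alpha = 0.05) {
  if (is.null(colnames(eqtl)) || ncol(eqtl) == 0) {
    stop("eqtl table must have named tissue columns")
  }
  if (!all(eqtl %in% c(0, 1))) stop("eqtl flags must be 0/1")
  rows <- list()
  for (s in spots) {
    if (is.null(s$genes) || length(s$genes) == 0) {
      stop("spot ", s$label, " has an empty gene list")
    }
    for (tis in colnames(eqtl)) {
      flagged <- universe[eqtl[universe, tis] == 1]
      rec <- fisher_overrepresentation(
        intersect(s$genes, universe), flagged, universe
      )
      p_adj <- min(1, rec$p * family)
      rows[[length(rows) + 1]] <- data.frame(
        spot = s$label, tissue = tis,
        t(rec$counts),
        odds_ratio = rec$odds_ratio,
        p = rec$p, p_adj = p_adj,
        enriched = p_adj < alpha,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Timeline of time-perturbed, eQTL-enriched modules
#'
#' Joins the perturbation-scan results passing the likelihood-ratio cut-off
#' with their enriched tissues (and, optionally, the direction of the
#' age-adjusted disease effect), producing the timeline report of perturbed
#' modules.
#'
#' @param perturbation Data frame with `spot`, `disease`, `map_tau`, `lr`
#'   ([perturbation_scan()] `table`).
#' @param enrichment [eqtl_enrichment()] output.
#' @param spot_diffs Optional [spot_diff()] output supplying the direction
#'   of the diagnosis coefficient.
#' @param lr_cutoff Keep spots with `lr > lr_cutoff` (strict; default 1).
#' @return Data frame: `spot`, `disease`, `map_tau`, `lr`, `direction`,
#'   `enriched_tissues` (comma-separated, empty if none), sorted by
#'   `map_tau`.
#' @export
select_perturbed_enriched <- function(perturbation, enrichment,
                                      spot_diffs = NULL, lr_cutoff = 1) {
  need <- c("spot", "disease", "map_tau", "lr")
  if (!all(need %in% names(perturbation))) {
    stop("perturbation table lacks columns: ",
      paste(setdiff(need, names(perturbation)), collapse = ", "))
  }
  hits <- perturbation[perturbation$lr > lr_cutoff, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(
      spot = character(), disease = character(),
      map_tau = numeric(), lr = numeric(),
      direction = numeric(), enriched_tissues = character(),
      stringsAsFactors = FALSE
    ))
  }
  if (!all(hits$spot %in% enrichment$spot)) {
    stop("spots missing from the enrichment table: ",
      paste(setdiff(hits$spot, enrichment$spot), collapse = ", "))
  }
  tissues <- vapply(hits$spot, function(sp) {
    e <- enrichment[enrichment$spot == sp & enrichment$enriched, ]
    paste(e$tissue, collapse = ",")
  }, character(1))
  direction <- rep(NA_real_, nrow(hits))
  if (!is.null(spot_diffs)) {
    key <- paste(hits$spot, hits$disease)
    m <- match(key, paste(spot_diffs$spot, spot_diffs$disease))
    direction <- sign(spot_diffs$coefficient[m])
  }
  out <- data.frame(
    spot = hits$spot, disease = hits$disease,
    map_tau = hits$map_tau, lr = hits$lr,
    direction = direction,
    enriched_tissues = tissues,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$map_tau, out$spot), , drop = FALSE]
  rownames(out) <- NULL
  out
}
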
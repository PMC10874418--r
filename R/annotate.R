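#' Gene Set Z-score per sample
#'
#' Standardized mean shift of a gene set's centered expression relative to
#' all genes: for each sample, `Z = (mean(set) - mean(all)) /
#' (sd(all) / sqrt(n_set))`, with `n_set` counted over set genes present in
#' the matrix and `sd` the sample standard deviation over all genes. Used to
#' project cell-type signatures and functional categories onto a cohort.
#'
#' @param X Centered numeric matrix, genes x samples.
#' @param set Character vector of gene ids.
#' @return Named numeric vector of Z-scores, one per sample.
#' @export
geneset_zscore <- function(X, set) {
  genes <- intersect(set, rownames(X))
  if (length(genes) == 0) stop("gene set has no genes in the matrix")
  n_set <- length(genes)
  set_mean <- colMeans(X[genes, , drop = FALSE])
  all_mean <- colMeans(X)
  all_sd <- apply(X, 2, stats::sd)
  (set_mean - all_mean) / (all_sd / sqrt(n_set))
}

#' One-tailed Fisher overrepresentation of a gene set in a spot
#'
#' Tests whether a spot's gene list is enriched for a gene set, using the
#' hypergeometric upper tail (one-tailed Fisher exact test in the enrichment
#' direction) on the 2x2 table of spot membership by set membership over the
#' gene universe. The odds ratio is the plain cross-product ratio with no
#' continuity correction.
#'
#' @param spot_genes Character vector of spot member genes (subset of
#'   `universe`).
#' @param set Character vector of gene-set genes (intersected with
#'   `universe`).
#' @param universe Character vector of all genes under consideration.
#' @return List with `counts` (named: `in_spot_in_set`, `in_spot_out_set`,
#'   `out_spot_in_set`, `out_spot_out_set`), `odds_ratio` and `p`.
#' @export
fisher_overrepresentation <- function(spot_genes, set, universe) {
  if (length(universe) == 0) stop("empty universe")
  spot_genes <- unique(spot_genes)
  if (!all(spot_genes %in% universe)) {
    stop("spot genes must be a subset of the universe")
  }
  set <- intersect(unique(set), universe)
  a <- length(intersect(spot_genes, set))
  b <- length(spot_genes) - a
  cc <- length(set) - a
  d <- length(universe) - a - b - cc
  p <- stats::phyper(
    a - 1,
    m = length(set), n = length(universe) - length(set),
    k = length(spot_genes), lower.tail = FALSE
  )
  list(
    counts = c(
      in_spot_in_set = a, in_spot_out_set = b,
      out_spot_in_set = cc, out_spot_out_set = d
    ),
    odds_ratio = (a * d) / (b * cc),
    p = p
  )
}

#' Annotate every spot against a gene-set collection
#'
#' Runs [fisher_overrepresentation()] for each spot x set pair and adjusts
#' p-values across sets within each spot by Benjamini-Hochberg.
#'
#' @param spots A [segment_spots()] result with member genes.
#' @param collection Named list of gene-id vectors (e.g. from [read_gmt()]
#'   or [generate_genesets()]).
#' @param universe Gene universe; defaults to all genes assigned to the map
#'   when spots carry genes from a model.
#' @return Data frame of enrichment records: `spot`, `set`, the four 2x2
#'   counts, `odds_ratio`, `p`, `p_adj`.
#' @export
annotate_spots <- function(spots, collection, universe) {
  if (is.null(names(collection)) || anyDuplicated(names(collection))) {
    stop("collection must have unique set names")
  }
  rows <- list()
  for (s in spots) {
    if (is.null(s$genes)) stop("spots carry no gene lists")
    recs <- lapply(collection, function(set) {
      fisher_overrepresentation(s$genes, set, universe)
    })
    p <- vapply(recs, `[[`, numeric(1), "p")
    p_adj <- stats::p.adjust(p, method = "BH")
    rows[[s$label]] <- data.frame(
      spot = s$label,
      set = names(collection),
      t(vapply(recs, function(r) r$counts, numeric(4))),
      odds_ratio = vapply(recs, `[[`, numeric(1), "odds_ratio"),
      p = p,
      p_adj = p_adj,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Correlate cell-type signature scores with spot expression
#'
#' Pearson correlation of every spot x signature pair over matched samples;
#' pairs with `r` strictly greater than the threshold form the reported
#' links.
#'
#' @param spot_expr Matrix, spots x samples ([spot_profiles()]).
#' @param signature_z Matrix, signatures x samples (rows of
#'   [geneset_zscore()] output).
#' @param r_threshold Link threshold; a pair is linked iff `r > r_threshold`
#'   (strict).
#' @return List with `r` (full spot x signature correlation matrix) and
#'   `edges` (data frame `spot`, `signature`, `r` for linked pairs).
#' @export
correlate_celltypes <- function(spot_expr, signature_z, r_threshold = 0.5) {
  if (ncol(spot_expr) != ncol(signature_z) ||
    !all(colnames(spot_expr) == colnames(signature_z))) {
    stop("spot and signature tables must share sample columns")
  }
  const_s <- apply(spot_expr, 1, stats::sd) == 0
  const_g <- apply(signature_z, 1, stats::sd) == 0
  if (any(const_s) || any(const_g)) {
    warning("constant rows skipped: ",
      paste(
        c(rownames(spot_expr)[const_s], rownames(signature_z)[const_g]),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  r <- suppressWarnings(stats::cor(t(spot_expr), t(signature_z)))
  r[const_s, ] <- NA
  r[, const_g] <- NA
  keep <- which(!is.na(r) & r > r_threshold, arr.ind = TRUE)
  edges <- data.frame(
    spot = rownames(r)[keep[, 1]],
    signature = colnames(r)[keep[, 2]],
    r = r[keep],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$spot, edges$signature), , drop = FALSE]
  rownames(edges) <- NULL
  list(r = r, edges = edges)
}
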
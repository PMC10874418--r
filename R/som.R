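#' Train a self-organizing map on gene expression profiles
#'
#' Clusters genes into a `k x k` grid of metagenes by batch self-organizing
#' map training. Each metagene carries an M-length weight profile (its
#' expression across samples); each gene is assigned to its best-matching
#' unit (BMU) under Euclidean distance, and the assignment is shared by all
#' samples, so per-sample portraits are directly comparable. Weights are
#' linearly initialized on the plane of the first two principal components
#' of the gene profiles; training uses a Gaussian grid neighborhood whose
#' radius decays linearly from `radius_init` to `radius_final`.
#'
#' With `radius_final` driven towards zero, the batch update reduces to
#' Lloyd's k-means step: each occupied metagene's weight converges to the
#' centroid of its member genes.
#'
#' @param X Centered numeric matrix, genes x samples (see [center_genes()]).
#' @param k Grid side; the map has `K = k * k` metagenes.
#' @param epochs Number of batch training epochs.
#' @param radius_init,radius_final Neighborhood radius schedule (grid units);
#'   defaults `k / 2` down to 0.5.
#' @param seed Integer seed (training is deterministic given the
#'   initialization; the seed is recorded for provenance).
#' @return An object of class `som_map`: `weights` (K x M, row-major grid
#'   order), `assignment` (named integer vector, gene -> metagene index),
#'   `k`, `K`, `samples`, `genes`, `qe` (mean quantization error per epoch,
#'   including the post-training value), and the training settings.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_genes = 150, n_modules = 2, genes_per_module = 20,
#'   n_control = 15, n_disease = c(SCZ = 10), seed = 7
#' ))
#' som <- som_fit(center_genes(cohort$expr), k = 4, epochs = 10)
#' table(som$assignment) # metagene occupancy
som_fit <- function(X, k, epochs = 40,
                    radius_init = k / 2, radius_final = 0.5,
                    seed = 1L) {
  if (!is.matrix(X) || !is.numeric(X)) stop("X must be a numeric matrix")
  if (!all(is.finite(X))) stop("X contains non-finite values")
  if (k < 1) stop("k must be >= 1")
  n <- nrow(X)
  K <- k * k
  if (K > n) {
    warning("grid has more metagenes (", K, ") than genes (", n,
      "); empty metagenes allowed",
      call. = FALSE
    )
  }
  if (is.null(rownames(X))) rownames(X) <- sprintf("g%d", seq_len(n))

  W <- som_linear_init(X, k)
  grid_d2 <- som_grid_dist2(k)
  radii <- if (epochs > 1) {
    seq(radius_init, radius_final, length.out = epochs)
  } else {
    radius_final
  }

  qe <- numeric(epochs + 1)
  bmu <- integer(n)
  for (e in seq_len(epochs)) {
    D2 <- dist2_cross(X, W)
    bmu <- max.col(-D2, ties.method = "first") # ties -> lowest index
    qe[e] <- mean(sqrt(pmax(D2[cbind(seq_len(n), bmu)], 0)))
    H <- exp(-grid_d2 / (2 * radii[e]^2))
    counts <- tabulate(bmu, nbins = K)
    sums <- matrix(0, K, ncol(X))
    agg <- rowsum(X, bmu)
    sums[as.integer(rownames(agg)), ] <- agg
    denom <- as.numeric(H %*% counts)
    numer <- H %*% sums
    upd <- denom > 1e-12
    W[upd, ] <- numer[upd, , drop = FALSE] / denom[upd]
  }
  D2 <- dist2_cross(X, W)
  bmu <- max.col(-D2, ties.method = "first")
  qe[epochs + 1] <- mean(sqrt(pmax(D2[cbind(seq_len(n), bmu)], 0)))

  dimnames(W) <- list(
    sprintf("MG%04d", seq_len(K)),
    colnames(X) %||% sprintf("s%d", seq_len(ncol(X)))
  )
  structure(
    list(
      weights = W,
      assignment = stats::setNames(bmu, rownames(X)),
      k = k, K = K,
      samples = colnames(X) %||% sprintf("s%d", seq_len(ncol(X))),
      genes = rownames(X),
      qe = qe,
      epochs = epochs,
      radius = c(init = radius_init, final = radius_final),
      seed = as.integer(seed)
    ),
    class = "som_map"
  )
}

# Squared Euclidean distances between rows of A (n x m) and rows of B (K x m).
dist2_cross <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

# Squared grid distances between metagenes; row-major order, row r col c.
som_grid_dist2 <- function(k) {
  rows <- rep(seq_len(k), each = k)
  cols <- rep(seq_len(k), times = k)
  outer(rows, rows, "-")^2 + outer(cols, cols, "-")^2
}

# Linear initialization: grid coordinates mapped affinely onto +/- 2 standard
# deviations along the first two principal axes of the gene profiles.
som_linear_init <- function(X, k) {
  M <- ncol(X)
  center <- colMeans(X)
  if (k == 1) {
    return(matrix(center, 1, M))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  sdev <- pc$sdev
  v1 <- pc$rotation[, 1]
  v2 <- if (ncol(pc$rotation) >= 2) pc$rotation[, 2] else rep(0, M)
  s2 <- if (length(sdev) >= 2) sdev[2] else 0
  a <- seq(-2, 2, length.out = k) * sdev[1] # along grid rows
  b <- seq(-2, 2, length.out = k) * s2 # along grid cols
  rows <- rep(seq_len(k), each = k)
  cols <- rep(seq_len(k), times = k)
  W <- matrix(center, k * k, M, byrow = TRUE) +
    outer(a[rows], v1) + outer(b[cols], v2)
  W
}

#' @export
print.som_map <- function(x, ...) {
  cat(
    "Self-organizing map: ", x$k, "x", x$k, " grid (", x$K,
    " metagenes), ", length(x$assignment), " genes, ",
    length(x$samples), " samples\n",
    sep = ""
  )
  cat(
    "  occupied metagenes: ", length(unique(x$assignment)),
    "; final quantization error: ",
    signif(x$qe[length(x$qe)], 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
plot.som_map <- function(x, sample = x$samples[1], ...) {
  plot(sample_portrait(x, sample), ...)
}

#' Expression portrait of one sample
#'
#' Reshapes the sample's column of the metagene weight matrix into the
#' `k x k` grid: cell (i, j) is the weight of metagene (i, j) for that
#' sample.
#'
#' @param model A [som_fit()] model.
#' @param sample Sample id present in the model's training set.
#' @return A `k x k` matrix of class `portrait` with a `label` attribute.
#' @export
sample_portrait <- function(model, sample) {
  stopifnot(inherits(model, "som_map"))
  j <- match(sample, model$samples)
  if (is.na(j)) stop("unknown sample id: ", sample)
  as_portrait(model$weights[, j], model$k, label = sample)
}

as_portrait <- function(v, k, label = "") {
  structure(matrix(v, k, k, byrow = TRUE), # row-major grid order
    class = c("portrait", "matrix"), label = label
  )
}

#' Mean portrait of a group of samples
#'
#' @param portraits Non-empty list of [sample_portrait()] matrices with equal
#'   grid size.
#' @param label Label for the averaged portrait.
#' @return The element-wise mean portrait.
#' @export
group_portrait <- function(portraits, label = "group") {
  if (length(portraits) == 0) stop("empty portrait list")
  ks <- vapply(portraits, nrow, integer(1))
  if (length(unique(ks)) != 1) stop("mixed portrait grid sizes")
  out <- Reduce(`+`, lapply(portraits, unclass)) / length(portraits)
  structure(out, class = c("portrait", "matrix"), label = label)
}

#' Pearson correlation between two portraits
#'
#' Correlates the flattened metagene values of two portraits, with the
#' two-sided p-value from the t transform, to quantify how closely two
#' transcriptome landscapes resemble each other.
#'
#' @param a,b Portraits of equal grid size.
#' @return List with `r` and `p`.
#' @export
portrait_correlation <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("portraits have different grid sizes")
  va <- as.numeric(a)
  vb <- as.numeric(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("constant portrait: correlation undefined")
  }
  ct <- stats::cor.test(va, vb)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' @export
plot.portrait <- function(x, main = attr(x, "label"),
                          zlim = max(abs(x)) * c(-1, 1), ...) {
  pal <- grDevices::colorRampPalette(
    c("blue", "cyan", "green", "yellow", "red")
  )(255)
  # transpose/flip so row 1 of the grid appears at the top
  img <- t(unclass(x))[, rev(seq_len(nrow(x))), drop = FALSE]
  graphics::image(
    seq_len(ncol(x)), seq_len(nrow(x)), img,
    col = pal, zlim = zlim, axes = FALSE, xlab = "", ylab = "",
    main = main, asp = 1, ...
  )
  invisible(x)
}
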
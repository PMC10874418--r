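#' Remove nuisance-covariate effects from an expression matrix
#'
#' Per-gene ordinary least-squares residualization: expression is regressed
#' on an intercept plus the nuisance design (categorical covariates
#' effect-coded, continuous covariates mean-centered) and the fitted nuisance
#' component is subtracted, so each gene's grand mean is preserved. This
#' reproduces the behaviour of standard batch-removal tools used to
#' harmonize multi-dataset cohorts for batch, sex, pH and post-mortem
#' interval.
#'
#' @param X Numeric matrix, genes x samples.
#' @param meta Sample metadata data frame, one row per column of `X` (in
#'   column order).
#' @param nuisance Character vector of metadata column names to remove.
#' @return Adjusted matrix with the same dimensions and dimnames.
#' @export
#' @examples
#' X <- matrix(c(1, 1, 3, 3), 1, 4, dimnames = list("g1", paste0("s", 1:4)))
#' meta <- data.frame(batch = c("A", "A", "B", "B"))
#' adjust_covariates(X, meta, "batch") # all 2: offset removed, mean kept
adjust_covariates <- function(X, meta,
                              nuisance = c("batch", "sex", "pH", "PMI")) {
  if (!is.matrix(X) || !is.numeric(X)) stop("X must be a numeric matrix")
  if (nrow(meta) != ncol(X)) {
    stop("metadata rows must match expression columns")
  }
  missing_cols <- setdiff(nuisance, names(meta))
  if (length(missing_cols) > 0) {
    stop(
      "nuisance covariates absent from metadata: ",
      paste(missing_cols, collapse = ", ")
    )
  }
  cols <- list()
  for (nm in nuisance) {
    v <- meta[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- matrix(v - mean(v), ncol = 1,
        dimnames = list(NULL, nm)
      )
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) next # single-level covariate carries no signal
      mm <- stats::model.matrix(
        ~f,
        contrasts.arg = list(f = "contr.sum")
      )[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, seq_len(ncol(mm)))
      cols[[nm]] <- mm
    }
  }
  if (length(cols) == 0) {
    return(X)
  }
  D <- cbind(1, do.call(cbind, cols))
  colnames(D)[1] <- "(Intercept)"
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop(
      "rank-deficient nuisance design; collinear columns: ",
      paste(dropped, collapse = ", ")
    )
  }
  beta <- qr.coef(qrD, t(X)) # coefficients x genes
  fitted_nuisance <- D[, -1, drop = FALSE] %*% beta[-1, , drop = FALSE]
  X - t(fitted_nuisance)
}

#' Center genes to log fold changes relative to the cohort mean
#'
#' Subtracts each gene's mean across all samples, giving signed log fold
#' change relative to the gene's cohort average. Idempotent.
#'
#' @param X Numeric matrix, genes x samples, no missing values.
#' @return Matrix with every gene row mean zero.
#' @export
#' @examples
#' center_genes(matrix(c(2, 4, 6), 1, 3))
center_genes <- function(X) {
  if (!is.matrix(X) || length(X) == 0) stop("X must be a non-empty matrix")
  if (anyNA(X)) stop("X contains missing values")
  X - rowMeans(X)
}
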
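#' Gene-level differential expression within one age group
#'
#' Compares disease against control samples inside a single age group with a
#' per-gene ordinary two-group linear model (equivalent to the pooled-variance
#' two-sample t-test): `logFC` is the arm-mean difference in log2 units,
#' p-values are adjusted across genes by Benjamini-Hochberg, and a gene is a
#' DEG iff `logFC != 0` and adjusted p < 0.05. Genes with zero pooled
#' variance but a non-zero mean difference are reported at the smallest
#' positive representable p and flagged.
#'
#' @param X Numeric matrix, genes x samples (centered log expression).
#' @param meta Sample metadata with `diagnosis` and `age` (model column
#'   order).
#' @param disease Disease arm label (e.g. `"SCZ"`).
#' @param age_group Age-group label from [age_bins()], or `NULL` to use all
#'   samples.
#' @param alpha Adjusted-p cutoff for the DEG call.
#' @return List with `table` (gene, logFC, p, p_adj, direction, deg,
#'   zero_variance), `up` and `down` DEG counts.
#' @export
gene_deg <- function(X, meta, disease, age_group = NULL, alpha = 0.05) {
  sel <- meta$diagnosis %in% c("CNTRL", disease)
  if (!is.null(age_group)) {
    sel <- sel & as.character(assign_age_groups(meta$age)) == age_group
  }
  grp <- meta$diagnosis[sel]
  n1 <- sum(grp == disease)
  n0 <- sum(grp == "CNTRL")
  if (n1 < 2 || n0 < 2) {
    stop("need >= 2 samples per arm (", disease, ": ", n1,
      ", CNTRL: ", n0, ")",
      call. = FALSE
    )
  }
  Xd <- X[, sel, drop = FALSE][, grp == disease, drop = FALSE]
  Xc <- X[, sel, drop = FALSE][, grp == "CNTRL", drop = FALSE]
  m1 <- rowMeans(Xd)
  m0 <- rowMeans(Xc)
  v1 <- apply(Xd, 1, stats::var)
  v0 <- apply(Xc, 1, stats::var)
  logfc <- m1 - m0
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  tstat <- logfc / se
  p <- 2 * stats::pt(abs(tstat), df = n1 + n0 - 2, lower.tail = FALSE)
  zero_var <- se == 0
  p[zero_var & logfc != 0] <- .Machine$double.xmin
  p[zero_var & logfc == 0] <- 1
  p_adj <- stats::p.adjust(p, method = "BH")
  deg <- logfc != 0 & p_adj < alpha
  tab <- data.frame(
    gene = rownames(X),
    disease = disease,
    age_group = if (is.null(age_group)) NA_character_ else age_group,
    logFC = logfc,
    p = p,
    p_adj = p_adj,
    direction = sign(logfc),
    deg = deg,
    zero_variance = zero_var,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  list(table = tab, up = sum(deg & logfc > 0), down = sum(deg & logfc < 0))
}

#' DEG counts per disease and age group
#'
#' Tabulates over- and under-expressed gene counts for every disease x age
#' group with at least two samples per arm (the bar-chart summary of
#' age-resolved differential expression).
#'
#' @inheritParams gene_deg
#' @param diseases Disease labels to test.
#' @return Data frame: `disease`, `age_group`, `up`, `down`.
#' @export
deg_counts <- function(X, meta, diseases = setdiff(
                         unique(meta$diagnosis), "CNTRL"
                       ), alpha = 0.05) {
  groups <- assign_age_groups(meta$age)
  out <- list()
  for (dx in diseases) {
    for (g in levels(groups)) {
      in_g <- as.character(groups) == g
      if (sum(in_g & meta$diagnosis == dx) < 2 ||
        sum(in_g & meta$diagnosis == "CNTRL") < 2) {
        next
      }
      res <- gene_deg(X, meta, dx, g, alpha = alpha)
      out[[length(out) + 1]] <- data.frame(
        disease = dx, age_group = g, up = res$up, down = res$down,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      disease = character(), age_group = character(),
      up = integer(), down = integer()
    ))
  }
  do.call(rbind, out)
}

#' Spot-level disease effect adjusted for age
#'
#' For each spot, fits `spot expression ~ diagnosis + age` over the union of
#' the disease's and control samples and reports the diagnosis coefficient
#' (disease minus control, at fixed age) with its p-value.
#'
#' @param spot_expr Matrix, spots x samples ([spot_profiles()]).
#' @param meta Sample metadata with `diagnosis` and `age` (column order of
#'   `spot_expr`).
#' @param disease Disease arm label.
#' @return Data frame: `spot`, `disease`, `coefficient`, `p`.
#' @export
spot_diff <- function(spot_expr, meta, disease) {
  sel <- meta$diagnosis %in% c("CNTRL", disease)
  if (sum(meta$diagnosis[sel] == disease) == 0 ||
    sum(meta$diagnosis[sel] == "CNTRL") == 0) {
    stop("both arms must be present")
  }
  dx <- factor(meta$diagnosis[sel], levels = c("CNTRL", disease))
  age <- meta$age[sel]
  design_rank <- qr(cbind(1, as.numeric(dx) - 1, age))$rank
  if (design_rank < 3) {
    stop(
      "confounded design: diagnosis and age are collinear for ", disease
    )
  }
  rows <- lapply(rownames(spot_expr), function(sp) {
    fit <- stats::lm(spot_expr[sp, sel] ~ dx + age)
    cf <- summary(fit)$coefficients
    data.frame(
      spot = sp,
      disease = disease,
      coefficient = cf[2, 1],
      p = cf[2, 4],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
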
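#' Read a tab-separated expression (or flag) matrix
#'
#' Expects a header row of sample ids and a first column of gene ids; all
#' cells must be numeric and all ids unique.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
    stringsAsFactors = FALSE)
  ids <- tab[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(m)[!vapply(
      seq_len(ncol(m)),
      function(j) is.numeric(tab[[j + 1]]), logical(1)
    )]
    stop("non-numeric cells in column(s): ", paste(bad, collapse = ", "))
  }
  dupc <- colnames(m)[duplicated(colnames(m))]
  if (length(dupc) > 0) {
    stop("duplicated sample id(s): ", paste(unique(dupc), collapse = ", "))
  }
  rownames(m) <- ids
  m
}

#' Write a matrix as tab-separated text
#'
#' @param X Matrix with rownames and colnames.
#' @param path Output path.
#' @param id_col Header of the first (id) column.
#' @export
write_matrix <- function(X, path, id_col = "gene") {
  df <- data.frame(rownames(X), X, check.names = FALSE,
    stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(X))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Tab-separated, one row per sample; a `sample` column is required, and the
#' conventional columns are `diagnosis`, `age`, `sex`, `pH`, `PMI`, `batch`.
#' Disease-arm samples younger than 18 raise a warning (paper-like cohorts
#' sample cases only after the age of onset).
#'
#' @param path File path.
#' @return Data frame of sample metadata.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(meta)) stop("metadata needs a 'sample' column")
  dup <- meta$sample[duplicated(meta$sample)]
  if (length(dup) > 0) {
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (all(c("diagnosis", "age") %in% names(meta))) {
    young_cases <- meta$diagnosis != "CNTRL" & meta$age < 18
    if (any(young_cases)) {
      warning(sum(young_cases),
        " disease sample(s) younger than 18 years", call. = FALSE)
    }
  }
  meta
}

#' @rdname read_metadata
#' @param meta Metadata data frame.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then gene ids. Lines with fewer than three fields (missing
#' description or genes) are an explicit failure.
#'
#' @param path File path.
#' @return Named list of gene-id vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short) > 0) {
    stop("ragged GMT line(s) (need name, description, genes): line ",
      paste(short, collapse = ", "))
  }
  names_ <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(names_)) {
    stop("duplicated set name(s): ",
      paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- names_
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, "", 2), names_
  )
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene-id vectors.
#' @param descriptions Optional named descriptions (default the set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions") %||%
      stats::setNames(names(sets), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a binary gene x tissue eQTL flag table
#'
#' @param path File path (tab-separated; first column gene ids, header of
#'   tissue names, 0/1 cells).
#' @return Integer 0/1 matrix.
#' @export
read_eqtl <- function(path) {
  m <- read_matrix(path)
  if (!all(m %in% c(0, 1))) stop("eQTL flags must be 0/1")
  storage.mode(m) <- "integer"
  m
}
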
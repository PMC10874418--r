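#' Age groups spanning the postnatal lifespan
#'
#' The nine age bins used to stratify cohorts, following the stages of normal
#' prefrontal-cortex development and aging. Bins are left-exclusive and
#' right-inclusive and tile (0, 100] years without overlap.
#'
#' @return A data frame with columns `label`, `lower` (exclusive) and `upper`
#'   (inclusive), in years.
#' @export
#' @examples
#' age_bins()
age_bins <- function() {
  upper <- c(1, 5, 10, 18, 35, 50, 65, 85, 100)
  lower <- c(0, upper[-length(upper)])
  data.frame(
    label = sprintf("(%g-%g]", lower, upper),
    lower = lower,
    upper = upper,
    stringsAsFactors = FALSE
  )
}

#' Assign samples to age groups
#'
#' Maps continuous age in years to the nine lifespan bins of [age_bins()].
#' Membership is left-exclusive/right-inclusive: age `a` belongs to
#' `(lo-hi]` iff `lo < a <= hi`, so age 18 falls in `(10-18]` and age 18.5
#' in `(18-35]`.
#'
#' @param age Numeric vector of ages in years, each in (0, 100].
#' @return Factor of bin labels (levels in bin order), one per input age.
#' @export
#' @examples
#' assign_age_groups(c(0.5, 18, 18.5, 85))
assign_age_groups <- function(age) {
  if (is.data.frame(age)) {
    age <- age$age
  }
  if (!is.numeric(age) || anyNA(age)) {
    stop("`age` must be numeric with no missing values")
  }
  bad <- age <= 0 | age > 100
  if (any(bad)) {
    stop(
      "ages outside (0, 100]: ",
      paste(utils::head(age[bad], 5), collapse = ", ")
    )
  }
  bins <- age_bins()
  # left.open: (lo, hi] membership, so ties at an upper edge stay in the
  # lower-labelled bin.
  idx <- findInterval(age, c(0, bins$upper), left.open = TRUE)
  factor(bins$label[idx], levels = bins$label)
}

#' Published cohort sample counts by age group
#'
#' The per-age-group sample counts of the harmonized post-mortem
#' prefrontal-cortex cohort (controls spanning (0, 100] years; disease arms
#' starting at (18-35]), including the printed per-group totals, bundled as a
#' plain-text table with the package.
#'
#' @param totals If `TRUE` (default) keep the printed `Total` row; otherwise
#'   return only the nine age-group rows.
#' @return Data frame with columns `age_group`, `CNTRL`, `SCZ`, `BD`, `MDD`.
#' @export
#' @examples
#' counts <- cohort_age_counts(totals = FALSE)
#' colSums(counts[, -1])
cohort_age_counts <- function(totals = TRUE) {
  path <- system.file("extdata", "cohort_age_counts.tsv",
    package = "somperturb", mustWork = TRUE
  )
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!totals) {
    tab <- tab[tab$age_group != "Total", , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}
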
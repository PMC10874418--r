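#' Summary maps over all portraits
#'
#' Superposes all sample portraits into two `k x k` summary maps: the
#' variance map (per-metagene variance of expression across all samples,
#' highlighting regions of highly variable genes) and the overexpression map
#' (per-metagene maximum of the group-mean portraits).
#'
#' Metagenes without member genes are masked to zero in both maps: their
#' weights are interpolations of neighbouring occupied units (they summarize
#' no genes), and leaving them in creates spurious high-variance bridges
#' between distinct modules.
#'
#' @param model A [som_fit()] model.
#' @param groups Character or factor group label per sample (model column
#'   order).
#' @param mask_empty Zero out metagenes with no assigned genes (default
#'   `TRUE`).
#' @return List with `variance` and `overexpression`, each a `k x k`
#'   [as.matrix] of class `portrait`.
#' @export
summary_maps <- function(model, groups, mask_empty = TRUE) {
  stopifnot(inherits(model, "som_map"))
  if (length(groups) != length(model$samples)) {
    stop("one group label per sample required")
  }
  if (length(model$samples) < 2) stop("variance map needs >= 2 samples")
  v <- apply(model$weights, 1, stats::var) # unbiased, n - 1 denominator
  group_means <- vapply(
    split(seq_along(groups), groups),
    function(idx) rowMeans(model$weights[, idx, drop = FALSE]),
    numeric(model$K)
  )
  group_means <- matrix(group_means, nrow = model$K)
  over <- apply(group_means, 1, max)
  if (mask_empty) {
    occupied <- tabulate(model$assignment, nbins = model$K) > 0
    v[!occupied] <- 0
    over[!occupied] <- 0
  }
  list(
    variance = as_portrait(v, model$k, label = "variance"),
    overexpression = as_portrait(over, model$k, label = "overexpression")
  )
}

#' Segment a summary map into spots
#'
#' Thresholds the map at a quantile of its values, takes connected
#' components of the foreground metagenes under 8- (default) or
#' 4-neighborhood grid adjacency, discards components below `min_size`, and
#' labels the survivors A, B, C, ... in decreasing size (ties broken by the
#' smallest row-major metagene index). If a model is supplied, each spot
#' also carries its member genes and per-sample expression (the mean weight
#' of its metagenes), and — because spots are modules of co-expressed genes
#' — adjacent foreground metagenes are joined into one component only when
#' their weight profiles cohere (Pearson `r > r_min`), so unrelated modules
#' whose territories happen to touch on the grid are not merged.
#'
#' @param map `k x k` matrix (e.g. a [summary_maps()] component).
#' @param quantile Foreground threshold quantile in (0, 1); metagenes with
#'   map value strictly above this quantile are foreground.
#' @param min_size Minimum metagenes per spot.
#' @param adjacency 8 (edges and corners) or 4 (edges only).
#' @param model Optional [som_fit()] model used to attach genes and
#'   expression.
#' @param r_min Profile-coherence gate for joining adjacent metagenes; only
#'   applied when a model is supplied (`NULL` disables the gate).
#' @return Object of class `spot_set`: list of spots, each with `label`,
#'   `metagenes` (row-major indices), and, with a model, `genes` and
#'   `expression` (named per-sample mean weight).
#' @export
segment_spots <- function(map, quantile = 0.9, min_size = 3,
                          adjacency = 8, model = NULL, r_min = 0.5) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  if (!adjacency %in% c(4, 8)) stop("adjacency must be 4 or 8")
  k <- nrow(map)
  if (ncol(map) != k) stop("map must be square")
  vals <- as.numeric(t(map)) # row-major metagene order
  cut <- stats::quantile(vals, quantile, names = FALSE)
  fg <- vals > cut
  gate <- NULL
  if (!is.null(model) && !is.null(r_min)) {
    W <- model$weights
    gate <- function(i, j) {
      r <- suppressWarnings(stats::cor(W[i, ], W[j, ]))
      !is.na(r) && r > r_min
    }
  }
  comps <- grid_components(fg, k, adjacency, gate)
  comps <- Filter(function(x) length(x) >= min_size, comps)
  ord <- order(
    -vapply(comps, length, integer(1)),
    vapply(comps, min, numeric(1))
  )
  comps <- comps[ord]
  spots <- lapply(seq_along(comps), function(i) {
    s <- list(label = spot_label(i), metagenes = sort(comps[[i]]))
    if (!is.null(model)) {
      s$genes <- names(model$assignment)[
        model$assignment %in% s$metagenes
      ]
      s$expression <- colMeans(
        model$weights[s$metagenes, , drop = FALSE]
      )
      names(s$expression) <- model$samples
    }
    s
  })
  structure(spots, class = "spot_set", k = k, adjacency = adjacency)
}

spot_label <- function(i) {
  if (i <= 26) LETTERS[i] else paste0(LETTERS[(i - 1) %/% 26], LETTERS[(i - 1) %% 26 + 1])
}

# Connected components of foreground cells on a k x k grid (row-major
# logical vector) by breadth-first search; an optional gate(i, j) predicate
# must also hold for two adjacent cells to be connected.
grid_components <- function(fg, k, adjacency = 8, gate = NULL) {
  idx_row <- function(i) (i - 1) %/% k + 1
  idx_col <- function(i) (i - 1) %% k + 1
  seen <- !fg
  comps <- list()
  for (start in which(fg)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      members <- c(members, cur)
      r <- idx_row(cur)
      c <- idx_col(cur)
      dr <- c(-1, 1, 0, 0, -1, -1, 1, 1)
      dc <- c(0, 0, -1, 1, -1, 1, -1, 1)
      if (adjacency == 4) {
        dr <- dr[1:4]
        dc <- dc[1:4]
      }
      nr <- r + dr
      nc <- c + dc
      ok <- nr >= 1 & nr <= k & nc >= 1 & nc <= k
      nb <- (nr[ok] - 1) * k + nc[ok]
      nb <- nb[!seen[nb]]
      if (!is.null(gate) && length(nb) > 0) {
        nb <- nb[vapply(nb, function(j) gate(cur, j), logical(1))]
      }
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- members
  }
  comps
}

#' @export
print.spot_set <- function(x, ...) {
  cat("Spot set:", length(x), "spots on a", attr(x, "k"), "x",
    attr(x, "k"), "grid\n")
  for (s in x) {
    cat(
      "  ", s$label, ": ", length(s$metagenes), " metagenes",
      if (!is.null(s$genes)) paste0(", ", length(s$genes), " genes"),
      "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Per-sample spot expression table
#'
#' Expression of a spot in a sample is the arithmetic mean of its member
#' metagene weights for that sample. Spots without member genes are dropped
#' with a warning (they carry no gene-level signal for downstream models).
#'
#' @param spots A [segment_spots()] result.
#' @param model The [som_fit()] model the spots were segmented from.
#' @return Matrix, spots x samples, rownames = spot labels.
#' @export
spot_profiles <- function(spots, model) {
  stopifnot(inherits(model, "som_map"))
  keep <- vapply(
    spots,
    function(s) sum(model$assignment %in% s$metagenes) > 0,
    logical(1)
  )
  if (any(!keep)) {
    warning(
      "dropping spots with no member genes: ",
      paste(vapply(spots[!keep], `[[`, "", "label"), collapse = ", "),
      call. = FALSE
    )
  }
  spots <- spots[keep]
  out <- t(vapply(
    spots,
    function(s) colMeans(model$weights[s$metagenes, , drop = FALSE]),
    numeric(length(model$samples))
  ))
  dimnames(out) <- list(
    vapply(spots, `[[`, "", "label"),
    model$samples
  )
  out
}
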
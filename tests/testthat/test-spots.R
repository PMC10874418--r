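test_that("summary maps compute per-metagene variance and group maxima", {
  X <- two_cluster_profiles(n_per = 30, m = 10)
  som <- som_fit(X, k = 3, epochs = 8)
  groups <- rep(c("a", "b"), each = 5)
  maps <- summary_maps(som, groups, mask_empty = FALSE)
  v <- as.numeric(t(unclass(maps$variance)))
  expect_equal(v, unname(apply(som$weights, 1, var)))
  expect_true(all(v >= 0))
  # hand case: two samples with metagene values 0 and 2 -> variance 2
  expect_equal(var(c(0, 2)), 2)
  fake <- som
  fake$weights <- matrix(c(0, 2), 1, 2)
  fake$samples <- c("x", "y")
  fake$k <- 1
  fake$K <- 1
  fake$assignment <- c(g1 = 1L)
  expect_equal(
    as.numeric(summary_maps(fake, c("a", "a"))$variance), 2
  )
  # single group: overexpression map equals the group mean portrait
  one <- summary_maps(som, rep("a", 10), mask_empty = FALSE)
  expect_equal(
    as.numeric(t(unclass(one$overexpression))),
    unname(rowMeans(som$weights))
  )
  # identical portraits: zero variance map
  same <- som
  same$weights <- matrix(1.5, som$K, 10)
  expect_true(all(summary_maps(same, groups, mask_empty = FALSE)$variance == 0))
  expect_error(summary_maps(som, "a"), "one group label")
})

test_that("a planted high block is recovered as exactly one spot", {
  map <- matrix(0, 10, 10)
  map[4:6, 5:7] <- 1
  spots <- segment_spots(map, quantile = 0.9, min_size = 3)
  expect_length(spots, 1)
  expect_length(spots[[1]]$metagenes, 9)
  expect_equal(spots[[1]]$label, "A")
  # the recovered indices are the planted block (row-major)
  expected <- sort(as.integer(outer((4:6 - 1) * 10, 5:7, "+")))
  expect_equal(spots[[1]]$metagenes, expected)
})

test_that("constant maps yield no spots and thresholds are monotone", {
  expect_length(segment_spots(matrix(1, 6, 6)), 0)
  set.seed(4)
  map <- matrix(runif(100), 10, 10)
  qs <- c(0.5, 0.7, 0.9)
  fgs <- lapply(qs, function(q) {
    unlist(lapply(segment_spots(map, q, min_size = 1), `[[`, "metagenes"))
  })
  expect_true(all(fgs[[2]] %in% fgs[[1]]))
  expect_true(all(fgs[[3]] %in% fgs[[2]]))
})

test_that("corner-touching blocks merge under 8-adjacency and split under 4", {
  map <- matrix(0, 10, 10)
  map[2:4, 2:4] <- 1
  map[5:7, 5:7] <- 1 # touches the first block only at corner (4,4)/(5,5)
  s8 <- segment_spots(map, quantile = 0.8, min_size = 3, adjacency = 8)
  s4 <- segment_spots(map, quantile = 0.8, min_size = 3, adjacency = 4)
  expect_length(s8, 1)
  expect_length(s4, 2)
  expect_error(segment_spots(map, adjacency = 6), "adjacency")
  expect_error(segment_spots(map, quantile = 1.2), "quantile")
})

test_that("spots are disjoint, connected, and labelled by size", {
  set.seed(8)
  map <- matrix(runif(400), 20, 20)
  map[2:5, 2:5] <- 2 # 16 cells
  map[10:11, 10:14] <- 2 # 10 cells
  spots <- segment_spots(map, quantile = 0.9, min_size = 3)
  expect_gte(length(spots), 2)
  sizes <- vapply(spots, function(s) length(s$metagenes), 0L)
  expect_true(all(diff(sizes) <= 0))
  expect_equal(
    vapply(spots, `[[`, "", "label"),
    LETTERS[seq_along(spots)]
  )
  all_cells <- unlist(lapply(spots, `[[`, "metagenes"))
  expect_equal(anyDuplicated(all_cells), 0)
  # BFS connectivity: every spot is one component under its own adjacency
  for (s in spots) {
    fg <- rep(FALSE, 400)
    fg[s$metagenes] <- TRUE
    comps <- somperturb:::grid_components(fg, 20, 8)
    expect_length(comps, 1)
  }
})

test_that("spot profiles average member metagene weights per sample", {
  X <- two_cluster_profiles(n_per = 30, m = 8)
  som <- som_fit(X, k = 3, epochs = 8)
  spot <- list(list(label = "A", metagenes = c(1L, 2L)))
  prof <- spot_profiles(spot, som)
  expect_equal(
    unname(prof["A", ]),
    unname(colMeans(som$weights[1:2, ]))
  )
  # hand case: weights 1 and 3 average to 2
  fake <- som
  fake$weights <- matrix(c(1, 3), 2, 8, byrow = FALSE)
  fake$weights[1, ] <- 1
  fake$weights[2, ] <- 3
  expect_true(all(spot_profiles(spot, fake)["A", ] == 2))
  # single-metagene spot passes the weight through
  single <- list(list(label = "B", metagenes = 2L))
  expect_equal(
    unname(spot_profiles(single, som)["B", ]),
    unname(som$weights[2, ])
  )
  # spots with no member genes are dropped with a warning
  empty_mg <- setdiff(seq_len(som$K), unique(som$assignment))
  if (length(empty_mg) > 0) {
    spots2 <- list(
      list(label = "A", metagenes = c(1L, 2L)),
      list(label = "Z", metagenes = empty_mg[1])
    )
    expect_warning(out <- spot_profiles(spots2, som), "no member genes")
    expect_equal(rownames(out), "A")
  }
})

test_that("profile-coherence gating separates touching but uncorrelated territories", {
  # two gene clusters with uncorrelated sample profiles
  set.seed(3)
  m <- 12
  base1 <- rnorm(m)
  base2 <- rnorm(m)
  X <- rbind(
    matrix(rep(base1, each = 30), 30) + rnorm(30 * m, 0, 0.1),
    matrix(rep(base2, each = 30), 30) + rnorm(30 * m, 0, 0.1)
  )
  rownames(X) <- sprintf("g%03d", 1:60)
  som <- som_fit(center_genes(X), k = 4, epochs = 20, seed = 2)
  maps <- summary_maps(som, rep("a", m))
  spots_gated <- segment_spots(maps$variance, 0.5, 1,
    model = som, r_min = 0.5)
  # no gated spot mixes genes from the two clusters
  for (s in spots_gated) {
    frac1 <- mean(as.integer(sub("g", "", s$genes)) <= 30)
    expect_true(frac1 == 0 || frac1 == 1)
  }
})
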
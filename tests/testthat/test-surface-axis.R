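test_that("seed selection honors the cluster fraction and seed", {
  m <- make_grid_mesh(20, 20, spacing = 1, parcel_blocks = c(2, 2))
  all_seed <- select_seed_nodes(m, seed_parcels = 1, cluster_fraction = 1)
  expect_setequal(all_seed, which(m$parcel == 1))

  s1 <- select_seed_nodes(m, 1, cluster_fraction = 0.1, n_clusters = 40, seed = 13)
  s2 <- select_seed_nodes(m, 1, cluster_fraction = 0.1, n_clusters = 40, seed = 13)
  expect_identical(s1, s2)
  expect_true(all(s1 %in% all_seed))
  # ceil(0.1 * 40) = 4 of 40 clusters retained: far fewer seeds than vertices
  expect_lt(length(s1), length(all_seed) / 2)
  expect_gt(length(s1), 0)
  expect_error(select_seed_nodes(m, 99), "no vertices")
})

test_that("selected clusters contribute all of their member vertices", {
  # five well-separated clumps of two vertices: the k-means clusters are the
  # clumps, so cluster_fraction 0.2 returns ceiling(0.2 * 5) = 1 clump, i.e.
  # exactly two member vertices
  v <- cbind(rep(c(0, 100, 200, 300, 400), each = 2) + c(0, 1), 0, 0)
  tri <- cbind(1:8, 2:9, 3:10)
  m <- surface_mesh(v, tri, parcel = rep(1, 10))
  s <- select_seed_nodes(m, 1, cluster_fraction = 0.2, n_clusters = 5, seed = 5)
  expect_length(s, 2L)
  expect_equal(diff(s), 1L)  # the two members of one clump
})

test_that("geodesic distances reproduce the worked lattice value", {
  m <- make_grid_mesh(10, 10, spacing = 1)
  d <- geodesic_distance(m, seeds = 1)
  expect_equal(d[1], 0)
  # vertex (row 4, col 5) i.e. coordinates (3, 4): three diagonals + one edge
  expect_equal(d[(4 - 1) * 10 + 5], 3 * sqrt(2) + 1, tolerance = 1e-12)
})

test_that("multi-source distance is the pointwise minimum over seeds", {
  m <- random_mesh(8, 9, seed = 4)
  seeds <- c(1, 37, 60)
  multi <- geodesic_distance(m, seeds)
  singles <- sapply(seeds, function(s) geodesic_distance(m, s))
  expect_equal(multi, apply(singles, 1, min), tolerance = 1e-12)
  expect_true(all(multi[seeds] == 0))
})

test_that("edge-graph distances match an exhaustive Dijkstra oracle", {
  for (i in 1:12) {
    nr <- sample(4:10, 1); nc <- sample(4:12, 1)
    m <- random_mesh(nr, nc, seed = 100 + i)
    seeds <- sample(nrow(m$vertices), sample(1:3, 1))
    ed <- corticalmyelin:::mesh_edges(m)
    oracle <- dijkstra_oracle(nrow(m$vertices), ed$edges, ed$lengths, seeds)
    expect_equal(geodesic_distance(m, seeds), oracle, tolerance = 1e-10)
  }
})

test_that("grid distances are bounded and never increase under refinement", {
  m1 <- make_grid_mesh(6, 6, spacing = 2)
  m2 <- make_grid_mesh(11, 11, spacing = 1)  # one dyadic refinement
  d1 <- geodesic_distance(m1, 1)
  d2 <- geodesic_distance(m2, 1)
  # coarse vertex (r, c) maps to fine vertex (2r-1, 2c-1)
  for (r in 1:6) for (c in 1:6) {
    v1 <- (r - 1) * 6 + c
    v2 <- (2 * r - 2) * 11 + (2 * c - 1)
    expect_lte(d2[v2], d1[v1] + 1e-12)
    eucl <- sqrt(sum((m1$vertices[v1, ] - m1$vertices[1, ])^2))
    expect_gte(d1[v1], eucl - 1e-12)
  }
})

test_that("parcel axis averages distances with deterministic tie-breaks", {
  d <- c(1, 3, 2, 2)
  axis <- parcel_axis(d, c("b", "b", "a", "a"))
  expect_equal(axis$distance[axis$parcel == "a"], 2)
  expect_equal(axis$distance[axis$parcel == "b"], 2)
  # tie broken lexicographically: parcel a gets rank 1
  expect_equal(axis$rank[axis$parcel == "a"], 1L)
  expect_equal(axis$rank[axis$parcel == "b"], 2L)

  one <- parcel_axis(c(0.5, 1.5), c("p", "p"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$distance, 1)
})

test_that("hierarchy groups are contiguous near-equal thirds", {
  mk_axis <- function(P) {
    axis <- parcel_axis(seq_len(P), seq_len(P))
    assign_groups(axis)
  }
  expect_equal(as.vector(table(mk_axis(399)$group)), c(133, 133, 133))
  expect_equal(as.vector(table(mk_axis(400)$group)), c(133, 134, 133))
  a3 <- mk_axis(3)
  expect_equal(as.character(a3$group[order(a3$rank)]),
               c("association", "middle", "sensorimotor"))
  # smallest distance = association end
  expect_equal(as.character(mk_axis(30)$group[1]), "association")
})

test_that("group assignment is invariant to monotone distance transforms", {
  set.seed(9)
  d <- runif(50)
  axis1 <- assign_groups(parcel_axis(d, seq_len(50)))
  axis2 <- assign_groups(parcel_axis(exp(3 * d) + 2, seq_len(50)))
  expect_equal(axis1$group, axis2$group)
  expect_equal(axis1$rank, axis2$rank)
})

test_that("axis validation reproduces rank correlations", {
  axis <- parcel_axis(c(5, 1, 3, 2, 4, 6), sprintf("p%d", 1:6))
  self <- validate_axis(axis, stats::setNames(axis$distance, axis$parcel))
  expect_equal(self$rho, 1)
  rev <- validate_axis(axis, stats::setNames(-axis$distance, axis$parcel))
  expect_equal(rev$rho, -1)
  set.seed(3)
  noisy <- axis$distance + rnorm(6, 0, 0.2)
  got <- validate_axis(axis, stats::setNames(noisy, axis$parcel))
  expect_equal(got$rho, stats::cor(rank(axis$distance), rank(noisy)),
               tolerance = 1e-12)
  expect_error(validate_axis(axis[1:3, ], stats::setNames(1:3, axis$parcel[1:3])),
               "at least 5")
})
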
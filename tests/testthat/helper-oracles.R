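# Independent oracles and small fixture builders used across the suite.

# naive single-source Dijkstra on an edge list; O(V^2), fine for <= 200 vertices
dijkstra_oracle <- function(n_vertices, edges, lengths, sources) {
  adj <- vector("list", n_vertices)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]; w <- lengths[i]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist <- rep(Inf, n_vertices)
  dist[sources] <- 0
  done <- rep(FALSE, n_vertices)
  for (iter in seq_len(n_vertices)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    if (!is.null(adj[[u]])) {
      for (j in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][j, 1]; w <- adj[[u]][j, 2]
        if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
      }
    }
  }
  dist
}

# random connected triangle mesh: jittered grid with random extra diagonal flips
random_mesh <- function(n_rows, n_cols, seed) {
  set.seed(seed)
  m <- make_grid_mesh(n_rows, n_cols, spacing = 1)
  v <- m$vertices
  v[, 1:2] <- v[, 1:2] + matrix(runif(2 * nrow(v), -0.3, 0.3), ncol = 2)
  v[, 3] <- runif(nrow(v), -0.5, 0.5)
  surface_mesh(v, m$triangles, m$parcel)
}

# noise-free saturating cohort table for a single unit
saturating_data <- function(n, age_range, baseline, amplitude, rate,
                            noise_sd = 0, seed = 1) {
  set.seed(seed)
  age <- runif(n, age_range[1], age_range[2])
  value <- baseline + amplitude * (1 - exp(-rate * age)) +
    rnorm(n, 0, noise_sd)
  data.frame(age = age, value = value)
}

expect_csv_identical <- function(path1, path2) {
  expect_identical(readBin(path1, "raw", file.info(path1)$size),
                   readBin(path2, "raw", file.info(path2)$size))
}
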
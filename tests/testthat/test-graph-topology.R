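test_that("proportional threshold keeps exactly round(density * pairs) edges", {
  z <- matrix(rnorm(400), 20, 20)
  z <- z + t(z)
  diag(z) <- 0
  adj <- proportional_threshold(z, 0.2)
  expect_equal(sum(adj) / 2, 38)
  expect_equal(adj, t(adj))
  expect_equal(diag(adj), rep(0L, 20))

  z3 <- matrix(0, 3, 3)
  z3[1, 2] <- z3[2, 1] <- 3
  z3[1, 3] <- z3[3, 1] <- 2
  z3[2, 3] <- z3[3, 2] <- 1
  adj3 <- proportional_threshold(z3, 0.34)
  expect_equal(sum(adj3) / 2, 1)
  expect_equal(adj3[1, 2], 1L)
})

test_that("threshold tie-breaks are deterministic and warned about", {
  z <- matrix(1, 4, 4)
  diag(z) <- 0
  expect_warning(a1 <- proportional_threshold(z, 0.5), "tied")
  a2 <- suppressWarnings(proportional_threshold(z, 0.5))
  expect_identical(a1, a2)
  expect_equal(sum(a1) / 2, 3)
  # lexicographic: the first pairs by (i, j) win
  expect_equal(a1[1, 2:4], c(1L, 1L, 1L))
})

test_that("thresholding is invariant to adding a constant", {
  z <- matrix(rnorm(100), 10, 10)
  z <- z + t(z)
  diag(z) <- 0
  a <- proportional_threshold(z, 0.2)
  b <- proportional_threshold(z + 3, 0.2)
  expect_identical(a, b)
})

test_that("absolute mode ranks weights by magnitude", {
  z <- matrix(0, 3, 3)
  z[1, 2] <- z[2, 1] <- -3
  z[1, 3] <- z[3, 1] <- 2
  z[2, 3] <- z[3, 2] <- 1
  expect_equal(proportional_threshold(z, 0.34)[1, 3], 1L)
  expect_equal(proportional_threshold(z, 0.34, mode = "absolute")[1, 2], 1L)
})

test_that("betweenness matches the textbook examples", {
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))
  expect_equal(unname(betweenness_centrality(star5)), c(6, 0, 0, 0, 0))
  expect_equal(unname(betweenness_centrality(cycle4)), rep(0.5, 4))
})

test_that("Brandes agrees with enumeration, plain-R enumeration, and igraph", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    adj <- random_adj(7, 9, seed)
    b <- betweenness_centrality(adj)
    expect_equal(b, betweenness_exhaustive(adj), tolerance = 1e-12)
    expect_equal(unname(b), bc_oracle_r(adj), tolerance = 1e-12)
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(unname(b), unname(igraph::betweenness(ig)), tolerance = 1e-10)
  }
  for (seed in 11:15) {
    adj <- random_adj(20, 38, seed)
    b <- betweenness_centrality(adj)
    expect_equal(b, betweenness_exhaustive(adj), tolerance = 1e-12)
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(unname(b), unname(igraph::betweenness(ig)), tolerance = 1e-10)
  }
})

test_that("disconnected pieces and isolated nodes are handled", {
  adj <- matrix(0L, 6, 6)
  adj[1, 2] <- adj[2, 1] <- 1L
  adj[2, 3] <- adj[3, 2] <- 1L  # path a-b-c plus three isolated nodes
  bc <- betweenness_centrality(adj)
  expect_equal(unname(bc), c(0, 1, 0, 0, 0, 0))
})

test_that("rank_centrality gives descending average-tie ranks", {
  expect_equal(rank_centrality(c(5, 2, 9)), c(2, 3, 1))
  expect_equal(rank_centrality(c(0, 0, 0, 0)), rep(2.5, 4))
  expect_equal(rank_centrality(c(7, 7, 1)), c(1.5, 1.5, 3))
  # rank rows always sum to n(n+1)/2
  for (seed in 1:5) {
    bc <- withr::with_seed(seed, round(rexp(20), 2))
    expect_equal(sum(rank_centrality(bc)), 20 * 21 / 2)
  }
})

test_that("centrality traces have the right shape and equivariance", {
  m <- matrix(rnorm(30 * 6), 30, 6)
  ts <- roi_timeseries(m, 1, node_labels = letters[1:6])
  tr <- centrality_trace(windowed_fc(ts, window_spec(10, 2)), density = 0.25)
  expect_equal(dim(tr$rank), c(11L, 6L))
  expect_true(all(abs(rowSums(tr$rank) - 21) < 1e-9))
  expect_true(all(tr$bc >= 0))

  # single window
  tr1 <- centrality_trace(windowed_fc(ts, window_spec(30, 1)), density = 0.25)
  expect_equal(dim(tr1$rank), c(1L, 6L))

  # permuting node order permutes the trace columns identically
  perm <- c(3, 1, 6, 2, 5, 4)
  ts_p <- roi_timeseries(m[, perm], 1, node_labels = letters[1:6][perm])
  tr_p <- centrality_trace(windowed_fc(ts_p, window_spec(10, 2)),
                           density = 0.25)
  expect_equal(unname(tr_p$bc), unname(tr$bc[, perm]))
  expect_equal(unname(tr_p$rank), unname(tr$rank[, perm]))
})

test_that("tidy and the writer expose the trace faithfully", {
  ts <- roi_timeseries(matrix(rnorm(120), 30, 4), 1)
  tr <- centrality_trace(windowed_fc(ts, window_spec(10, 5)))
  tl <- tidy(tr)
  expect_equal(nrow(tl), nrow(tr$rank) * 4)
  expect_equal(tl$rank[tl$node == 2], unname(tr$rank[, 2]))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- as.matrix(readr::read_csv(path, show_col_types = FALSE))
  expect_equal(unname(back), unname(tr$rank))
})
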
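test_that("mpfc rewards a correct two-blob partition", {
  x <- withr::with_seed(1, c(rnorm(30, 2, 0.2), rnorm(30, 18, 0.2)))
  labels <- rep(1:2, each = 30)
  val <- mpfc(x, labels)
  comp <- attr(val, "components")
  expect_gt(comp$as, 0.9)
  expect_true(is.finite(val) && val > 0)
  # one mislabeled point strictly lowers the silhouette
  bad <- labels
  bad[1] <- 2L
  comp_bad <- attr(mpfc(x, bad), "components")
  expect_lt(comp_bad$as, comp$as)
})

test_that("mpfc silhouette matches a naive quadratic implementation", {
  for (seed in 1:4) {
    x <- withr::with_seed(seed, sample(rep(1:20, length.out = 150)))
    labels <- cut(x, breaks = c(0, 7, 13, 21), labels = FALSE)
    comp <- attr(mpfc(x, labels), "components")
    expect_equal(comp$as, silhouette_naive(x, labels), tolerance = 1e-12)
  }
})

test_that("mpfc signals degenerate configurations explicitly", {
  # empty cluster
  out <- mpfc(c(1, 2, 3, 10), c(1L, 1L, 1L, 2L), centroids = c(2, 10, 15))
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "empty")
  # all-singleton partition: zero diameter
  out2 <- mpfc(c(1, 5, 9), 1:3)
  expect_true(is.na(out2))
  expect_match(attr(out2, "reason"), "diameter")
  # coincident centroids
  out3 <- mpfc(c(1, 1, 2, 9, 9, 10), rep(1:2, each = 3),
               centroids = c(4, 4))
  expect_identical(as.numeric(out3), -Inf)
})

test_that("cityblock k-medians recovers separated levels deterministically", {
  x <- withr::with_seed(5, c(rnorm(80, 2, 0.5), rnorm(80, 10, 0.5),
                             rnorm(80, 18, 0.5)))
  fit <- dynhub:::kmedians_1d(x, 3, seed = 42)
  expect_equal(sort(round(fit$centroids)), c(2, 10, 18))
  expect_equal(fit$sizes, rep(80L, 3))
  fit2 <- dynhub:::kmedians_1d(x, 3, seed = 42)
  expect_identical(fit, fit2)
  # assignment is by value: equal values always share a cluster
  expect_equal(length(unique(fit$labels[abs(x - 10) < 1])), 1L)
})

test_that("fit_modes picks three modes for three rank levels", {
  ranks <- withr::with_seed(8, matrix(
    sample(c(2, 10, 18), 300, replace = TRUE) +
      sample(c(-1, 0, 1), 300, replace = TRUE),
    ncol = 1
  ))
  trace <- structure(
    list(bc = ranks * 0, rank = cbind(ranks, 21 - ranks),
         window_starts = seq_len(300) - 1, subject_id = "s1",
         node_labels = c("a", "b")),
    class = "centrality_trace"
  )
  model <- fit_modes(trace, node = 1, seed = 3)
  expect_equal(model$k, 3L)
  expect_equal(model$hcm_id, 1L)
  expect_equal(model$centroids, sort(model$centroids))
  expect_lt(model$centroids[1], 5)
  expect_equal(unname(which.max(model$mpfc_by_k)),
               which(names(model$mpfc_by_k) == "3"))
})

test_that("a single tight level falls back to one mode with a note", {
  ranks <- matrix(rep(3, 120), ncol = 1)
  trace <- structure(
    list(bc = ranks * 0, rank = cbind(ranks, ranks), window_starts = 0:119,
         subject_id = "s1", node_labels = c("a", "b")),
    class = "centrality_trace"
  )
  expect_message(model <- fit_modes(trace, node = 1, seed = 1), "constant")
  expect_equal(model$k, 1L)
  expect_equal(unname(hcm_occupancy(model)$hcm_windows), 120L)
})

test_that("per-subject label slices preserve window order and counts", {
  cohort <- tiny_cohort(seed = 21)
  traces <- lapply(cohort$timeseries, function(ts) {
    centrality_trace(windowed_fc(ts, window_spec(10, 2)))
  })
  model <- fit_modes(traces, node = cohort$spec$hub_index, seed = 4)
  expect_named(model$labels, names(cohort$timeseries))
  w_each <- vapply(traces, function(tr) nrow(tr$rank), integer(1))
  expect_equal(vapply(model$labels, length, integer(1)), w_each)
  occ <- hcm_occupancy(model)
  expect_true(all(occ$hcm_windows >= 0 & occ$hcm_windows <= w_each))
  # per-mode counts partition the windows
  for (id in names(model$labels)) {
    expect_equal(length(model$labels[[id]]), w_each[[id]])
    expect_equal(sum(tabulate(model$labels[[id]], model$k)), w_each[[id]])
  }
})

test_that("mode models are deterministic and order-invariant across subjects", {
  cohort <- tiny_cohort(seed = 22)
  traces <- lapply(cohort$timeseries, function(ts) {
    centrality_trace(windowed_fc(ts, window_spec(10, 2)))
  })
  m1 <- fit_modes(traces, node = 2, seed = 9)
  m2 <- fit_modes(traces, node = 2, seed = 9)
  expect_identical(m1, m2)
  models <- fit_modes_cohort(traces, nodes = c(2, 5), seed = 9)
  occ <- occupancy_table(models)
  expect_equal(nrow(occ), 2 * length(traces))
  wide <- occupancy_matrix(occ)
  expect_equal(dim(wide), c(length(traces), 2L))
})

test_that("tidiers summarise a mode model", {
  cohort <- tiny_cohort(seed = 23)
  traces <- lapply(cohort$timeseries, function(ts) {
    centrality_trace(windowed_fc(ts, window_spec(10, 2)))
  })
  model <- fit_modes(traces, node = 1, seed = 2)
  td <- tidy(model)
  expect_equal(nrow(td), model$k)
  expect_equal(td$centroid, model$centroids)
  expect_equal(sum(td$hcm), 1L)
  gl <- glance(model)
  expect_equal(gl$k, model$k)
  expect_equal(gl$hcm_centroid, model$centroids[1])
})
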
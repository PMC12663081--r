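test_that("3-node construction plants a star on the hub", {
  sc <- make_state_covariances(3, hub_index = 1)
  expect_gte(sc$hub[1, 2], 0.6)
  expect_gte(sc$hub[1, 3], 0.6)
  expect_lte(abs(sc$hub[2, 3]), 0.2)
  expect_true(all(abs(sc$nonhub[1, -1]) <= 0.1))
  expect_gte(max(sc$nonhub[-1, -1][upper.tri(diag(2))]), 0.5)
})

test_that("state covariance matrices are valid correlation matrices", {
  for (n in c(5, 12, 20)) {
    sc <- make_state_covariances(n, hub_index = min(5, n))
    for (m in list(sc$hub, sc$nonhub)) {
      expect_equal(diag(m), rep(1, n))
      expect_equal(m, t(m))
      expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
})

test_that("hub tops betweenness of the thresholded hub-state matrix (brute force)", {
  sc <- make_state_covariances(20, hub_index = 5)
  adj <- proportional_threshold(sc$hub, 0.2)
  bc <- bc_oracle_r(adj)
  expect_equal(unname(rank_centrality(bc)[5]), 1)
  # hub strongly tied to at least half the other nodes
  expect_gte(sum(sc$hub[5, -5] >= 0.6), 10)
  # non-hub state: hub uncoupled
  expect_true(all(abs(sc$nonhub[5, -5]) <= 0.1))
})

test_that("simulate_subject honours occupancy extremes and its seed", {
  spec <- cohort_spec(n_subjects = 5, n_nodes = 8, n_volumes = 50, seed = 3)
  all_on <- simulate_subject(spec, 1, seed = 7)
  expect_true(all(all_on$states == 1L))
  expect_equal(all_on$occupancy, 1)
  all_off <- simulate_subject(spec, 0, seed = 7)
  expect_true(all(all_off$states == 0L))
  twice <- simulate_subject(spec, 0.5, seed = 7)
  again <- simulate_subject(spec, 0.5, seed = 7)
  expect_identical(twice$ts$data, again$ts$data)
  expect_identical(twice$states, again$states)
  expect_equal(twice$occupancy, mean(twice$states))
  expect_error(simulate_subject(spec, 1.2, seed = 1), "occupancy")
})

test_that("long noise-free subject reproduces the hub-state correlations", {
  spec <- cohort_spec(n_subjects = 5, n_nodes = 10, n_volumes = 2000,
                      noise_sd = 0, seed = 5)
  covs <- make_state_covariances(10, spec$hub_index, seed = spec$seed)
  sub <- simulate_subject(spec, 1, seed = 21, covariances = covs)
  expect_lt(max(abs(cor(sub$ts$data) - covs$hub)), 0.1)
})

test_that("cohort couples occupancy to ULS at the requested strength", {
  cohort <- simulate_cohort(cohort_spec(seed = 2))
  rho <- cor(cohort$truth$occupancy, cohort$truth$uls, method = "spearman")
  expect_lt(rho, -0.4)
  # impairment marginal: 1 unimpaired, 11 mild/moderate, 8 severe
  expect_equal(as.integer(table(factor(cohort$truth$uls, levels = 0:4))),
               c(1L, 6L, 5L, 4L, 4L))
  # shapes: one 260 x 20 series per subject
  expect_length(cohort$timeseries, 20)
  expect_true(all(vapply(cohort$timeseries,
                         function(ts) all(dim(ts$data) == c(260, 20)),
                         logical(1))))
})

test_that("null coupling stays null across seeds", {
  rhos <- vapply(1:100, function(s) {
    cohort <- simulate_cohort(cohort_spec(
      n_subjects = 20, n_nodes = 8, n_volumes = 40, coupling_rho = 0,
      seed = s
    ))
    cor(cohort$truth$occupancy, cohort$truth$uls, method = "spearman")
  }, numeric(1))
  expect_gte(sum(abs(rhos) < 0.3), 90)
})

test_that("identical spec and seed give an identical cohort", {
  spec <- cohort_spec(n_subjects = 5, n_nodes = 8, n_volumes = 60, seed = 9)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$truth, b$truth)
  expect_identical(a$states, b$states)
  expect_identical(lapply(a$timeseries, `[[`, "data"),
                   lapply(b$timeseries, `[[`, "data"))
})

test_that("tiny cohorts are refused", {
  expect_error(simulate_cohort(cohort_spec(n_subjects = 4)), "at least 5")
})

test_that("written cohorts round-trip through the manifest", {
  dir <- withr::local_tempdir()
  cohort <- tiny_cohort(seed = 13)
  manifest <- write_cohort(cohort, dir)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(m$subject_id, cohort$truth$subject_id)
  expect_equal(m$uls, cohort$truth$uls)
  ts <- read_timeseries(m$path[1], tr_seconds = 1.714)
  expect_equal(unname(ts$data), unname(cohort$timeseries[[1]]$data),
               tolerance = 1e-12)
  truth <- readr::read_csv(file.path(dir, "ground_truth.csv"),
                           show_col_types = FALSE)
  expect_equal(truth$occupancy, cohort$truth$occupancy)
})
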
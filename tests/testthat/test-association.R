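test_that("spearman_rho handles monotone and degenerate inputs", {
  expect_equal(as.numeric(spearman_rho(1:5, 5:1)), -1)
  expect_equal(as.numeric(spearman_rho(1:5, 1:5)), 1)
  out <- spearman_rho(c(1, 2, 3, 4, 5), c(2, 2, 2, 2, 2))
  expect_true(is.na(out))
  expect_true(attr(out, "degenerate"))
  # tie-corrected: matches cor(..., method = "spearman")
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  expect_equal(as.numeric(spearman_rho(x, y)),
               cor(x, y, method = "spearman"))
})

test_that("a near-perfect monotone association is significant", {
  withr::with_seed(1, {
    uls <- sample(rep(0:4, c(1, 6, 5, 4, 4)))
    metric <- -uls + rnorm(20, sd = 0.01)
  })
  res <- permutation_test(metric, uls, n_perm = 1000, seed = 5)
  expect_true(res$significant)
  expect_lte(res$p_perm, 0.01)
  expect_lt(res$rho, -0.9)
  expect_gte(res$p_perm, 1 / 1001)
})

test_that("permutation nulls are seeded and shared consistently", {
  metric <- rnorm(20)
  uls <- sample(0:4, 20, replace = TRUE)
  a <- permutation_test(metric, uls, n_perm = 300, seed = 7)
  b <- permutation_test(metric, uls, n_perm = 300, seed = 7)
  expect_identical(a, b)
  c <- permutation_test(metric, uls, n_perm = 300, seed = 8)
  expect_false(isTRUE(all.equal(a$null_q99, c$null_q99)))
  perms <- make_permutations(20, 300, seed = 9)
  expect_equal(dim(perms), c(20L, 300L))
  expect_true(all(apply(perms, 2, sort) == 1:20))
})

test_that("the one-sided negative rule only flags the negative tail", {
  withr::with_seed(2, {
    uls <- sample(rep(0:4, c(1, 6, 5, 4, 4)))
    pos_metric <- uls + rnorm(20, sd = 0.01)
  })
  two <- permutation_test(pos_metric, uls, n_perm = 500, seed = 1)
  neg <- permutation_test(pos_metric, uls, n_perm = 500, seed = 1,
                          alternative = "less")
  expect_true(two$significant)
  expect_false(neg$significant)
})

test_that("degenerate metrics give an explicit degenerate test result", {
  res <- permutation_test(rep(3, 10), sample(0:4, 10, replace = TRUE),
                          n_perm = 200, seed = 1)
  expect_true(res$degenerate)
  expect_false(res$significant)
  expect_true(is.na(res$rho))
})

test_that("identify_dcmn picks the largest significant |rho| and reports all nodes", {
  withr::with_seed(3, {
    uls <- rep(0:4, 4)
    subj <- sprintf("s%02d", 1:20)
    strong <- -2 * uls + rnorm(20, sd = 0.1)     # |rho| close to 1
    medium <- uls + rnorm(20, sd = 0.8)          # weaker, positive
    occupancy <- dplyr::bind_rows(
      tibble::tibble(subject_id = subj, node = 1L, node_label = "weak",
                     hcm_windows = withr::with_seed(4, rpois(20, 50))),
      tibble::tibble(subject_id = subj, node = 2L, node_label = "strong",
                     hcm_windows = as.integer(round(100 + 10 * strong))),
      tibble::tibble(subject_id = subj, node = 3L, node_label = "medium",
                     hcm_windows = as.integer(round(100 + 10 * medium)))
    )
  })
  truth <- tibble::tibble(subject_id = subj, uls = uls)
  res <- identify_dcmn(occupancy, truth, n_perm = 500, seed = 2)
  expect_s3_class(res, "dcmn_result")
  expect_equal(res$dcmn, 2L)
  expect_lt(res$rho, 0)
  expect_equal(nrow(res$table), 3)
  expect_gte(sum(res$table$significant), 2)

  # invariance to node order
  res2 <- identify_dcmn(occupancy[order(-occupancy$node), ], truth,
                        n_perm = 500, seed = 2)
  expect_equal(res2$dcmn, res$dcmn)
  expect_equal(res2$table$rho, res$table$rho)

  # null occupancancies: explicit "no DCMN"
  null_occ <- occupancy
  null_occ$hcm_windows <- withr::with_seed(9, rpois(60, 50))
  res3 <- identify_dcmn(null_occ, truth, n_perm = 500, seed = 2)
  expect_true(is.na(res3$dcmn))
})

test_that("linked-mode counts windows with an edge to the DCMN during its HCM", {
  adj <- array(0L, dim = c(4, 3, 3))  # 4 windows, 3 nodes; DCMN = node 3
  adj[1, 1, 3] <- adj[1, 3, 1] <- 1L
  adj[3, 1, 3] <- adj[3, 3, 1] <- 1L
  adj[3, 2, 3] <- adj[3, 2, 3] <- 1L
  adj[3, 3, 2] <- 1L
  adj[4, 2, 3] <- adj[4, 3, 2] <- 1L
  graphs <- structure(
    list(adj = adj, density = 0.2, window_starts = 0:3, subject_id = "s1",
         node_labels = c("a", "b", "dcmn")),
    class = "binary_graphs"
  )
  model <- structure(
    list(node = 3L, node_label = "dcmn", k = 2L, centroids = c(2, 10),
         labels = list(s1 = c(1L, 2L, 1L, 2L)), hcm_id = 1L,
         mpfc_by_k = c(`2` = 1), sizes = c(2L, 2L)),
    class = "mode_model"
  )
  lm_tbl <- linked_mode(graphs, model, dcmn = 3)
  # HCM windows are 1 and 3; node a has DCMN edges in both, node b only in 3
  expect_equal(lm_tbl$lm_windows[lm_tbl$node_label == "a"], 2L)
  expect_equal(lm_tbl$lm_windows[lm_tbl$node_label == "b"], 1L)
  expect_false(3 %in% lm_tbl$node)
  expect_true(all(lm_tbl$lm_windows <= sum(model$labels$s1 == 1L)))

  # window/label mismatch is a structural error naming the subject
  bad <- model
  bad$labels$s1 <- c(1L, 2L)
  expect_error(linked_mode(graphs, bad, dcmn = 3), "s1")
})

test_that("partial spearman controls a covariate via rank residuals", {
  withr::with_seed(6, {
    n <- 200
    metric <- rnorm(n)
    uls <- sample(0:4, n, replace = TRUE)
    cov_ind <- rnorm(n)
  })
  plain <- as.numeric(spearman_rho(metric, uls))
  partial <- as.numeric(partial_spearman(metric, uls, cov_ind))
  expect_lt(abs(partial - plain), 0.1)

  expect_message(
    same <- partial_spearman(metric, uls, rep(1, n)),
    "constant covariate"
  )
  expect_equal(as.numeric(same), plain)

  degen <- partial_spearman(metric, uls, metric)
  expect_true(is.na(degen))
  expect_true(attr(degen, "degenerate"))
})

test_that("permutation p-values are valid under independence", {
  # P(p <= alpha) <= alpha + binomial noise for a modest simulation
  withr::with_seed(10, {
    hits05 <- 0
    reps <- 200
    uls_pool <- rep(0:4, c(1, 6, 5, 4, 4))
    for (r in seq_len(reps)) {
      p <- permutation_test(rnorm(20), sample(uls_pool), n_perm = 200,
                            seed = 1000 + r)$p_perm
      hits05 <- hits05 + (p <= 0.05)
    }
  })
  expect_lte(hits05, qbinom(0.995, 200, 0.05) + 3)
})
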
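# Synthetic cohort generator: multivariate time series with a planted
# state-switching hub node and an ordinal impairment score coupled to the
# time the hub spends in its high-connectivity state. Used as ground truth
# for end-to-end recovery tests of the pipeline.

#' Specify a synthetic cohort
#'
#' Defaults emulate the study conditions the pipeline targets: 20 subjects,
#' a 20-node motor network, 260 volumes at TR = 1.714 s, and an upper-limb
#' score (ULS, 0-4) whose rank correlation with hub-state occupancy is
#' `coupling_rho`.
#'
#' @param n_subjects number of subjects (at least 5).
#' @param n_nodes number of network nodes (at least 3).
#' @param n_volumes number of volumes (time points) per subject.
#' @param tr_seconds repetition time in seconds.
#' @param hub_index index of the planted hub node.
#' @param occupancy_range numeric pair: the range over which per-subject
#'   target hub-state occupancies are spread.
#' @param coupling_rho target Spearman correlation between occupancy and
#'   ULS, in `[-1, 0]` (more impairment goes with less hub-state time).
#' @param state_dwell_mean_tr mean dwell time of the hub state, in TRs.
#'   Several times the analysis window step so windows can resolve states.
#' @param noise_sd standard deviation of white measurement noise added on
#'   top of the unit-variance state signal.
#' @param seed integer seed; every random draw in the cohort derives from it.
#' @return A `cohort_spec` object (a validated list).
#' @examples
#' spec <- cohort_spec(n_subjects = 6, n_volumes = 80, seed = 42)
#' spec$hub_index
#' @export
cohort_spec <- function(n_subjects = 20, n_nodes = 20, n_volumes = 260,
                        tr_seconds = 1.714, hub_index = 5,
                        occupancy_range = c(0.15, 0.85), coupling_rho = -0.6,
                        state_dwell_mean_tr = 200, noise_sd = 0.3, seed = 1) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 1L)
  n_nodes <- check_count(n_nodes, "n_nodes", min = 3L)
  n_volumes <- check_count(n_volumes, "n_volumes", min = 2L)
  tr_seconds <- check_positive(tr_seconds, "tr_seconds")
  hub_index <- check_count(hub_index, "hub_index")
  if (hub_index > n_nodes) abort("`hub_index` must not exceed `n_nodes`")
  if (length(occupancy_range) != 2L || anyNA(occupancy_range) ||
      occupancy_range[1] < 0 || occupancy_range[2] > 1 ||
      occupancy_range[1] >= occupancy_range[2]) {
    abort("`occupancy_range` must satisfy 0 <= min < max <= 1")
  }
  if (length(coupling_rho) != 1L || is.na(coupling_rho) ||
      coupling_rho < -1 || coupling_rho > 0) {
    abort("`coupling_rho` must be in [-1, 0]")
  }
  state_dwell_mean_tr <- check_positive(state_dwell_mean_tr, "state_dwell_mean_tr")
  if (length(noise_sd) != 1L || is.na(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be a single non-negative number")
  }
  structure(
    list(n_subjects = n_subjects, n_nodes = n_nodes, n_volumes = n_volumes,
         tr_seconds = tr_seconds, hub_index = hub_index,
         occupancy_range = as.numeric(occupancy_range),
         coupling_rho = as.numeric(coupling_rho),
         state_dwell_mean_tr = state_dwell_mean_tr,
         noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_spec> %d subjects, %d nodes, %d volumes (TR %gs)\n",
    "  hub node %d, occupancy %g-%g, coupling rho %g, seed %d\n"),
    x$n_subjects, x$n_nodes, x$n_volumes, x$tr_seconds, x$hub_index,
    x$occupancy_range[1], x$occupancy_range[2], x$coupling_rho, x$seed))
  invisible(x)
}

# Tiered correlation structure centred on `hub`. Satellites are split into
# two groups whose cross-correlation sits below the proportional-threshold
# cut, so the hub is the only bridge between them and collects the
# between-group shortest paths. The leftover nodes form a chain community so
# no single peripheral node can out-rank the hub. Weight tiers are separated
# by gaps larger than any jitter so edge ordering is unambiguous.
build_hub_matrix <- function(n, hub, jitter = NULL) {
  others <- setdiff(seq_len(n), hub)
  n_sat <- min(length(others), max(2L, ceiling((n - 1) / 2)))
  sats <- others[seq_len(n_sat)]
  rest <- setdiff(others, sats)
  g_a <- sats[seq_len(ceiling(length(sats) / 2))]
  g_b <- setdiff(sats, g_a)
  small <- n <= 6
  S <- matrix(0.05, n, n)
  # Pairs inside a community are graded in round-robin (ring, then
  # successively longer chords) order: every node's edges are spread evenly
  # across the tier, so no node systematically owns the weakest
  # (noise-flippable) weights and node roles stay exchangeable wherever the
  # proportional cut falls.
  round_robin_pairs <- function(nodes) {
    m <- length(nodes)
    out <- list()
    for (d in seq_len(floor(m / 2))) {
      for (i in seq_len(m)) {
        j <- (i + d - 1L) %% m + 1L
        if (d < m / 2 || i <= m / 2) out[[length(out) + 1L]] <- c(nodes[i], nodes[j])
      }
    }
    out
  }
  # The leftover community keeps a fixed small backbone (its first few
  # round-robin pairs) that clears the proportional cut in *both* states;
  # its remaining pairs sit far below the cut. Its topology is therefore
  # state-independent by construction.
  if (length(rest) >= 2) {
    pairs <- round_robin_pairs(rest)
    for (pr in seq_along(pairs)) {
      p <- pairs[[pr]]
      S[p[1], p[2]] <- S[p[2], p[1]] <- 0.52 - 5e-4 * (pr - 1)
    }
  }
  # cross-group correlations stay well below the 20% cut in either state:
  # the hub is the groups' only reliable bridge while its state is active
  pr <- 0
  for (d in seq_along(g_b)) {
    for (i in seq_along(g_a)) {
      b <- g_b[(i + d - 2L) %% length(g_b) + 1L]
      S[g_a[i], b] <- S[b, g_a[i]] <- (if (small) 0.15 else 0.24) - 5e-4 * pr
      pr <- pr + 1
    }
  }
  within <- if (small) 0.15 else 0.58
  for (g in list(g_a, g_b)) {
    if (length(g) >= 2) {
      pairs <- round_robin_pairs(g)
      for (pr in seq_along(pairs)) {
        p <- pairs[[pr]]
        S[p[1], p[2]] <- S[p[2], p[1]] <- within - 5e-4 * (pr - 1)
      }
    }
  }
  # the two designated linked satellites get the strongest hub edges so
  # their hub connection survives windowing noise almost surely
  hub_r <- c(0.74, 0.73, 0.66 - 0.008 * (seq_len(max(0, length(sats) - 2)) - 1))
  for (i in seq_along(sats)) {
    S[hub, sats[i]] <- S[sats[i], hub] <- hub_r[i]
  }
  if (length(rest)) {
    for (i in seq_along(rest)) S[hub, rest[i]] <- S[rest[i], hub] <- 0.12
  }
  if (!is.null(jitter)) {
    J <- matrix(0, n, n)
    J[upper.tri(J)] <- jitter
    S <- S + J + t(J)
  }
  diag(S) <- 1
  attr(S, "satellites") <- sats
  attr(S, "groups") <- list(a = g_a, b = g_b)
  attr(S, "rest") <- rest
  S
}

# Repair a symmetric matrix that fails positive definiteness: clip
# eigenvalues at a small floor and rescale back to unit diagonal.
ensure_correlation <- function(S, label) {
  atts <- attributes(S)[c("satellites", "groups", "rest")]
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 1e-10) {
    inform(sprintf(
      "state covariance '%s' was not positive definite (min eigenvalue %.2e); repaired by eigenvalue clipping",
      label, min(ev$values)))
    vals <- pmax(ev$values, 1e-6)
    S <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    S <- stats::cov2cor(S)
    S <- (S + t(S)) / 2
  }
  attributes(S)[names(atts)] <- atts
  S
}

#' Planted-hub state covariance matrices
#'
#' Builds the two N x N correlation matrices that define the hub node's two
#' connectivity states. In the *hub* state the hub is strongly correlated
#' (>= 0.6) with at least half of the other nodes, which are split into two
#' groups whose mutual correlation falls below the 20% proportional
#' threshold -- making the hub the sole bridge between them, hence the node
#' with the highest betweenness centrality of the thresholded graph. In the
#' *non-hub* state the hub's correlations are uniformly weak (0.05) and an
#' alternative node carries the strong structure instead. Non-positive-
#' definite constructions are repaired by eigenvalue clipping and reported.
#'
#' The first two satellites (the hub's two strongest partners in the hub
#' state) are designated "linked" nodes: their edge to the hub exists
#' essentially only while the hub state is active, which grounds the
#' linked-mode recovery tests.
#'
#' @param n_nodes number of nodes (at least 3).
#' @param hub_index index of the hub node.
#' @param seed optional integer seed for a tiny (+/- 5e-4) jitter of the
#'   correlation tiers; `NULL` gives the deterministic tier values.
#' @return A list of class `state_covariances` with elements `hub` and
#'   `nonhub` (correlation matrices), `satellites`, `linked` (two node
#'   indices) and `alt_hub`.
#' @examples
#' sc <- make_state_covariances(20, hub_index = 5)
#' range(eigen(sc$hub, symmetric = TRUE, only.values = TRUE)$values)
#' @export
make_state_covariances <- function(n_nodes, hub_index, seed = NULL) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 3L)
  hub_index <- check_count(hub_index, "hub_index")
  if (hub_index > n_nodes) abort("`hub_index` must not exceed `n_nodes`")
  npair <- n_nodes * (n_nodes - 1) / 2
  jit <- if (is.null(seed)) NULL else {
    with_seed(derive_seed(seed, 1L), runif(npair, -5e-4, 5e-4))
  }
  hub_mat <- ensure_correlation(
    build_hub_matrix(n_nodes, hub_index, jit), "hub")
  sats <- attr(hub_mat, "satellites")
  linked <- sats[1:2]

  # Non-hub state: identical peripheral structure, but the hub's row is
  # flattened to near zero. Sharing the background between states is what
  # keeps every *other* node's centrality statistically state-independent,
  # so only the hub (and its linked edges) carries a state-locked signal.
  jit2 <- if (is.null(seed)) NULL else {
    with_seed(derive_seed(seed, 2L), runif(npair, -5e-4, 5e-4))
  }
  nonhub_mat <- build_hub_matrix(n_nodes, hub_index, jit2)
  nonhub_mat[hub_index, -hub_index] <- 0.05
  nonhub_mat[-hub_index, hub_index] <- 0.05
  alt <- sats[1]
  if (n_nodes <= 6) {
    # at tiny N the flattened matrix has no strong edges left; keep one
    # strongly connected satellite pair so the state is not featureless
    pair <- sats[1:2]
    nonhub_mat[pair[1], pair[2]] <- nonhub_mat[pair[2], pair[1]] <- 0.6
  }
  nonhub_mat <- ensure_correlation(nonhub_mat, "nonhub")

  structure(
    list(hub = unname_keep(hub_mat), nonhub = unname_keep(nonhub_mat),
         satellites = sats, linked = linked, alt_hub = alt,
         hub_index = hub_index),
    class = "state_covariances"
  )
}

unname_keep <- function(S) {
  attr(S, "satellites") <- NULL
  attr(S, "groups") <- NULL
  attr(S, "rest") <- NULL
  S
}

# Two-state Markov chain with stationary hub-state probability `p` and mean
# hub-state dwell time `dwell` (TRs). Exit rates are capped at 1.
markov_states_once <- function(t, p, dwell) {
  q_leave_hub <- min(1, 1 / dwell)
  q_enter_hub <- min(1, q_leave_hub * p / (1 - p))
  states <- integer(t)
  states[1] <- rbinom(1L, 1L, p)
  u <- runif(t - 1L)
  for (i in seq_len(t - 1L)) {
    states[i + 1L] <- if (states[i] == 1L) {
      if (u[i] < q_leave_hub) 0L else 1L
    } else {
      if (u[i] < q_enter_hub) 1L else 0L
    }
  }
  states
}

# Conditioned chain: over a finite series the raw chain's realized occupancy
# wobbles by several times the cohort's between-subject spacing, which would
# clump subjects together; drawing a bounded number of chains and keeping
# the realization closest to the target keeps per-subject occupancies spaced
# as specified while preserving Markov dwell structure.
simulate_states <- function(t, p, dwell, tol = 0.02, max_draws = 100L) {
  if (p <= 0) return(integer(t))
  if (p >= 1) return(rep(1L, t))
  best <- NULL
  best_key <- c(Inf, Inf)
  for (i in seq_len(max_draws)) {
    states <- markov_states_once(t, p, dwell)
    gap <- abs(mean(states) - p)
    # among on-target draws prefer the fewest state episodes (longest
    # realized dwells); off-target draws rank purely by occupancy gap
    key <- if (gap <= tol) c(sum(diff(states) != 0L), gap) else c(Inf, gap)
    if (key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2])) {
      best <- states
      best_key <- key
    }
    if (best_key[1] <= 1) break
  }
  best
}

#' Simulate one subject's time series
#'
#' Draws a two-state Markov state sequence with the requested stationary
#' hub-state occupancy and mean dwell time, then samples each volume from a
#' multivariate normal with the covariance of the active state
#' (temporally white within state), plus optional white measurement noise.
#'
#' @param spec a [cohort_spec()].
#' @param occupancy target hub-state occupancy in `[0, 1]`.
#' @param seed integer seed (bit-identical output for identical seeds).
#' @param subject_id subject identifier for the returned series.
#' @param covariances optional precomputed [make_state_covariances()] result.
#' @return A list with `ts` (an [roi_timeseries()]), `states` (integer 0/1
#'   vector, 1 = hub state) and `occupancy` (the realized mean of `states`).
#' @export
simulate_subject <- function(spec, occupancy, seed, subject_id = "subject",
                             covariances = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  occupancy <- check_probability(occupancy, "occupancy")
  covs <- covariances %||%
    make_state_covariances(spec$n_nodes, spec$hub_index, seed = spec$seed)
  r_hub <- chol(covs$hub)
  r_non <- chol(covs$nonhub)
  t_len <- spec$n_volumes
  n <- spec$n_nodes
  with_seed(seed, {
    states <- simulate_states(t_len, occupancy, spec$state_dwell_mean_tr)
    z <- matrix(rnorm(t_len * n), t_len, n)
    x <- matrix(NA_real_, t_len, n)
    in_hub <- states == 1L
    if (any(in_hub)) x[in_hub, ] <- z[in_hub, , drop = FALSE] %*% r_hub
    if (any(!in_hub)) x[!in_hub, ] <- z[!in_hub, , drop = FALSE] %*% r_non
    if (spec$noise_sd > 0) x <- x + spec$noise_sd * matrix(rnorm(t_len * n), t_len, n)
  })
  ts <- roi_timeseries(x, spec$tr_seconds, subject_id = subject_id,
                       node_labels = default_node_labels(n))
  list(ts = ts, states = states, occupancy = mean(states))
}

# ULS marginal close to a motor-stroke cohort: ~5% unimpaired, ~55%
# mild/moderate (1-2), ~40% severe (3-4). Largest-remainder rounding.
uls_counts <- function(n) {
  props <- c(0.05, 0.30, 0.25, 0.20, 0.20)
  raw <- props * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Couple ULS to occupancy by deterministic block-permutation rank binning:
# subjects ordered by decreasing occupancy are cut into contiguous blocks
# sized to the ULS marginal, and each block is given one ULS level. Among
# all level-to-block permutations the one whose realized Spearman
# correlation is closest to the target is kept (seeded tie-break). Because
# subjects inside a block share a ULS level, the realized coupling is
# insensitive to small perturbations of the occupancy ordering -- the
# downstream estimate of occupancy (HCM window counts) sees the same
# correlation the generator planted.
assign_uls <- function(occupancy, target, seed) {
  n <- length(occupancy)
  counts <- uls_counts(n)
  grid <- as.matrix(expand.grid(rep(list(0:4), 5)))
  perms <- grid[apply(grid, 1, function(p) all(sort(p) == 0:4)), , drop = FALSE]
  ord <- order(-occupancy)
  shuffle <- with_seed(derive_seed(seed, 999L), sample.int(nrow(perms)))
  perms <- perms[shuffle, , drop = FALSE]
  best <- NULL
  best_gap <- Inf
  for (i in seq_len(nrow(perms))) {
    uls <- integer(n)
    uls[ord] <- rep(perms[i, ], counts[perms[i, ] + 1L])
    realized <- suppressWarnings(cor(occupancy, uls, method = "spearman"))
    if (is.na(realized)) realized <- 0
    gap <- abs(realized - target)
    if (gap < best_gap) {
      best <- uls
      best_gap <- gap
    }
  }
  as.integer(best)
}

#' Simulate a synthetic cohort
#'
#' Generates one time series per subject with per-subject hub-state
#' occupancies spread evenly over `spec$occupancy_range` (in seeded random
#' subject order), then assigns each subject an upper-limb score so that
#' the cohort's Spearman correlation between realized occupancy and ULS
#' tracks `spec$coupling_rho`.
#'
#' @param spec a [cohort_spec()]; `n_subjects` must be at least 5, below
#'   which the downstream association stage is untestable.
#' @return An object of class `synthetic_cohort`: a list with `timeseries`
#'   (named list of `roi_ts`), `truth` (tibble: `subject_id`, `uls`,
#'   `occupancy`), `states` (named list of 0/1 vectors), `covariances` and
#'   `spec`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 6, n_volumes = 60,
#'                                       n_nodes = 8, seed = 7))
#' cohort$truth
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_subjects < 5L) {
    abort("`n_subjects` must be at least 5 for the association stage to be testable")
  }
  covs <- make_state_covariances(spec$n_nodes, spec$hub_index, seed = spec$seed)
  targets <- seq(spec$occupancy_range[1], spec$occupancy_range[2],
                 length.out = spec$n_subjects)
  targets <- with_seed(derive_seed(spec$seed, 3L), sample(targets))
  ids <- sprintf("sub-%02d", seq_len(spec$n_subjects))
  subjects <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    subjects[[i]] <- simulate_subject(
      spec, targets[i], seed = derive_seed(spec$seed, 100L + i),
      subject_id = ids[i], covariances = covs
    )
  }
  occ <- vapply(subjects, `[[`, numeric(1), "occupancy")
  uls <- assign_uls(occ, spec$coupling_rho, seed = spec$seed)
  timeseries <- lapply(subjects, `[[`, "ts")
  states <- lapply(subjects, `[[`, "states")
  names(timeseries) <- names(states) <- ids
  structure(
    list(
      timeseries = timeseries,
      truth = tibble(subject_id = ids, uls = uls, occupancy = occ),
      states = states,
      covariances = covs,
      spec = spec
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects x (%d volumes, %d nodes), hub node %d\n",
              length(x$timeseries), x$spec$n_volumes, x$spec$n_nodes,
              x$spec$hub_index))
  cat(sprintf("  realized Spearman(occupancy, ULS) = %.3f\n",
              cor(x$truth$occupancy, x$truth$uls, method = "spearman")))
  invisible(x)
}

#' @rdname simulate_cohort
#' @param x a `synthetic_cohort`.
#' @param ... unused.
#' @export
tidy.synthetic_cohort <- function(x, ...) x$truth

#' Write a synthetic cohort to disk
#'
#' Writes one CSV per subject (readable by [read_timeseries()]), a cohort
#' manifest (`manifest.csv`: subject_id, path, uls) and a ground-truth file
#' (`ground_truth.csv`: subject_id, uls, occupancy and the binary state
#' sequence as a compact 0/1 string).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort$timeseries)
  files <- paste0(ids, ".csv")
  for (i in seq_along(ids)) {
    write_timeseries(cohort$timeseries[[i]], file.path(dir, files[i]))
  }
  manifest <- tibble(subject_id = ids, path = files, uls = cohort$truth$uls)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  truth <- cohort$truth
  truth$states <- vapply(cohort$states, paste, character(1), collapse = "")
  readr::write_csv(truth, file.path(dir, "ground_truth.csv"), progress = FALSE)
  invisible(manifest)
}
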
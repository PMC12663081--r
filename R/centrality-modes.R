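# Per-node "centrality modes": k-means clustering of the cohort-concatenated
# windowed rank-BC sequence under the cityblock (Manhattan) metric, with the
# cluster count chosen by a mixed performance criterion
# MPFC = (CS * AS * DI) / DB. For 1-D observations the cityblock centroid is
# the median, so the clustering is median-update k-means; all validity
# indices use the same cityblock distance.

# mean |x - y| of each query point against a sorted set with prefix sums
mad_to_set <- function(xq, ys, ps) {
  m <- length(ys)
  p <- findInterval(xq, ys)
  ps0 <- c(0, ps)
  slo <- ps0[p + 1]
  (xq * p - slo + (ps[m] - slo) - xq * (m - p)) / m
}

#' Mixed performance criterion for a 1-D clustering
#'
#' `MPFC = (CS * AS * DI) / DB` under the cityblock distance, where CS is
#' the average cluster size (n/k), AS the average silhouette, DI the Dunn
#' index (minimum inter-cluster point distance over maximum intra-cluster
#' diameter), and DB the Davies-Bouldin index computed from mean absolute
#' deviations around the cluster centroids.
#'
#' Degenerate configurations are signalled rather than silently propagated:
#' an empty cluster or an all-singleton partition (zero maximum diameter)
#' yields `NA` with a `reason` attribute, and coincident centroids (zero DB
#' denominator) yield `-Inf`.
#'
#' @param points numeric vector of 1-D observations.
#' @param labels integer cluster assignment in `1:k`.
#' @param centroids optional k centroid values; defaults to cluster medians.
#' @return The criterion value, with the four components attached as the
#'   `components` attribute.
#' @examples
#' x <- c(rnorm(30, 2, 0.2), rnorm(30, 18, 0.2))
#' mpfc(x, rep(1:2, each = 30))
#' @export
mpfc <- function(points, labels, centroids = NULL) {
  if (length(points) != length(labels)) {
    abort("`points` and `labels` must have equal length")
  }
  labels <- as.integer(labels)
  k <- if (is.null(centroids)) max(labels) else length(centroids)
  if (k < 2L) abort("the criterion needs at least 2 clusters")
  sizes <- tabulate(labels, nbins = k)
  if (any(sizes == 0L)) {
    out <- NA_real_
    attr(out, "reason") <- sprintf("empty cluster (k = %d)", k)
    return(out)
  }
  n <- length(points)
  if (is.null(centroids)) {
    centroids <- vapply(seq_len(k), function(c) median(points[labels == c]),
                        numeric(1))
  }

  # silhouette under cityblock distance, O(n log n) via sorted prefix sums
  sets <- lapply(seq_len(k), function(c) {
    ys <- sort(points[labels == c])
    list(ys = ys, ps = cumsum(ys))
  })
  mad <- vapply(seq_len(k),
                function(c) mad_to_set(points, sets[[c]]$ys, sets[[c]]$ps),
                numeric(n))
  a <- ifelse(sizes[labels] > 1L,
              mad[cbind(seq_len(n), labels)] * sizes[labels] /
                (sizes[labels] - 1L),
              0)
  other <- mad
  other[cbind(seq_len(n), labels)] <- Inf
  b <- apply(other, 1, min)
  denom <- pmax(a, b)
  sil <- ifelse(denom > 0 & sizes[labels] > 1L, (b - a) / denom, 0)
  as_mean <- mean(sil)

  # Dunn index: min inter-cluster point distance / max intra-cluster diameter
  ord <- order(points)
  xs <- points[ord]
  ls <- labels[ord]
  gaps <- diff(xs)
  inter <- if (any(diff(ls) != 0L)) min(gaps[diff(ls) != 0L]) else Inf
  diam <- max(vapply(seq_len(k),
                     function(c) diff(range(points[labels == c])), numeric(1)))
  if (diam == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero intra-cluster diameter"
    return(out)
  }
  di <- inter / diam

  # Davies-Bouldin with cityblock scatter
  dmu <- abs(outer(centroids, centroids, "-"))
  if (any(dmu[upper.tri(dmu)] == 0)) {
    out <- -Inf
    attr(out, "reason") <- "coincident centroids"
    return(out)
  }
  s_c <- vapply(seq_len(k),
                function(c) mean(abs(points[labels == c] - centroids[c])),
                numeric(1))
  r_mat <- outer(s_c, s_c, "+") / dmu
  diag(r_mat) <- -Inf
  db <- mean(apply(r_mat, 1, max))

  cs <- n / k
  out <- if (db == 0) Inf else (cs * as_mean * di) / db
  attr(out, "components") <- list(cs = cs, as = as_mean, di = di, db = db)
  out
}

# Median-update k-means for 1-D data under cityblock distance, exploiting
# that nearest-centroid assignment partitions the sorted sample into
# contiguous segments: each iteration is O(k log n) after one sort.
kmedians_1d <- function(x, k, n_start = 20L, max_iter = 300L, seed = NULL) {
  n <- length(x)
  ux <- unique(x)
  if (length(ux) < k) return(NULL)
  xs <- sort(x)
  ps <- cumsum(xs)
  ps0 <- c(0, ps)

  seg_median <- function(lo, hi) {
    len <- hi - lo + 1L
    mid <- lo + (len - 1L) %/% 2L
    if (len %% 2L == 1L) xs[mid] else (xs[mid] + xs[mid + 1L]) / 2
  }
  seg_cost <- function(lo, hi, m) {
    p <- lo - 1L + findInterval(m, xs[lo:hi])
    m * (p - lo + 1L) - (ps0[p + 1L] - ps0[lo]) +
      (ps0[hi + 1L] - ps0[p + 1L]) - m * (hi - p)
  }
  run_once <- function(cent) {
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      cent <- sort(cent)
      if (anyDuplicated(cent)) {
        cent <- unique(cent)
        cent <- c(cent, ux[!ux %in% cent][seq_len(k - length(cent))])
        cent <- sort(cent)
      }
      mids <- (cent[-1] + cent[-k]) / 2
      bounds <- c(0L, findInterval(mids, xs), n)
      lo <- bounds[-length(bounds)] + 1L
      hi <- bounds[-1]
      if (any(hi < lo)) {
        # empty segment: re-seed its centroid at the point farthest from
        # the nearest non-empty centroid, deterministically
        live <- hi >= lo
        d_near <- do.call(pmin, lapply(cent[live], function(cc) abs(xs - cc)))
        cent[!live] <- xs[order(-d_near)][seq_len(sum(!live))]
        next
      }
      new_cent <- vapply(seq_len(k), function(j) seg_median(lo[j], hi[j]),
                         numeric(1))
      if (identical(new_cent, cent)) {
        converged <- TRUE
        break
      }
      cent <- new_cent
    }
    cost <- sum(vapply(seq_len(k),
                       function(j) seg_cost(lo[j], hi[j], cent[j]), numeric(1)))
    list(cent = cent, mids = mids, cost = cost, converged = converged)
  }

  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_start)) {
      # k-means++-style seeding with cityblock-distance weighting
      cent <- numeric(k)
      cent[1] <- x[sample.int(n, 1L)]
      d <- abs(x - cent[1])
      for (j in 2:k) {
        cent[j] <- if (sum(d) == 0) {
          pool <- ux[!ux %in% cent[seq_len(j - 1L)]]
          pool[sample.int(length(pool), 1L)]
        } else {
          x[sample.int(n, 1L, prob = d)]
        }
        d <- pmin(d, abs(x - cent[j]))
      }
      fit <- run_once(cent)
      if (is.null(best) || fit$cost < best$cost) best <- fit
    }
  })
  if (!best$converged) {
    warn(sprintf("k-medians (k = %d) did not converge in %d iterations; using best iterate",
                 k, max_iter))
  }
  labels <- findInterval(x, best$mids) + 1L
  list(centroids = best$cent, labels = labels, cost = best$cost,
       sizes = tabulate(labels, nbins = k))
}

#' Fit centrality modes for one node
#'
#' Concatenates the node's windowed rank-BC values across all subjects,
#' clusters them with seeded cityblock k-means (k-means++-style starts,
#' median updates) for every candidate k, scores each k with [mpfc()], and
#' keeps the k with the highest criterion. Modes are relabelled by
#' ascending centroid, so mode 1 -- the smallest mean rank, i.e. the
#' highest centrality -- is the high-centrality mode (HCM).
#'
#' @param traces a `centrality_trace` or list of them (one per subject).
#' @param node node index to fit.
#' @param k_grid candidate cluster counts (all >= 2).
#' @param n_start number of k-means restarts per k.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed.
#' @return An object of class `mode_model`: `node`, `node_label`, `k`,
#'   `centroids` (ascending), `labels` (named list of per-subject,
#'   per-window mode sequences), `hcm_id` (always 1 after relabelling),
#'   `mpfc_by_k`, `sizes`.
#' @export
fit_modes <- function(traces, node, k_grid = 2:6, n_start = 20L,
                      max_iter = 300L, seed = 1L) {
  if (inherits(traces, "centrality_trace")) traces <- list(traces)
  if (!length(traces) || !all(vapply(traces, inherits, logical(1), "centrality_trace"))) {
    abort("`traces` must be one or more centrality_trace objects")
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 2L)) abort("`k_grid` values must be at least 2")
  node <- check_count(node, "node")
  n_nodes <- ncol(traces[[1]]$rank)
  if (node > n_nodes) abort("`node` exceeds the number of nodes")
  node_label <- traces[[1]]$node_labels[node]
  ids <- vapply(traces, `[[`, character(1), "subject_id")
  lens <- vapply(traces, function(tr) nrow(tr$rank), integer(1))
  x <- unlist(lapply(traces, function(tr) tr$rank[, node]), use.names = FALSE)
  if (length(x) <= max(k_grid)) {
    abort("fewer observations than the largest candidate k")
  }

  if (length(unique(x)) == 1L) {
    inform(sprintf("node %d ('%s'): constant rank trace; single mode fitted",
                   node, node_label))
    fits <- list()
    k_sel <- 1L
    centroids <- x[1]
    labels_all <- rep(1L, length(x))
    mpfc_by_k <- stats::setNames(rep(NA_real_, length(k_grid)), k_grid)
  } else {
    fits <- list()
    mpfc_by_k <- stats::setNames(rep(NA_real_, length(k_grid)), k_grid)
    for (k in k_grid) {
      fit <- kmedians_1d(x, k, n_start = n_start, max_iter = max_iter,
                         seed = derive_seed(seed, 10L + k))
      if (is.null(fit) || any(fit$sizes == 0L)) {
        inform(sprintf(
          "node %d ('%s'): k = %d excluded (no valid partition with %d nonempty clusters)",
          node, node_label, k, k))
        next
      }
      fits[[as.character(k)]] <- fit
      mpfc_by_k[as.character(k)] <- as.numeric(mpfc(x, fit$labels, fit$centroids))
    }
    finite <- which(is.finite(mpfc_by_k))
    if (!length(finite)) {
      k_sel <- k_grid[which(as.character(k_grid) %in% names(fits))][1]
      if (is.na(k_sel)) abort("no candidate k produced a valid clustering")
      inform(sprintf(
        "node %d ('%s'): low separation, criterion undefined for every k; smallest candidate k = %d kept",
        node, node_label, k_sel))
    } else {
      k_sel <- as.integer(names(mpfc_by_k)[finite[which.max(mpfc_by_k[finite])]])
    }
    fit <- fits[[as.character(k_sel)]]
    ord <- order(fit$centroids)
    relabel <- integer(k_sel)
    relabel[ord] <- seq_len(k_sel)
    centroids <- fit$centroids[ord]
    labels_all <- relabel[fit$labels]
  }

  stops <- cumsum(lens)
  starts <- c(1L, head(stops, -1L) + 1L)
  labels <- lapply(seq_along(lens),
                   function(i) labels_all[starts[i]:stops[i]])
  names(labels) <- ids

  structure(
    list(node = node, node_label = node_label, k = length(centroids),
         centroids = centroids, labels = labels, hcm_id = 1L,
         mpfc_by_k = mpfc_by_k,
         sizes = tabulate(labels_all, nbins = length(centroids))),
    class = "mode_model"
  )
}

#' @export
print.mode_model <- function(x, ...) {
  cat(sprintf("<mode_model> node %d ('%s'): k = %d, centroids [%s], HCM centroid %.2f\n",
              x$node, x$node_label, x$k,
              paste(sprintf("%.2f", x$centroids), collapse = ", "),
              x$centroids[x$hcm_id]))
  invisible(x)
}

#' Fit centrality modes for every node
#'
#' @inheritParams fit_modes
#' @param nodes node indices to fit; defaults to all.
#' @return A named list of [fit_modes()] results, class `mode_models`.
#' @export
fit_modes_cohort <- function(traces, nodes = NULL, k_grid = 2:6,
                             n_start = 20L, max_iter = 300L, seed = 1L) {
  if (inherits(traces, "centrality_trace")) traces <- list(traces)
  nodes <- nodes %||% seq_len(ncol(traces[[1]]$rank))
  models <- lapply(nodes, function(v) {
    fit_modes(traces, v, k_grid = k_grid, n_start = n_start,
              max_iter = max_iter, seed = derive_seed(seed, 500L + v))
  })
  names(models) <- traces[[1]]$node_labels[nodes]
  structure(models, class = "mode_models")
}

#' High-centrality-mode occupancy
#'
#' Number of sliding windows each subject spends in a node's
#' high-centrality mode.
#'
#' @param model a `mode_model`.
#' @return A tibble with `subject_id`, `node`, `node_label`, `hcm_windows`.
#' @export
hcm_occupancy <- function(model) {
  stopifnot(inherits(model, "mode_model"))
  tibble(
    subject_id = names(model$labels),
    node = model$node,
    node_label = model$node_label,
    hcm_windows = vapply(model$labels,
                         function(l) sum(l == model$hcm_id), integer(1))
  )
}

#' Occupancy table across nodes
#'
#' @param models a `mode_models` list (one `mode_model` per node).
#' @return A long tibble: `subject_id`, `node`, `node_label`, `hcm_windows`.
#'   Use [occupancy_matrix()] for the subject-by-node wide form.
#' @export
occupancy_table <- function(models) {
  stopifnot(inherits(models, "mode_models") ||
              all(vapply(models, inherits, logical(1), "mode_model")))
  list_rbind(lapply(models, hcm_occupancy))
}

#' @rdname occupancy_table
#' @param occupancy a long occupancy tibble from [occupancy_table()].
#' @export
occupancy_matrix <- function(occupancy) {
  wide <- tidyr::pivot_wider(occupancy[, c("subject_id", "node_label", "hcm_windows")],
                             names_from = "node_label",
                             values_from = "hcm_windows")
  out <- as.matrix(wide[, -1])
  rownames(out) <- wide$subject_id
  out
}
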
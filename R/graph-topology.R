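# Proportional thresholding of windowed connectivity matrices and
# per-window, per-node betweenness centrality with within-window ranks.

#' Proportional threshold of a connectivity matrix
#'
#' Keeps exactly `k = round(density * N(N-1)/2)` undirected edges: the k
#' largest off-diagonal weights, by signed value by default (`"absolute"`
#' ranks by magnitude instead, for sensitivity analyses). Ties at the cut
#' boundary are broken deterministically by ascending `(i, j)` node-index
#' pair, and a warning reports how many boundary weights were tied.
#'
#' @param z N x N symmetric numeric matrix (diagonal ignored).
#' @param density fraction of edges to retain, in (0, 1).
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return Symmetric 0/1 integer matrix with zero diagonal and exactly k
#'   edges.
#' @examples
#' z <- matrix(0, 3, 3); z[1, 2] <- z[2, 1] <- 3
#' z[1, 3] <- z[3, 1] <- 2; z[2, 3] <- z[3, 2] <- 1
#' sum(proportional_threshold(z, 0.34)) / 2 # 1 edge
#' @export
proportional_threshold <- function(z, density = 0.2,
                                   mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (!is.matrix(z) || nrow(z) != ncol(z) || nrow(z) < 2L) {
    abort("`z` must be a square matrix with at least 2 nodes")
  }
  if (length(density) != 1L || is.na(density) || density <= 0 || density >= 1) {
    abort("`density` must be a single number in (0, 1)")
  }
  n <- nrow(z)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  w <- z[ut]
  if (mode == "absolute") w <- abs(w)
  k <- round(density * n * (n - 1) / 2)
  ord <- order(-w, ut[, 1], ut[, 2])
  adj <- matrix(0L, n, n)
  if (k > 0) {
    if (k < length(w)) {
      boundary <- w[ord[k]]
      n_tied <- sum(w == boundary)
      if (n_tied > 1L && w[ord[k + 1L]] == boundary) {
        warn(sprintf(
          "proportional threshold: %d weights tied at the cut boundary; resolved by node-index order",
          n_tied))
      }
    }
    keep <- ut[ord[seq_len(k)], , drop = FALSE]
    adj[keep] <- 1L
    adj <- adj + t(adj)
  }
  dimnames(adj) <- dimnames(z)
  adj
}

#' Betweenness centrality of a binary graph
#'
#' Raw (unnormalized) betweenness on an undirected, unweighted graph:
#' for each node v, the sum over unordered reachable pairs `{s, t}` (both
#' distinct from v) of the fraction of shortest s-t paths passing through v.
#' Pairs in different components contribute nothing; isolated nodes score 0.
#' Computed with Brandes' algorithm; [betweenness_exhaustive()] is the
#' explicit path-enumeration reference.
#'
#' @param adj symmetric 0/1 matrix with zero diagonal.
#' @return Numeric vector of betweenness values, one per node.
#' @examples
#' path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
#' betweenness_centrality(path3) # 0 1 0
#' @export
betweenness_centrality <- function(adj) {
  adj <- validate_adjacency(adj)
  out <- bc_brandes(adj)
  names(out) <- rownames(adj)
  out
}

#' @rdname betweenness_centrality
#' @export
betweenness_exhaustive <- function(adj) {
  adj <- validate_adjacency(adj)
  out <- bc_enumerate(adj)
  names(out) <- rownames(adj)
  out
}

validate_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    abort("`adj` must be a square matrix")
  }
  if (any(adj != 0 & adj != 1)) abort("`adj` must be binary (0/1)")
  if (any(diag(adj) != 0)) abort("`adj` must have a zero diagonal")
  if (any(adj != t(adj))) abort("`adj` must be symmetric")
  storage.mode(adj) <- "integer"
  adj
}

#' Descending centrality ranks with average ties
#'
#' Rank 1 marks the highest betweenness value and rank N the lowest; tied
#' values receive the average of the ranks they span, so every row of ranks
#' sums to `N(N+1)/2` regardless of ties.
#'
#' @param bc numeric vector of finite centrality values.
#' @return Numeric vector of ranks.
#' @examples
#' rank_centrality(c(5, 2, 9)) # 2 3 1
#' @export
rank_centrality <- function(bc) {
  if (!is.numeric(bc) || anyNA(bc) || any(!is.finite(bc))) {
    abort("`bc` must be a vector of finite numbers")
  }
  rank(-bc, ties.method = "average")
}

#' Binarize every window of a dynamic-connectivity series
#'
#' @param dfc a `dynamic_fc` object.
#' @inheritParams proportional_threshold
#' @return An object of class `binary_graphs`: list with `adj`
#'   (W x N x N 0/1 array), `density`, `window_starts`, `subject_id`,
#'   `node_labels`.
#' @export
binarize_windows <- function(dfc, density = 0.2,
                             mode = c("signed", "absolute")) {
  stopifnot(inherits(dfc, "dynamic_fc"))
  mode <- match.arg(mode)
  w_count <- dim(dfc$z)[1]
  n <- dim(dfc$z)[2]
  adj <- array(0L, dim = c(w_count, n, n))
  for (w in seq_len(w_count)) {
    adj[w, , ] <- proportional_threshold(dfc$z[w, , ], density, mode)
  }
  structure(
    list(adj = adj, density = density, window_starts = dfc$window_starts,
         subject_id = dfc$subject_id, node_labels = dfc$node_labels),
    class = "binary_graphs"
  )
}

#' @export
print.binary_graphs <- function(x, ...) {
  cat(sprintf("<binary_graphs> subject %s: %d windows x %d nodes, density %.2f\n",
              x$subject_id, dim(x$adj)[1], dim(x$adj)[2], x$density))
  invisible(x)
}

#' Per-window betweenness-centrality trace
#'
#' Thresholds each windowed connectivity matrix, computes raw betweenness
#' per node, and converts every window's values to descending average-tie
#' ranks (1 = most central).
#'
#' @param x a `dynamic_fc` or `binary_graphs` object.
#' @inheritParams proportional_threshold
#' @return An object of class `centrality_trace`: list with `bc` and `rank`
#'   (both W x N matrices), `window_starts`, `subject_id`, `node_labels`.
#' @export
centrality_trace <- function(x, density = 0.2,
                             mode = c("signed", "absolute")) {
  graphs <- if (inherits(x, "dynamic_fc")) {
    binarize_windows(x, density, match.arg(mode))
  } else if (inherits(x, "binary_graphs")) {
    x
  } else {
    abort("`x` must be a dynamic_fc or binary_graphs object")
  }
  w_count <- dim(graphs$adj)[1]
  n <- dim(graphs$adj)[2]
  bc <- matrix(NA_real_, w_count, n)
  rk <- matrix(NA_real_, w_count, n)
  for (w in seq_len(w_count)) {
    a <- matrix(graphs$adj[w, , ], n, n)
    storage.mode(a) <- "integer"
    bc[w, ] <- bc_brandes(a)
    rk[w, ] <- rank(-bc[w, ], ties.method = "average")
  }
  colnames(bc) <- colnames(rk) <- graphs$node_labels
  structure(
    list(bc = bc, rank = rk, window_starts = graphs$window_starts,
         subject_id = graphs$subject_id, node_labels = graphs$node_labels),
    class = "centrality_trace"
  )
}

#' @export
print.centrality_trace <- function(x, ...) {
  cat(sprintf("<centrality_trace> subject %s: %d windows x %d nodes\n",
              x$subject_id, nrow(x$rank), ncol(x$rank)))
  invisible(x)
}

#' @rdname centrality_trace
#' @param ... unused.
#' @export
tidy.centrality_trace <- function(x, ...) {
  w_count <- nrow(x$rank)
  tibble(
    subject_id = x$subject_id,
    window = rep(seq_len(w_count), times = ncol(x$rank)),
    node = rep(seq_along(x$node_labels), each = w_count),
    node_label = rep(x$node_labels, each = w_count),
    bc = as.vector(x$bc),
    rank = as.vector(x$rank)
  )
}

#' Write a rank trace as delimited text
#'
#' @param trace a `centrality_trace`.
#' @param path output CSV path (W rows x N node columns of ranks).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "centrality_trace"))
  readr::write_csv(as.data.frame(trace$rank), path, progress = FALSE)
  invisible(path)
}
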
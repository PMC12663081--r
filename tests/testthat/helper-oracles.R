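# Independent oracles used to validate the package implementations.

# Exhaustive betweenness by explicit enumeration of every geodesic,
# written in plain R (independent of the compiled code paths): for each
# pair, list all shortest paths with a DFS pruned by BFS distances and
# count pass-throughs.
bc_oracle_r <- function(adj) {
  n <- nrow(adj)
  nbr <- lapply(seq_len(n), function(i) which(adj[i, ] == 1))
  bfs <- function(s) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    q <- s
    while (length(q)) {
      v <- q[1]
      q <- q[-1]
      for (w in nbr[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          q <- c(q, w)
        }
      }
    }
    dist
  }
  bc <- numeric(n)
  for (t in seq_len(n)[-1]) {
    dist_t <- bfs(t)
    for (s in seq_len(t - 1L)) {
      if (is.na(dist_t[s])) next
      paths <- list()
      enum <- function(path) {
        u <- path[length(path)]
        if (u == t) {
          paths[[length(paths) + 1L]] <<- path
          return(invisible(NULL))
        }
        for (w in nbr[[u]]) {
          if (!is.na(dist_t[w]) && dist_t[w] == dist_t[u] - 1L) {
            enum(c(path, w))
          }
        }
      }
      enum(s)
      through <- numeric(n)
      for (p in paths) {
        if (length(p) > 2) {
          interior <- p[-c(1, length(p))]
          through[interior] <- through[interior] + 1
        }
      }
      bc <- bc + through / length(paths)
    }
  }
  bc
}

# random symmetric 0/1 adjacency with exactly m edges
random_adj <- function(n, m, seed) {
  withr::with_seed(seed, {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
    adj <- matrix(0L, n, n)
    adj[keep] <- 1L
    adj + t(adj)
  })
}

# naive O(n^2) mean silhouette under cityblock distance
silhouette_naive <- function(x, labels) {
  n <- length(x)
  k <- max(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) {
      s[i] <- 0
      next
    }
    a <- sum(abs(x[i] - x[own])) / (length(own) - 1L)
    b <- min(vapply(setdiff(seq_len(k), labels[i]), function(c) {
      mean(abs(x[i] - x[labels == c]))
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# small ready-made graphs
path3 <- rbind(c(0L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 0L))
star5 <- {
  m <- matrix(0L, 5, 5)
  m[1, 2:5] <- 1L
  m + t(m)
}
cycle4 <- {
  m <- matrix(0L, 4, 4)
  for (i in 1:4) {
    j <- i %% 4 + 1
    m[i, j] <- 1L
  }
  m + t(m)
}

# compact synthetic cohort used by several pipeline-level tests
tiny_cohort <- function(seed = 11, n_subjects = 6, n_volumes = 80,
                        n_nodes = 10) {
  simulate_cohort(cohort_spec(
    n_subjects = n_subjects, n_nodes = n_nodes, n_volumes = n_volumes,
    seed = seed
  ))
}
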
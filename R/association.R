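# Association between per-node high-centrality-mode occupancy and the
# ordinal impairment score: tie-corrected Spearman correlation with a
# permutation null, identification of the dynamic central motor node (DCMN),
# DCMN-linked-mode occurrence counting, and rank-residual partial
# correlations for covariate control.

#' Tie-corrected Spearman correlation
#'
#' Pearson correlation of average-tie ranks. If either variable's ranks are
#' constant the correlation is undefined; the function then returns `NA`
#' with attribute `degenerate = TRUE` instead of propagating `NaN`.
#'
#' @param x,y numeric vectors of equal length (at least 5).
#' @return A double, with a logical `degenerate` attribute.
#' @examples
#' spearman_rho(1:4, 4:1) # -1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 5L) abort("need at least 5 paired observations")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  structure(cor(rx, ry), degenerate = FALSE)
}

#' Shared permutation set
#'
#' The same permutations are reused for every node within one analysis so
#' per-node null distributions are comparable.
#'
#' @param n number of subjects.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return An `n` x `n_perm` integer matrix of permuted indices.
#' @export
make_permutations <- function(n, n_perm = 1000L, seed = 1L) {
  n <- check_count(n, "n", min = 2L)
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  with_seed(seed, {
    matrix(unlist(lapply(seq_len(n_perm), function(i) sample.int(n))),
           nrow = n, ncol = n_perm)
  })
}

#' Permutation test of a Spearman association
#'
#' Correlates a per-subject metric with the impairment score and builds a
#' null distribution by recomputing the correlation for `n_perm` random
#' permutations of the score. With the default two-sided rule the critical
#' value `null_q99` is the 99th percentile of the *signed* null correlations
#' and the observed `|rho|` must exceed it (two symmetric tails, nominal
#' level about 0.02); `alternative = "less"` instead compares the signed
#' observed rho against the 1st percentile of the null (negative tail).
#' `p_perm` is the add-one permutation p-value matching the chosen rule.
#'
#' @param metric per-subject numeric metric (e.g. HCM window counts).
#' @param uls per-subject ordinal impairment scores.
#' @param n_perm number of permutations (at least 100).
#' @param seed integer seed used when `perms` is not supplied.
#' @param alternative `"two.sided"` (default) or `"less"`.
#' @param q_level percentile of the null used as critical value.
#' @param perms optional precomputed [make_permutations()] matrix.
#' @return A one-row tibble: `rho`, `p_perm`, `null_q99`, `significant`,
#'   `n_perm`, `degenerate`.
#' @examples
#' set.seed(1)
#' permutation_test(rnorm(20), sample(0:4, 20, TRUE), n_perm = 200, seed = 9)
#' @export
permutation_test <- function(metric, uls, n_perm = 1000L, seed = 1L,
                             alternative = c("two.sided", "less"),
                             q_level = 0.99, perms = NULL) {
  alternative <- match.arg(alternative)
  if (length(metric) != length(uls)) {
    abort("`metric` and `uls` must have equal length")
  }
  n <- length(metric)
  if (is.null(perms)) perms <- make_permutations(n, n_perm, seed)
  n_perm <- ncol(perms)
  rho <- spearman_rho(metric, uls)
  if (isTRUE(attr(rho, "degenerate"))) {
    return(tibble(rho = NA_real_, p_perm = NA_real_, null_q99 = NA_real_,
                  significant = FALSE, n_perm = as.integer(n_perm),
                  degenerate = TRUE))
  }
  rx <- rank(metric, ties.method = "average")
  ry <- rank(uls, ties.method = "average")
  null_rho <- as.vector(cor(rx, matrix(ry[perms], nrow = n)))
  if (alternative == "two.sided") {
    crit <- quantile(null_rho, q_level, names = FALSE)
    significant <- abs(rho) > crit
    p_perm <- (1 + sum(abs(null_rho) >= abs(rho))) / (n_perm + 1)
  } else {
    crit <- quantile(null_rho, 1 - q_level, names = FALSE)
    significant <- rho < crit
    p_perm <- (1 + sum(null_rho <= rho)) / (n_perm + 1)
  }
  tibble(rho = as.numeric(rho), p_perm = p_perm, null_q99 = crit,
         significant = significant, n_perm = as.integer(n_perm),
         degenerate = FALSE)
}

# run permutation_test for each node of a long metric table, sharing one
# permutation set
associate_nodes <- function(metric_tbl, value_col, truth, n_perm, seed,
                            alternative, q_level = 0.99) {
  ord <- match(truth$subject_id, unique(metric_tbl$subject_id))
  if (anyNA(ord)) abort("metric table and score table subjects disagree")
  perms <- make_permutations(nrow(truth), n_perm, seed)
  nodes <- sort(unique(metric_tbl$node))
  rows <- lapply(nodes, function(v) {
    sub <- metric_tbl[metric_tbl$node == v, ]
    sub <- sub[match(truth$subject_id, sub$subject_id), ]
    if (anyNA(sub$subject_id)) {
      abort(sprintf("node %d: missing subjects in metric table", v))
    }
    res <- permutation_test(sub[[value_col]], truth$uls, perms = perms,
                            alternative = alternative, q_level = q_level)
    res$node <- v
    res$node_label <- sub$node_label[1]
    res
  })
  out <- list_rbind(rows)
  out[, c("node", "node_label", "rho", "p_perm", "null_q99", "significant",
          "n_perm", "degenerate")]
}

#' Identify the dynamic central motor node (DCMN)
#'
#' Runs the permutation test of HCM occupancy against the impairment score
#' for every node (one shared permutation set) and names as DCMN the
#' significant node with the largest `|rho|` (ties broken by the smaller
#' node index). With no significant node the result is an explicit
#' "no DCMN" outcome (`dcmn = NA`).
#'
#' @param occupancy long occupancy tibble from [occupancy_table()].
#' @param truth tibble with `subject_id` and `uls`.
#' @inheritParams permutation_test
#' @return An object of class `dcmn_result`: list with `dcmn` (node index
#'   or `NA`), `dcmn_label`, `rho` (of the DCMN), and `table` (per-node
#'   association tibble).
#' @export
identify_dcmn <- function(occupancy, truth, n_perm = 1000L, seed = 1L,
                          alternative = c("two.sided", "less"),
                          q_level = 0.99) {
  alternative <- match.arg(alternative)
  if (length(unique(occupancy$node)) < 2L) abort("need at least 2 nodes")
  validate_uls(truth$uls)
  tab <- associate_nodes(occupancy, "hcm_windows", truth, n_perm, seed,
                         alternative, q_level)
  sig <- tab[tab$significant & !tab$degenerate, ]
  if (nrow(sig) == 0L) {
    res <- list(dcmn = NA_integer_, dcmn_label = NA_character_,
                rho = NA_real_, table = tab)
  } else {
    pick <- sig[order(-abs(sig$rho), sig$node), ][1, ]
    res <- list(dcmn = pick$node, dcmn_label = pick$node_label,
                rho = pick$rho, table = tab)
  }
  structure(res, class = "dcmn_result")
}

#' @export
print.dcmn_result <- function(x, ...) {
  if (is.na(x$dcmn)) {
    cat("<dcmn_result> no node reached permutation significance\n")
  } else {
    row <- x$table[x$table$node == x$dcmn, ]
    cat(sprintf("<dcmn_result> DCMN = node %d ('%s'): rho = %.4f, p_perm = %.4f\n",
                x$dcmn, x$dcmn_label, row$rho, row$p_perm))
  }
  cat(sprintf("  %d nodes tested, %d significant\n", nrow(x$table),
              sum(x$table$significant)))
  invisible(x)
}

#' DCMN-linked-mode occurrence counts
#'
#' For every node other than the DCMN, counts the sliding windows in which
#' that node shares an edge with the DCMN *while the DCMN is in its
#' high-centrality mode*. Each count is bounded above by the subject's HCM
#' window count for the DCMN.
#'
#' @param graphs a `binary_graphs` object or named list of them (one per
#'   subject, window counts matching the model's label sequences).
#' @param dcmn_model the DCMN's `mode_model`.
#' @param dcmn DCMN node index.
#' @return A long tibble: `subject_id`, `node`, `node_label`, `lm_windows`.
#' @export
linked_mode <- function(graphs, dcmn_model, dcmn) {
  if (inherits(graphs, "binary_graphs")) graphs <- list(graphs)
  stopifnot(inherits(dcmn_model, "mode_model"))
  dcmn <- check_count(dcmn, "dcmn")
  ids <- vapply(graphs, `[[`, character(1), "subject_id")
  rows <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    labels <- dcmn_model$labels[[ids[i]]]
    if (is.null(labels) || length(labels) != dim(g$adj)[1]) {
      abort(sprintf(
        "subject '%s': %d windows in graphs but %d mode labels", ids[i],
        dim(g$adj)[1], length(dcmn_model$labels[[ids[i]]]) %||% 0L))
    }
    hcm <- labels == dcmn_model$hcm_id
    n <- dim(g$adj)[2]
    edges <- matrix(g$adj[, , dcmn], ncol = n)  # W x N slice: edges to DCMN
    counts <- as.integer(colSums(edges[hcm, , drop = FALSE]))
    tibble(subject_id = ids[i], node = seq_len(n),
           node_label = g$node_labels, lm_windows = counts)
  })
  out <- list_rbind(rows)
  out[out$node != dcmn, ]
}

#' Association of DCMN-linked-mode counts with the impairment score
#'
#' [permutation_test()] applied per non-DCMN node with a shared permutation
#' set.
#'
#' @param lm_tbl long tibble from [linked_mode()].
#' @param truth tibble with `subject_id` and `uls`.
#' @inheritParams permutation_test
#' @return Per-node association tibble (DCMN excluded).
#' @export
linked_mode_association <- function(lm_tbl, truth, n_perm = 1000L, seed = 1L,
                                    alternative = c("two.sided", "less"),
                                    q_level = 0.99) {
  alternative <- match.arg(alternative)
  validate_uls(truth$uls)
  associate_nodes(lm_tbl, "lm_windows", truth, n_perm, seed, alternative,
                  q_level)
}

#' Partial Spearman correlation by rank residuals
#'
#' Ranks all three variables (average ties), regresses the metric ranks and
#' score ranks on the covariate ranks, and correlates the residuals. A
#' constant covariate reduces to the plain Spearman correlation (with a
#' message); a metric identical to the covariate leaves zero-variance
#' residuals and yields an explicit degenerate result.
#'
#' @param metric,uls,covariate per-subject numeric vectors (at least 6
#'   subjects).
#' @return A double with a logical `degenerate` attribute.
#' @export
partial_spearman <- function(metric, uls, covariate) {
  n <- length(metric)
  if (length(uls) != n || length(covariate) != n) {
    abort("all three vectors must have equal length")
  }
  if (n < 6L) abort("need at least 6 paired observations")
  rc <- rank(covariate, ties.method = "average")
  if (sd(rc) == 0) {
    inform("constant covariate: partial correlation reduces to plain Spearman")
    return(spearman_rho(metric, uls))
  }
  rx <- rank(metric, ties.method = "average")
  ry <- rank(uls, ties.method = "average")
  ex <- residuals(lm(rx ~ rc))
  ey <- residuals(lm(ry ~ rc))
  if (sd(ex) < 1e-10 || sd(ey) < 1e-10) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  structure(cor(ex, ey), degenerate = FALSE)
}
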
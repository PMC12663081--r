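# Sliding-window dynamic functional connectivity: windowed Pearson
# correlation matrices, Fisher z-transformed.

#' Sliding-window specification
#'
#' Windows are half-open volume index ranges `[s, s + length_tr)` in 0-based
#' indexing; the first window starts at volume 0 and onsets advance by
#' `step_tr`. The defaults (20-TR windows moved by 1 TR) give 241 windows
#' for a 260-volume series.
#'
#' @param length_tr window length in TRs (at least 3).
#' @param step_tr onset step in TRs, between 1 and `length_tr`.
#' @return A `window_spec` object.
#' @export
window_spec <- function(length_tr = 20, step_tr = 1) {
  length_tr <- check_count(length_tr, "length_tr", min = 3L)
  step_tr <- check_count(step_tr, "step_tr", min = 1L)
  if (step_tr > length_tr) abort("`step_tr` must not exceed `length_tr`")
  structure(list(length_tr = length_tr, step_tr = step_tr),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> length %d TR, step %d TR\n", x$length_tr, x$step_tr))
  invisible(x)
}

#' Number of sliding windows
#'
#' `floor((t - length_tr) / step_tr) + 1` fully contained windows.
#'
#' @param t number of volumes.
#' @param spec a [window_spec()].
#' @return Integer window count.
#' @examples
#' count_windows(260, window_spec(20, 1)) # 241
#' @export
count_windows <- function(t, spec = window_spec()) {
  t <- check_count(t, "t")
  stopifnot(inherits(spec, "window_spec"))
  if (t < spec$length_tr) {
    abort(sprintf("series too short: %d volumes with window length %d",
                  t, spec$length_tr))
  }
  as.integer((t - spec$length_tr) %/% spec$step_tr + 1L)
}

#' Windowed Fisher-z functional connectivity
#'
#' For every sliding window, computes the Pearson correlation between all
#' node pairs over the window's samples and applies the Fisher z-transform
#' `atanh(r)`. Perfect correlations are clipped to `|r| = 1 - r_clip_eps`
#' before the transform so all z values stay finite and totally ordered.
#' The diagonal is set to 0 and excluded from all downstream use.
#'
#' A node with zero variance inside a window makes the correlation
#' undefined; by default this aborts the subject with an error naming the
#' window and node, or with `on_degenerate = "drop"` the affected windows
#' are dropped with a warning.
#'
#' @param ts an [roi_timeseries()] object.
#' @param spec a [window_spec()].
#' @param r_clip_eps clipping margin for `|r| = 1`.
#' @param on_degenerate `"error"` (default) or `"drop"`.
#' @return An object of class `dynamic_fc`: list with `z` (W x N x N array),
#'   `window_starts` (0-based onset volumes), `subject_id`, `node_labels`,
#'   `tr_seconds`, `spec`.
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(200), 50, 4), tr_seconds = 2)
#' dfc <- windowed_fc(ts, window_spec(10, 5))
#' dim(dfc$z)
#' @export
windowed_fc <- function(ts, spec = window_spec(), r_clip_eps = 1e-7,
                        on_degenerate = c("error", "drop")) {
  stopifnot(inherits(ts, "roi_ts"))
  on_degenerate <- match.arg(on_degenerate)
  t_len <- nrow(ts$data)
  n <- ncol(ts$data)
  w_count <- count_windows(t_len, spec)
  starts <- (seq_len(w_count) - 1L) * spec$step_tr  # 0-based onsets
  z <- array(NA_real_, dim = c(w_count, n, n))
  bad <- logical(w_count)
  for (w in seq_len(w_count)) {
    rows <- (starts[w] + 1L):(starts[w] + spec$length_tr)
    x <- ts$data[rows, , drop = FALSE]
    degenerate <- which(matrixStats_colSds(x) == 0)
    if (length(degenerate)) {
      msg <- sprintf(
        "zero within-window variance for subject '%s', window %d (volumes %d-%d), node '%s'",
        ts$subject_id, w, starts[w], starts[w] + spec$length_tr - 1L,
        ts$node_labels[degenerate[1]])
      if (on_degenerate == "error") abort(msg) else {
        warn(paste0(msg, "; window dropped"))
        bad[w] <- TRUE
        next
      }
    }
    r <- cor(x)
    r <- pmin(pmax(r, -(1 - r_clip_eps)), 1 - r_clip_eps)
    zw <- atanh(r)
    diag(zw) <- 0
    z[w, , ] <- zw
  }
  if (any(bad)) {
    z <- z[!bad, , , drop = FALSE]
    starts <- starts[!bad]
  }
  structure(
    list(z = z, window_starts = starts, subject_id = ts$subject_id,
         node_labels = ts$node_labels, tr_seconds = ts$tr_seconds,
         spec = spec),
    class = "dynamic_fc"
  )
}

# column standard deviations without the matrixStats dependency
matrixStats_colSds <- function(x) {
  apply(x, 2, sd)
}

#' @export
print.dynamic_fc <- function(x, ...) {
  cat(sprintf("<dynamic_fc> subject %s: %d windows x %d nodes (length %d TR, step %d TR)\n",
              x$subject_id, dim(x$z)[1], dim(x$z)[2],
              x$spec$length_tr, x$spec$step_tr))
  invisible(x)
}

# fixed upper-triangle column order used by the flattened writer
upper_pair_labels <- function(labels) {
  n <- length(labels)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  list(idx = idx, names = paste(labels[idx[, 1]], labels[idx[, 2]], sep = "|"))
}

#' Write a flattened dynamic-connectivity table
#'
#' One row per window, one column per unordered node pair (upper triangle in
#' row-major order, columns named `nodeA|nodeB`), values Fisher-z.
#'
#' @param dfc a `dynamic_fc` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dfc <- function(dfc, path) {
  stopifnot(inherits(dfc, "dynamic_fc"))
  up <- upper_pair_labels(dfc$node_labels)
  w_count <- dim(dfc$z)[1]
  flat <- t(vapply(seq_len(w_count),
                   function(w) dfc$z[w, , ][up$idx], numeric(nrow(up$idx))))
  colnames(flat) <- up$names
  out <- as.data.frame(flat)
  out <- cbind(window_start = dfc$window_starts, out)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
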
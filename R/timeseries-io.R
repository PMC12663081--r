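# Reading, writing and filtering of per-subject ROI time series and cohort
# manifests. One subject = one delimited text file, T rows (volumes) by N
# columns (nodes), with a header row of unique node labels.

#' Construct an ROI time-series object
#'
#' Bundles one subject's T x N matrix of BOLD-like signals with its sampling
#' interval and node labels, validating shape and completeness.
#'
#' @param data numeric matrix, T volumes by N nodes. Column names, when
#'   present, become the node labels.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param subject_id subject identifier.
#' @param node_labels character vector of N unique node labels; defaults to
#'   the column names of `data` or `n01`, `n02`, ....
#' @return An object of class `roi_ts` with fields `data`, `tr_seconds`,
#'   `subject_id`, `node_labels`.
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(40), 10, 4), tr_seconds = 1.714)
#' dim(ts$data)
#' @export
roi_timeseries <- function(data, tr_seconds, subject_id = "subject",
                           node_labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) abort("`data` must be a numeric matrix")
  if (nrow(data) < 2L || ncol(data) < 2L) {
    abort("`data` must have at least 2 rows (volumes) and 2 columns (nodes)")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    abort("`data` contains missing or non-finite values")
  }
  tr_seconds <- check_positive(tr_seconds, "tr_seconds")
  node_labels <- node_labels %||% colnames(data) %||%
    default_node_labels(ncol(data))
  if (length(node_labels) != ncol(data)) {
    abort("`node_labels` length must equal the number of columns")
  }
  if (anyDuplicated(node_labels)) abort("`node_labels` must be unique")
  colnames(data) <- node_labels
  structure(
    list(data = data, tr_seconds = tr_seconds,
         subject_id = as.character(subject_id),
         node_labels = as.character(node_labels)),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject %s: %d volumes x %d nodes, TR = %gs\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

#' @rdname roi_timeseries
#' @param x an `roi_ts` object.
#' @param ... unused.
#' @export
as_tibble.roi_ts <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$data))
  out$volume <- seq_len(nrow(out))
  out$subject_id <- x$subject_id
  tidyr::pivot_longer(out, cols = -c("volume", "subject_id"),
                      names_to = "node", values_to = "signal")
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort(sprintf("'%s' is empty", path))
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

#' Read an ROI time-series file
#'
#' Reads a delimited text file (comma- or tab-separated, auto-detected) with
#' one header row of node labels and T numeric rows in acquisition order.
#' Ragged rows, non-numeric or missing cells and duplicated labels are
#' format errors that name the offending line.
#'
#' @param path path to the file.
#' @param tr_seconds sampling interval in seconds.
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @return An [roi_timeseries()] object.
#' @export
read_timeseries <- function(path, tr_seconds, subject_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  delim <- detect_delim(path)
  raw <- suppressWarnings(readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_double()),
    show_col_types = FALSE, progress = FALSE, name_repair = "minimal"
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort(sprintf(
      "format error in '%s' at line %d, column %d: expected %s, got %s",
      path, p$row, p$col, p$expected, p$actual
    ))
  }
  labs <- names(raw)
  if (anyDuplicated(labs)) {
    abort(sprintf("duplicate node labels in '%s' header: %s", path,
                  paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  }
  mat <- as.matrix(raw)
  if (anyNA(mat) || any(!is.finite(mat))) {
    bad <- which(!is.finite(mat) | is.na(mat), arr.ind = TRUE)[1, ]
    abort(sprintf("format error in '%s' at line %d, column %d: %s",
                  path, bad[1] + 1L, bad[2], "missing or non-numeric cell"))
  }
  subject_id <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
  roi_timeseries(mat, tr_seconds, subject_id = subject_id, node_labels = labs)
}

#' Write an ROI time-series file
#'
#' Inverse of [read_timeseries()]: one header row of node labels, then T
#' comma-separated numeric rows. Values round-trip at full double precision.
#'
#' @param ts an `roi_ts` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  readr::write_csv(as.data.frame(ts$data), path, progress = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `subject_id`, `path`, `uls` (ordinal
#' upper-limb impairment score, integers 0-4) and optionally further numeric
#' covariate columns (e.g. lesion size) used by partial correlations.
#' Relative `path` entries are resolved against the manifest's directory.
#'
#' @param path path to the manifest CSV.
#' @return A tibble with one row per subject.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "path", "uls")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    abort(sprintf("manifest '%s' lacks column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(m$subject_id)) abort("manifest subject_id values must be unique")
  validate_uls(m$uls)
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

validate_uls <- function(uls) {
  if (anyNA(uls) || !all(uls %in% 0:4)) {
    abort("`uls` values must be integers in {0, 1, 2, 3, 4}")
  }
  invisible(as.integer(uls))
}

#' Zero-phase band-pass filter for ROI time series
#'
#' Applies a 4th-order Butterworth band-pass forward and backward (zero net
#' phase shift) to every node's signal, after odd-reflection padding at both
#' ends to suppress filter transients. The default band, 0.029-0.15 Hz, is
#' the conventional band for sliding-window functional-connectivity analysis
#' of BOLD data.
#'
#' @param ts an `roi_ts` object.
#' @param low_hz,high_hz passband edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 * tr_seconds)`.
#' @param order Butterworth filter order (per pass).
#' @return A filtered `roi_ts` of the same shape.
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(2000), 500, 4), tr_seconds = 1.714)
#' filt <- bandpass(ts)
#' @export
bandpass <- function(ts, low_hz = 0.029, high_hz = 0.15, order = 4) {
  stopifnot(inherits(ts, "roi_ts"))
  nyquist <- 1 / (2 * ts$tr_seconds)
  low_hz <- check_positive(low_hz, "low_hz")
  high_hz <- check_positive(high_hz, "high_hz")
  if (low_hz >= high_hz) abort("`low_hz` must be smaller than `high_hz`")
  if (high_hz >= nyquist) {
    abort(sprintf("`high_hz` (%g) must be below the Nyquist frequency (%g Hz)",
                  high_hz, nyquist))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  n <- nrow(ts$data)
  # filter transients settle over a few periods of the low band edge;
  # demeaning plus odd-reflection padding of that length keeps them out of
  # the returned samples
  pad <- min(n - 1L, max(3L * order,
                         ceiling(3 / (low_hz * ts$tr_seconds))))
  out <- apply(ts$data, 2, function(x) {
    x <- x - mean(x)
    xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
            2 * x[n] - rev(x[(n - pad):(n - 1)]))
    y <- signal::filtfilt(bf, xp)
    y[pad + seq_len(n)]
  })
  roi_timeseries(out, ts$tr_seconds, subject_id = ts$subject_id,
                 node_labels = ts$node_labels)
}
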
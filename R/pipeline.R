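# End-to-end orchestration: (optional band-pass) -> windowed Fisher-z
# connectivity -> proportional threshold -> rank-BC traces -> centrality
# modes -> HCM occupancy -> DCMN identification -> linked-mode association.

#' Run the dynamic-centrality pipeline
#'
#' Takes a cohort (a manifest pointing at per-subject time-series files, a
#' `synthetic_cohort`, or a manifest plus pre-loaded series) and runs every
#' stage with the given parameters. Defaults correspond to the reference
#' analysis settings: 20-TR windows stepped by 1 TR, 20% proportional
#' threshold, candidate k 2-6, 1000 permutations against the 99th
#' percentile of the null.
#'
#' @param cohort one of: a manifest tibble (columns `subject_id`, `path`,
#'   `uls`, covariates...), a path to a manifest CSV, or a
#'   `synthetic_cohort`.
#' @param timeseries optional named list of `roi_ts` objects keyed by
#'   subject id, overriding file reads.
#' @param tr_seconds repetition time used when reading files.
#' @param window a [window_spec()].
#' @param density proportional-threshold edge fraction.
#' @param threshold_mode `"signed"` or `"absolute"` weight ordering.
#' @param k_grid candidate cluster counts for the mode fit.
#' @param n_perm number of permutations.
#' @param seed integer seed governing k-means restarts and permutations.
#' @param alternative sidedness of the permutation rule (`"two.sided"` or
#'   `"less"`).
#' @param filter_band optional numeric pair `(low_hz, high_hz)`; when given,
#'   each series is band-pass filtered before windowing (off by default:
#'   inputs are normally already filtered upstream).
#' @param out_dir optional directory; when given, all result tables and a
#'   JSON run-metadata file are written there (deterministic content).
#' @param keep_graphs keep the per-subject binary graph arrays in the
#'   result (needed for linked-mode counting; disable to save memory when
#'   only occupancy associations are wanted).
#' @return An object of class `dynhub_result`: list with `occupancy`
#'   (long tibble), `modes` (`mode_models`), `mode_summary` (tibble),
#'   `association` (`dcmn_result`), `linked_mode` (tibble or `NULL`),
#'   `linked_association` (tibble or `NULL`), `truth` (manifest-derived
#'   subject table), `config` (list) and `log` (character vector of
#'   collected condition messages).
#' @export
run_pipeline <- function(cohort, timeseries = NULL, tr_seconds = 1.714,
                         window = window_spec(), density = 0.2,
                         threshold_mode = c("signed", "absolute"),
                         k_grid = 2:6, n_perm = 1000L, seed = 1L,
                         alternative = c("two.sided", "less"),
                         filter_band = NULL, out_dir = NULL,
                         keep_graphs = TRUE) {
  threshold_mode <- match.arg(threshold_mode)
  alternative <- match.arg(alternative)

  if (inherits(cohort, "synthetic_cohort")) {
    truth <- cohort$truth
    timeseries <- cohort$timeseries
    tr_seconds <- cohort$spec$tr_seconds
  } else {
    if (is.character(cohort) && length(cohort) == 1L) {
      cohort <- read_manifest(cohort)
    }
    if (!is.data.frame(cohort)) {
      abort("`cohort` must be a manifest, a manifest path, or a synthetic_cohort")
    }
    truth <- as_tibble(cohort)
    validate_uls(truth$uls)
    if (is.null(timeseries)) {
      timeseries <- lapply(seq_len(nrow(truth)), function(i) {
        read_timeseries(truth$path[i], tr_seconds,
                        subject_id = truth$subject_id[i])
      })
      names(timeseries) <- truth$subject_id
    }
  }
  if (anyDuplicated(truth$subject_id)) abort("duplicate subject ids")
  timeseries <- timeseries[truth$subject_id]
  if (any(vapply(timeseries, is.null, logical(1)))) {
    abort("`timeseries` is missing some manifest subjects")
  }

  log_lines <- character()
  note <- function(msg) log_lines <<- c(log_lines, msg)
  collect <- function(expr) {
    withCallingHandlers(
      expr,
      message = function(m) {
        note(trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      },
      warning = function(w) {
        note(paste("warning:", trimws(conditionMessage(w))))
        invokeRestart("muffleWarning")
      }
    )
  }

  if (!is.null(filter_band)) {
    stopifnot(length(filter_band) == 2L)
    timeseries <- collect(lapply(timeseries, bandpass,
                                 low_hz = filter_band[1],
                                 high_hz = filter_band[2]))
  }

  graphs <- collect(lapply(timeseries, function(ts) {
    binarize_windows(windowed_fc(ts, window), density, threshold_mode)
  }))
  traces <- collect(lapply(graphs, centrality_trace))
  note(sprintf("%d subjects, %d windows each, %d edges per window",
               length(traces), nrow(traces[[1]]$rank),
               sum(graphs[[1]]$adj[1, , ]) / 2))

  models <- collect(fit_modes_cohort(traces, k_grid = k_grid,
                                     seed = derive_seed(seed, 1L)))
  occupancy <- occupancy_table(models)
  association <- identify_dcmn(occupancy, truth, n_perm = n_perm,
                               seed = derive_seed(seed, 2L),
                               alternative = alternative)

  linked <- NULL
  linked_assoc <- NULL
  if (!is.na(association$dcmn)) {
    linked <- linked_mode(graphs, models[[association$dcmn]],
                          association$dcmn)
    linked_assoc <- linked_mode_association(linked, truth, n_perm = n_perm,
                                            seed = derive_seed(seed, 2L),
                                            alternative = alternative)
  } else {
    note("no DCMN identified; linked-mode stage skipped")
  }

  config <- list(
    tr_seconds = tr_seconds, window_length_tr = window$length_tr,
    window_step_tr = window$step_tr, density = density,
    threshold_mode = threshold_mode, k_grid = as.integer(k_grid),
    n_perm = as.integer(n_perm), seed = as.integer(seed),
    alternative = alternative,
    filter_band = if (is.null(filter_band)) NULL else as.numeric(filter_band)
  )

  result <- structure(
    list(occupancy = occupancy, modes = models,
         mode_summary = mode_summary(models), association = association,
         linked_mode = linked, linked_association = linked_assoc,
         truth = truth, graphs = if (keep_graphs) graphs else NULL,
         config = config, log = log_lines),
    class = "dynhub_result"
  )
  if (!is.null(out_dir)) write_results(result, out_dir)
  result
}

mode_summary <- function(models) {
  list_rbind(lapply(models, function(m) {
    tibble(node = m$node, node_label = m$node_label, k = m$k,
           hcm_centroid = m$centroids[m$hcm_id],
           centroids = paste(sprintf("%.3f", m$centroids), collapse = ";"),
           best_mpfc = suppressWarnings(max(m$mpfc_by_k, na.rm = TRUE)),
           mpfc_by_k = paste(sprintf("%s=%.3f", names(m$mpfc_by_k),
                                     m$mpfc_by_k), collapse = ";"))
  }))
}

#' @export
print.dynhub_result <- function(x, ...) {
  cat(sprintf("<dynhub_result> %d subjects x %d nodes\n",
              nrow(x$truth), nrow(x$mode_summary)))
  cat(sprintf("  mode counts k: %s | mean HCM centroid rank %.2f\n",
              paste(sort(unique(x$mode_summary$k)), collapse = "/"),
              mean(x$mode_summary$hcm_centroid)))
  print(x$association)
  if (!is.null(x$linked_association)) {
    sig <- x$linked_association[x$linked_association$significant, ]
    cat(sprintf("  linked-mode: %d of %d non-DCMN nodes significant\n",
                nrow(sig), nrow(x$linked_association)))
  }
  invisible(x)
}

#' Write pipeline result tables
#'
#' Writes `occupancy.csv` (subject x node HCM counts), `mode_summary.csv`,
#' `association.csv`, `linked_mode_association.csv` (when available) and
#' `run_metadata.json` (configuration, seed, package version, stage
#' counts). Output is deterministic: identical configuration and seed give
#' byte-identical files.
#'
#' @param result a `dynhub_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "dynhub_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  occ <- as.data.frame(occupancy_matrix(result$occupancy))
  occ <- cbind(subject_id = rownames(occ), occ)
  readr::write_csv(occ, file.path(dir, "occupancy.csv"), progress = FALSE)
  readr::write_csv(result$mode_summary, file.path(dir, "mode_summary.csv"),
                   progress = FALSE)
  readr::write_csv(result$association$table, file.path(dir, "association.csv"),
                   progress = FALSE)
  if (!is.null(result$linked_association)) {
    readr::write_csv(result$linked_association,
                     file.path(dir, "linked_mode_association.csv"),
                     progress = FALSE)
  }
  meta <- list(
    package = "dynhub",
    version = as.character(utils::packageVersion("dynhub")),
    config = result$config,
    n_subjects = nrow(result$truth),
    n_nodes = nrow(result$mode_summary),
    dcmn = if (is.na(result$association$dcmn)) NULL else result$association$dcmn,
    log = result$log
  )
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
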
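# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @rdname fit_modes
#' @param x a `mode_model`.
#' @param ... unused.
#' @export
tidy.mode_model <- function(x, ...) {
  tibble(
    node = x$node, node_label = x$node_label,
    mode = seq_len(x$k), centroid = x$centroids,
    size = x$sizes, hcm = seq_len(x$k) == x$hcm_id
  )
}

#' @rdname fit_modes
#' @export
glance.mode_model <- function(x, ...) {
  tibble(
    node = x$node, node_label = x$node_label, k = x$k,
    hcm_centroid = x$centroids[x$hcm_id],
    best_mpfc = suppressWarnings(max(x$mpfc_by_k, na.rm = TRUE))
  )
}

#' @rdname fit_modes_cohort
#' @param x a `mode_models` list.
#' @param ... unused.
#' @export
tidy.mode_models <- function(x, ...) list_rbind(lapply(x, tidy))

#' @rdname fit_modes_cohort
#' @export
glance.mode_models <- function(x, ...) list_rbind(lapply(x, glance))

#' @rdname identify_dcmn
#' @param x a `dcmn_result`.
#' @param ... unused.
#' @export
tidy.dcmn_result <- function(x, ...) x$table

#' @rdname identify_dcmn
#' @export
glance.dcmn_result <- function(x, ...) {
  tibble(
    dcmn = x$dcmn, dcmn_label = x$dcmn_label, rho = x$rho,
    n_significant = sum(x$table$significant),
    n_nodes = nrow(x$table)
  )
}

#' @rdname run_pipeline
#' @param x a `dynhub_result`.
#' @param ... unused.
#' @export
tidy.dynhub_result <- function(x, ...) x$association$table

#' @rdname run_pipeline
#' @export
glance.dynhub_result <- function(x, ...) {
  g <- glance(x$association)
  g$mean_hcm_centroid <- mean(x$mode_summary$hcm_centroid)
  g$n_subjects <- nrow(x$truth)
  g
}

#' @rdname identify_dcmn
#' @param object a `dcmn_result`.
#' @export
autoplot.dcmn_result <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = stats::reorder(.data$node_label, .data$node),
                                    y = .data$rho,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$null_q99),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = -.data$null_q99),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#c0392b")) +
    ggplot2::labs(x = NULL, y = "Spearman rho (metric vs ULS)",
                  fill = "significant",
                  title = "Per-node association with impairment",
                  subtitle = "dashed: +/- 99th percentile of the permutation null") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname fit_modes
#' @param object a `mode_model`.
#' @export
autoplot.mode_model <- function(object, ...) {
  values <- unlist(object$labels, use.names = FALSE)
  dat <- tibble(mode = factor(values))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mode, fill = .data$mode)) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = "centrality mode (1 = high centrality)", y = "windows",
      title = sprintf("Node %s: %d centrality modes", object$node_label,
                      object$k),
      subtitle = sprintf("centroid ranks: %s",
                         paste(sprintf("%.1f", object$centroids),
                               collapse = ", "))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::guides(fill = "none")
}

#' Occupancy-versus-impairment scatter plot
#'
#' Scatter of a node's HCM window counts against the impairment score, with
#' the Spearman correlation in the title. The DCMN's version of this plot
#' is the pipeline's headline figure.
#'
#' @param result a `dynhub_result`.
#' @param node node index; defaults to the DCMN.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(result, node = NULL) {
  stopifnot(inherits(result, "dynhub_result"))
  node <- node %||% result$association$dcmn
  if (is.na(node)) abort("no DCMN identified; supply `node` explicitly")
  occ <- result$occupancy[result$occupancy$node == node, ]
  dat <- dplyr::left_join(occ, result$truth[, c("subject_id", "uls")],
                          by = "subject_id")
  rho <- spearman_rho(dat$hcm_windows, dat$uls)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$uls, y = .data$hcm_windows)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2.5,
                         colour = "#2c3e50", alpha = 0.85) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#c0392b", linewidth = 0.6) +
    ggplot2::labs(
      x = "upper-limb score (0 = none, 4 = severe)",
      y = "windows in high-centrality mode",
      title = sprintf("Node %s: HCM occupancy vs impairment",
                      dat$node_label[1]),
      subtitle = sprintf("Spearman rho = %.3f", as.numeric(rho))
    ) +
    ggplot2::theme_minimal()
}

#' Rank-trace plot for one subject and node
#'
#' Time course of a node's within-window centrality rank (1 = most
#' central), optionally annotated with the fitted mode labels.
#'
#' @param trace a `centrality_trace`.
#' @param node node index.
#' @param model optional `mode_model` for that node; adds mode colouring
#'   and the HCM centroid line.
#' @return A ggplot object.
#' @export
plot_rank_trace <- function(trace, node, model = NULL) {
  stopifnot(inherits(trace, "centrality_trace"))
  dat <- tibble(
    window = seq_len(nrow(trace$rank)),
    rank = trace$rank[, node]
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$window, y = .data$rank))
  if (!is.null(model)) {
    labels <- model$labels[[trace$subject_id]]
    if (!is.null(labels)) {
      dat$mode <- factor(labels)
      p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$window, y = .data$rank,
                                             colour = .data$mode)) +
        ggplot2::geom_hline(yintercept = model$centroids[model$hcm_id],
                            linetype = "dotted")
    }
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "sliding window",
                  y = "centrality rank (1 = most central)",
                  title = sprintf("Subject %s, node %s", trace$subject_id,
                                  trace$node_labels[node])) +
    ggplot2::theme_minimal()
}
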
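# ggplot2 views of the analysis results. Each plot_* takes the tidy tibble
# (or the report object) and returns a ggplot.

#' Plot RMSD series
#'
#' @param data A tibble with `frame`, `rmsd` and optionally `series`
#'   columns, or a `bda_comparison`.
#' @return A ggplot.
#' @export
plot_rmsd <- function(data) {
  if (inherits(data, "bda_comparison")) data <- data$rmsd
  if (!("series" %in% names(data))) data$series <- "trajectory"
  ggplot2::ggplot(data, ggplot2::aes(x = .data$frame, y = .data$rmsd,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frame", y = "RMSD (\u00c5)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-residue RMSF
#'
#' @param data A tibble from [rmsf()] (columns `resnum`, `rmsf`, optional
#'   `chain`) or the `rmsf` table of a `bda_comparison` (plotted as wt vs
#'   mutant).
#' @return A ggplot.
#' @export
plot_rmsf <- function(data) {
  if (inherits(data, "bda_comparison")) data <- data$rmsf
  if (all(c("rmsf_wt", "rmsf_mut") %in% names(data))) {
    long <- tidyr::pivot_longer(data, c("rmsf_wt", "rmsf_mut"),
                                names_to = "series", values_to = "rmsf",
                                names_prefix = "rmsf_")
  } else {
    long <- data
    long$series <- "trajectory"
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$resnum, y = .data$rmsf,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chain)) +
    ggplot2::labs(x = "Residue", y = "RMSF (\u00c5)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cluster populations
#'
#' @param x A `bda_cluster` or the `clusters` table of a `bda_comparison`.
#' @return A ggplot.
#' @export
plot_cluster_populations <- function(x) {
  data <- if (inherits(x, "bda_cluster")) x$populations
  else if (inherits(x, "bda_comparison")) x$clusters
  else x
  if (!("series" %in% names(data))) data$series <- "trajectory"
  ggplot2::ggplot(data, ggplot2::aes(x = factor(.data$cluster),
                                     y = .data$population,
                                     fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Cluster", y = "Population", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot pose evaluations in the distance-angle plane
#'
#' Accepted poses sit in the low-distance, low-angle corner; the
#' threshold box is drawn.
#'
#' @param x A `bda_pose_eval`.
#' @return A ggplot.
#' @export
plot_pose_filter <- function(x) {
  data <- x$evaluations[x$evaluations$inside_cavity, ]
  ggplot2::ggplot(data, ggplot2::aes(x = .data$distance, y = .data$angle,
                                     colour = .data$verdict)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$thresholds$d_max,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = x$thresholds$theta_max,
                        linetype = "dashed") +
    ggplot2::labs(x = "Reference-carbon distance (\u00c5)",
                  y = "Directionality angle (\u00b0)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_rmsd
#' @param object A `bda_comparison`.
#' @param ... Unused.
#' @export
autoplot.bda_comparison <- function(object, ...) plot_rmsd(object)

#' @rdname plot_cluster_populations
#' @param object A `bda_cluster`.
#' @param ... Unused.
#' @export
autoplot.bda_cluster <- function(object, ...) plot_cluster_populations(object)

#' @rdname plot_pose_filter
#' @param object A `bda_pose_eval`.
#' @param ... Unused.
#' @export
autoplot.bda_pose_eval <- function(object, ...) plot_pose_filter(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
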
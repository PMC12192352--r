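#' Raster plot of an event train
#'
#' One row per cell, one point per deconvolved event; point size can encode
#' amplitude.
#'
#' @param events events tibble.
#' @param size_by_amplitude scale point size by event amplitude.
#' @return A ggplot object.
#' @export
plot_event_raster <- function(events, size_by_amplitude = FALSE) {
  p <- ggplot2::ggplot(events, ggplot2::aes(x = .data$time_s, y = .data$cell_id))
  p <- if (size_by_amplitude) {
    p + ggplot2::geom_point(ggplot2::aes(size = .data$amplitude),
                            shape = "|", show.legend = FALSE)
  } else {
    p + ggplot2::geom_point(shape = "|")
  }
  p + ggplot2::labs(x = "time (s)", y = NULL)
}

#' Heat map of trial-averaged peri-event Z-scores
#'
#' Cells (rows) by time relative to the alignment event, averaged across
#' trials, optionally per condition.
#'
#' @param object a `ca_epochs` from [extract_epochs()].
#' @param facet_by_direction facet the heat map by target direction.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ca_epochs <- function(object, facet_by_direction = FALSE, ...) {
  grp <- if (facet_by_direction) {
    dplyr::group_by(object, .data$cell_id, .data$direction, .data$time_rel_s)
  } else {
    dplyr::group_by(object, .data$cell_id, .data$time_rel_s)
  }
  avg <- dplyr::summarise(grp, z = mean(.data$z), .groups = "drop")
  p <- ggplot2::ggplot(avg, ggplot2::aes(x = .data$time_rel_s, y = .data$cell_id,
                                         fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from event (s)", y = NULL, fill = "Z")
  if (facet_by_direction) p <- p + ggplot2::facet_wrap(~direction)
  p
}

#' Histogram of pairwise Z-Jaccard values
#'
#' Valid pairs only; dashed lines mark the +/-1.96 synchrony threshold.
#'
#' @param object a `ca_pairsync` from [z_jaccard()].
#' @param threshold threshold drawn on the plot.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ca_pairsync <- function(object, threshold = 1.96, ...) {
  v <- dplyr::filter(object, .data$valid)
  ggplot2::ggplot(v, ggplot2::aes(x = .data$z_jaccard)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold), linetype = 2) +
    ggplot2::labs(x = "Z-Jaccard", y = "cell pairs")
}

#' Z-Jaccard versus centroid distance with its loess smoother
#'
#' @param object a `ca_distsync` from [distance_vs_synchrony()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ca_distsync <- function(object, ...) {
  p <- ggplot2::ggplot(object$pairs,
                       ggplot2::aes(x = .data$distance, y = .data$z_jaccard)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "centroid distance", y = "Z-Jaccard")
  if (!is.null(object$curve)) {
    p <- p + ggplot2::geom_line(data = object$curve,
                                ggplot2::aes(x = .data$distance, y = .data$z_fit),
                                color = "blue", linewidth = 1)
  }
  p
}

#' Observed sequence counts against their permutation null
#'
#' One bar per candidate motif (observed count) with the null 95th-percentile
#' marked; significant motifs are highlighted.
#'
#' @param object a `ca_sequences` from [detect_sequences()].
#' @param max_motifs show at most this many motifs (highest counts first).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ca_sequences <- function(object, max_motifs = 30, ...) {
  m <- tidy_sequences(object) |>
    dplyr::arrange(dplyr::desc(.data$count)) |>
    head(max_motifs)
  m$motif_id <- factor(m$motif_id, levels = rev(m$motif_id))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$count, y = .data$motif_id,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(ggplot2::aes(x = .data$null_q), shape = 124, size = 4,
                        color = "black", show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "occurrences (bar) / null 95th percentile (tick)",
                  y = NULL, fill = "significant")
}
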
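#' Heat map of the ΔAICc landscape
#'
#' Lower-triangular raster of ΔAICc over (window end, window start); a
#' point at start 100 and end 50 is the window covering 50-100 days before
#' the (adjusted) measurement date. The best window is circled. Multiple
#' separated minima indicate multiple candidate climate signals.
#'
#' @param modelset a `window_modelset` (or its serialized dataset).
#' @return a ggplot object.
#' @export
plot_delta <- function(modelset) {
  ds <- modelset_dataset(modelset)
  if (nrow(ds) == 0L) stop("empty model set", call. = FALSE)
  best <- ds[which.min(ds$delta_aicc), ]
  ggplot2::ggplot(ds, ggplot2::aes(x = .data$window_end,
                                   y = .data$window_start,
                                   fill = .data$delta_aicc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = c("red", "yellow", "blue"),
                                  name = expression(Delta * "AICc")) +
    ggplot2::geom_point(data = best, shape = 21, size = 3,
                        fill = NA, colour = "black", stroke = 1) +
    ggplot2::labs(x = "Window end (days before reference)",
                  y = "Window start (days before reference)",
                  title = "Delta AICc landscape") +
    ggplot2::theme_minimal()
}

#' Heat map of confidence-set membership
#'
#' Shades each candidate window by the smallest confidence set (by
#' cumulative Akaike weight) it belongs to; the C statistic of the outer
#' level is shown in the subtitle. Compact shading indicates a
#' concentrated, credible signal; diffuse shading is the signal-free
#' pattern.
#'
#' @param modelset a `window_modelset` (or its serialized dataset).
#' @param levels decreasing confidence levels to shade.
#' @return a ggplot object.
#' @export
plot_weights <- function(modelset, levels = c(0.95, 0.5, 0.25)) {
  ds <- modelset_dataset(modelset)
  if (nrow(ds) == 0L) stop("empty model set", call. = FALSE)
  levels <- sort(levels, decreasing = TRUE)
  ds$set <- NA_character_
  for (lv in levels) {
    idx <- rownames(confidence_set(ds, lv))
    ds[idx, "set"] <- paste0(100 * lv, "%")
  }
  ds$set <- factor(ds$set, levels = paste0(100 * levels, "%"))
  cstat <- c_statistic(ds, levels[1L])
  ggplot2::ggplot(ds, ggplot2::aes(x = .data$window_end,
                                   y = .data$window_start,
                                   fill = .data$set)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_brewer(palette = "Blues", direction = -1,
                               na.value = "grey95",
                               name = "Confidence set") +
    ggplot2::labs(x = "Window end (days before reference)",
                  y = "Window start (days before reference)",
                  title = "Akaike-weight confidence sets",
                  subtitle = sprintf("C = %.1f%% of windows in the %g%% set",
                                     cstat, 100 * levels[1L])) +
    ggplot2::theme_minimal()
}
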
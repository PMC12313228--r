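#' Bar chart of per-experiment invasion metrics
#'
#' Mean with SEM error bars, per experiment, for either the invasion
#' index or SPOI of an experiment summary.
#'
#' @param experiment_summary Result of [aggregate_experiment()].
#' @param metric `"invasion_index"` or `"spoi"`.
#' @return A ggplot.
#' @export
plot_experiment_summary <- function(experiment_summary,
                                    metric = c("invasion_index", "spoi")) {
  metric <- match.arg(metric)
  m <- paste0(metric, "_mean"); s <- paste0(metric, "_sem")
  ggplot(experiment_summary,
         aes(x = .data$experiment_id, y = .data[[m]])) +
    geom_col(fill = "grey40") +
    geom_errorbar(aes(ymin = .data[[m]] - .data[[s]],
                      ymax = .data[[m]] + .data[[s]]), width = 0.3) +
    labs(x = NULL, y = gsub("_", " ", metric)) +
    theme_minimal()
}

#' Display an organ image channel with island outlines
#'
#' Raster view of one channel; if a measured island table is given, the
#' island centroids are marked and annotated with their nucleus counts.
#'
#' @param image An `organ_image`.
#' @param channel Channel to display.
#' @param island_table Optional result of [measure_islands()].
#' @return A ggplot.
#' @export
plot_organ_image <- function(image, channel = "cytokeratin",
                             island_table = NULL) {
  ch <- image$channels[[channel]]
  if (is.null(ch)) abort(paste0("Channel '", channel, "' not found."))
  df <- tibble(
    row = rep(seq_len(nrow(ch)), times = ncol(ch)),
    col = rep(seq_len(ncol(ch)), each = nrow(ch)),
    intensity = as.vector(ch)
  )
  p <- ggplot(df, aes(x = .data$col, y = .data$row,
                      fill = .data$intensity)) +
    geom_raster() +
    scale_y_reverse() +
    scale_fill_gradient(low = "black", high = "white") +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = channel) +
    theme_void()
  if (!is.null(island_table)) {
    isl <- island_table |> filter(!.data$is_sheet)
    p <- p +
      geom_point(data = isl,
                 aes(x = .data$centroid_col, y = .data$centroid_row),
                 colour = "red", inherit.aes = FALSE) +
      geom_text(data = isl,
                aes(x = .data$centroid_col, y = .data$centroid_row,
                    label = .data$nuclei_count),
                colour = "red", vjust = -1, inherit.aes = FALSE)
  }
  p
}
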
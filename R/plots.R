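# ggplot2 displays: adjacency heatmaps, ERD time-frequency maps, degree
# topographies, and edge-count comparisons.

#' Plot a connectivity matrix as a heatmap
#'
#' @param object A `conn_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conn_matrix <- function(object, ...) {
  labels <- rownames(object)
  df <- expand.grid(chan_i = labels, chan_j = labels,
                    stringsAsFactors = FALSE)
  df$weight <- as.vector(unclass(object))
  df$chan_i <- factor(df$chan_i, levels = labels)
  df$chan_j <- factor(df$chan_j, levels = rev(labels))
  ggplot(df, aes(x = .data$chan_i, y = .data$chan_j, fill = .data$weight)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(
      x = NULL, y = NULL, fill = attr(object, "method"),
      title = sprintf("%s network (%s, %s hand, %s reference)",
                      attr(object, "method"), attr(object, "stage"),
                      attr(object, "hand"), attr(object, "reference"))
    ) +
    theme_minimal(base_size = 8) +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}

#' Plot an ERD/ERS time-frequency map for one channel
#'
#' Negative (blue) values are event-related desynchronisation, positive
#' (yellow/red) synchronisation, in percent change versus the baseline.
#'
#' @param object A `tfr_map` from [tfr_erd()].
#' @param channel Channel label (default first).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tfr_map <- function(object, channel = object$labels[1], ...) {
  ci <- match(channel, object$labels)
  if (is.na(ci)) abort(sprintf("channel %s not in TFR", channel))
  df <- expand.grid(freq = object$freqs, time_ms = object$times_ms)
  df$value <- as.vector(object$power[ci, , ])
  lim <- max(abs(df$value))
  ggplot(df, aes(x = .data$time_ms, y = .data$freq, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         limits = c(-lim, lim)) +
    labs(x = "time (ms, 0 = movement onset)", y = "frequency (Hz)",
         fill = "% change", title = sprintf("ERD/ERS at %s", channel)) +
    theme_minimal()
}

#' Scalp topography of node degree
#'
#' Electrodes are shown in a top-down azimuthal projection of the unit
#' sphere, coloured by weighted degree.
#'
#' @param degrees A `degree_vector` from [node_degree()].
#' @param montage The montage supplying electrode positions.
#' @return A ggplot.
#' @export
plot_degree_topo <- function(degrees, montage) {
  pos <- montage_positions(montage)
  idx <- match(toupper(degrees$node), toupper(rownames(pos)))
  if (anyNA(idx)) abort("degree nodes missing from montage")
  incl <- acos(pmin(1, pos[idx, "z"]))
  az <- atan2(pos[idx, "x"], pos[idx, "y"])
  df <- tibble(
    node = degrees$node, degree = degrees$degree,
    px = incl * sin(az), py = incl * cos(az)
  )
  ggplot(df, aes(x = .data$px, y = .data$py)) +
    geom_point(aes(colour = .data$degree), size = 6) +
    geom_text(aes(label = .data$node), size = 2, vjust = -1.6) +
    scale_colour_viridis_c() +
    coord_equal() +
    labs(title = "Weighted node degree", x = NULL, y = NULL) +
    theme_void()
}

#' Compare significant-edge counts across references
#'
#' Bar chart of the Table-1 style counts from a pipeline run.
#'
#' @param result A `scalpnet_result`.
#' @return A ggplot.
#' @export
plot_edge_counts <- function(result) {
  df <- result$edge_counts
  df$cell <- paste(df$stage, df$hand)
  ggplot(df, aes(x = .data$cell, y = .data$n_significant,
                 fill = .data$reference)) +
    geom_col(position = "dodge") +
    facet_wrap(~method) +
    labs(x = NULL, y = "significantly increased edges",
         fill = "reference") +
    theme_minimal()
}
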
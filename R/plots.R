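# ggplot2 visualizations for the package's result types.

#' Plot a tissue substrate
#'
#' Fibroblast labels as a raster with ACh / fibrosis patch outlines.
#' @param object [tissue_model()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.achmap_tissue <- function(object, ...) {
  df <- tibble::tibble(
    x = rep((seq_len(object$nx) - 1) * object$dx, each = object$ny),
    y = rep((seq_len(object$ny) - 1) * object$dx, times = object$nx),
    fibroblast = as.vector(object$label == 1L),
    ach = as.vector(object$ach > 0))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fibroblast)) +
    ggplot2::geom_point(data = df[df$ach, ], color = "red", size = 0.1) +
    ggplot2::scale_fill_manual(values = c("FALSE" = "grey95", "TRUE" = "grey40")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)",
                  title = sprintf("%s tissue", object$condition))
}

#' Plot a Vm movie frame
#'
#' @param object `achmap_vm`.
#' @param time Frame time (ms); nearest frame is shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.achmap_vm <- function(object, time = NULL, ...) {
  if (is.null(time)) time <- object$t[round(length(object$t) / 2)]
  k <- which.min(abs(object$t - time))
  df <- tibble::tibble(
    x = rep((seq_len(object$nx) - 1) * object$dx, times = object$ny),
    y = rep((seq_len(object$ny) - 1) * object$dx, each = object$nx),
    vm = object$vm[k, ])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$vm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Vm (mV)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)",
                  title = sprintf("Vm at t = %.0f ms", object$t[k]))
}

#' Plot electrogram waveforms
#'
#' @param object `achmap_egm`.
#' @param ... Unused.
#' @return A ggplot (one facet line per electrode, overlaid).
#' @export
autoplot.achmap_egm <- function(object, ...) {
  df <- tidy(object)
  df$electrode <- interaction(df$row, df$col)
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$phi,
                                   group = .data$electrode)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3) +
    ggplot2::labs(x = "t (ms)", y = expression(phi[e] ~ "(mV)"),
                  title = "Unipolar electrograms")
}

#' Plot a detection map
#'
#' Electrode classification (4 classes) with ground-truth ACh circles where
#' available.
#' @param object `achmap_detection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.achmap_detection <- function(object, ...) {
  df <- object$map
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$label), color = "white") +
    ggplot2::geom_point(data = df[df$truth_ach, ], shape = 1, size = 3) +
    ggplot2::scale_fill_manual(values = c(
      "nonACh" = "steelblue", "ACh" = "firebrick",
      "nonACh+fibro" = "lightblue", "ACh+fibro" = "orange"), drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "electrode column", y = "electrode row",
                  title = sprintf("ACh detection (Ac %.2f, Se %.2f, FPR %.2f)",
                                  object$metrics$ac, object$metrics$se,
                                  object$metrics$fpr),
                  caption = "circles: ground-truth ACh electrodes")
}
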
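#' Plot an axial slice of a volume, optionally with mask overlays
#'
#' @param object A `vol_image`.
#' @param slice Axial (z) slice index; defaults to the middle slice.
#' @param masks Optional named list of `vol_mask` overlays.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vol_image <- function(object, slice = NULL, masks = NULL, ...) {
  d <- dim(object$values)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  stopifnot(slice >= 1, slice <= d[3])
  sl <- object$values[, , slice]
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$intensity <- as.vector(sl)
  p <- ggplot2::ggplot(
    df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$intensity)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed(ratio = object$voxel_size[2] /
      object$voxel_size[1]) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = paste0("Axial slice ", slice)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(masks)) {
    pal <- c("red", "dodgerblue", "gold", "green3", "purple")
    for (i in seq_along(masks)) {
      msl <- masks[[i]]$values[, , slice]
      mdf <- df[as.vector(msl), c("x", "y")]
      if (nrow(mdf) > 0) {
        p <- p + ggplot2::geom_tile(
          data = mdf,
          ggplot2::aes(x = .data$x, y = .data$y),
          fill = pal[(i - 1) %% length(pal) + 1],
          alpha = 0.45, inherit.aes = FALSE
        )
      }
    }
  }
  p
}

#' Coefficient plot for a set of outcome models
#'
#' Forest-style display of the log2-volume coefficients (with 95%
#' confidence intervals) from a list of [fit_outcome_model()] fits.
#'
#' @param fits A list of `outcome_fit` objects.
#' @return A ggplot.
#' @export
plot_outcome_coefficients <- function(fits) {
  df <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      label = paste0(f$dependent, " ~ ", f$volume),
      B = f$B, lo = f$conf_int[1], hi = f$conf_int[2]
    )
  })
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$B, y = .data$label)
  ) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi)
    ) +
    ggplot2::labs(
      x = "B per volume doubling (score points)", y = NULL
    ) +
    ggplot2::theme_minimal()
}
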
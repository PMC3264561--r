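#' Plot a tissue with the publication color coding
#'
#' Cells are shaded green with brightness increasing in auxin concentration,
#' differentiated cells are marked blue, and the endosomal PIN amount is shown
#' as a red dot at the cell centroid. Optionally draws the whorl-separation
#' circle used by the organ classification.
#'
#' @param x a `tissue_mesh`.
#' @param A_max auxin level mapped to full brightness (defaults to the current
#'   maximum).
#' @param whorl_radius_fraction if not `NULL`, draw the whorl circle at this
#'   fraction of the tissue radius.
#' @param ... passed to `plot.default` for the window set-up.
#' @return invisibly, `x`.
#' @export
plot.tissue_mesh <- function(x, A_max = NULL, whorl_radius_fraction = NULL,
                             ...) {
  if (is.null(A_max)) A_max <- max(x$auxin, 1e-9)
  ex <- tissue_extent(x)
  graphics::plot(NA, xlim = ex$center[1] + c(-1, 1) * ex$radius,
                 ylim = ex$center[2] + c(-1, 1) * ex$radius,
                 asp = 1, xlab = "", ylab = "", axes = FALSE, ...)
  bright <- pmin(x$auxin / A_max, 1)
  for (i in seq_along(x$cells)) {
    xy <- x$pos[x$cells[[i]], , drop = FALSE]
    col <- if (x$differentiated[i])
      grDevices::rgb(0.2, 0.2, 0.5 + 0.5 * bright[i])
    else grDevices::rgb(0.05, 0.25 + 0.7 * bright[i], 0.05)
    graphics::polygon(xy[, 1], xy[, 2], col = col, border = "grey30",
                      lwd = 0.4)
  }
  cen <- cell_centroids(x)
  pmax_ <- max(x$pin_endo, 1e-9)
  graphics::points(cen[, 1], cen[, 2], pch = 16,
                   col = grDevices::rgb(1, 0, 0, 0.7),
                   cex = 0.2 + 1.2 * x$pin_endo / pmax_)
  if (!is.null(whorl_radius_fraction)) {
    th <- seq(0, 2 * pi, length.out = 200)
    r <- whorl_radius_fraction * ex$radius
    graphics::lines(ex$center[1] + r * cos(th), ex$center[2] + r * sin(th),
                    col = "white", lty = 2)
  }
  invisible(x)
}
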
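#' Height-field container for skin-surface topography
#'
#' A `height_field` stores a regular grid of surface elevations in
#' millimetres, together with the pixel pitch (mm between adjacent grid
#' samples, square pixels), the physical position of the grid corner, and a
#' per-cell validity mask. It is the working representation of both the raw
#' forearm surface and the band-passed surface with the global arm curvature
#' removed.
#'
#' The grid is row-major with the origin at the top-left corner and 0-based
#' physical indexing: the cell in row `r`, column `c` (1-based R indices)
#' sits at `x = origin[1] + (c - 1) * pitch`, `y = origin[2] + (r - 1) * pitch`.
#' Invalid cells (holes in the reconstruction) carry `NA` heights and
#' `FALSE` in the mask.
#'
#' @param heights Numeric matrix of elevations in mm. Non-finite entries are
#'   marked invalid.
#' @param pitch Positive scalar, mm per pixel.
#' @param origin Numeric length-2, physical (x, y) position in mm of the
#'   top-left grid corner. Default `c(0, 0)`.
#' @param mask Optional logical matrix, same shape as `heights`; `TRUE` marks
#'   valid cells. Defaults to `is.finite(heights)`. Cells flagged invalid have
#'   their height set to `NA`.
#'
#' @return An object of class `height_field`.
#' @examples
#' hf <- height_field(matrix(0, 8, 8), pitch = 0.5)
#' dim(hf)
#' @export
height_field <- function(heights, pitch, origin = c(0, 0), mask = NULL) {
  heights <- as.matrix(heights)
  if (length(heights) == 0L) stop("height field grid is empty")
  storage.mode(heights) <- "double"
  if (!is.numeric(pitch) || length(pitch) != 1L || !is.finite(pitch) || pitch <= 0)
    stop("`pitch` must be a positive scalar (mm per pixel)")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("`origin` must be a finite length-2 (x, y) position in mm")
  if (is.null(mask)) {
    mask <- is.finite(heights)
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(heights)))
      stop("`mask` must match the shape of `heights`")
    mask <- mask & is.finite(heights)
  }
  heights[!mask] <- NA_real_
  structure(
    list(heights = heights, pitch = as.numeric(pitch),
         origin = as.numeric(origin), mask = mask),
    class = "height_field"
  )
}

#' @export
dim.height_field <- function(x) dim(x$heights)

#' @export
print.height_field <- function(x, ...) {
  d <- dim(x$heights)
  zr <- suppressWarnings(range(x$heights, na.rm = TRUE))
  cat(sprintf(
    "<height_field> %d x %d px, pitch %.4g mm (%.3g x %.3g mm)\n",
    d[1], d[2], x$pitch, d[2] * x$pitch, d[1] * x$pitch))
  cat(sprintf("  origin (%.3g, %.3g) mm; %d/%d valid cells; z in [%.4g, %.4g] mm\n",
              x$origin[1], x$origin[2], sum(x$mask), length(x$mask),
              zr[1], zr[2]))
  invisible(x)
}

is_height_field <- function(x) inherits(x, "height_field")

stopifnot_height_field <- function(x) {
  if (!is_height_field(x)) stop("expected a `height_field` object")
  invisible(x)
}

#' Physical x/y coordinates of the grid axes
#'
#' @param field A `height_field`.
#' @return For `field_x`, the x position (mm) of each column; for `field_y`,
#'   the y position (mm) of each row.
#' @keywords internal
#' @noRd
field_x <- function(field) field$origin[1] + (seq_len(ncol(field$heights)) - 1) * field$pitch
field_y <- function(field) field$origin[2] + (seq_len(nrow(field$heights)) - 1) * field$pitch

#' Convert a height field to a tidy table
#'
#' One row per grid cell with physical coordinates, suitable for ggplot2 or
#' dplyr summaries.
#'
#' @param x A `height_field`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y` (mm), `z` (mm,
#'   `NA` where invalid) and `valid`.
#' @exportS3Method tibble::as_tibble
as_tibble.height_field <- function(x, ...) {
  d <- dim(x$heights)
  xs <- rep(field_x(x), each = d[1])
  ys <- rep(field_y(x), times = d[2])
  zs <- as.vector(x$heights)
  vs <- as.vector(x$mask)
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    x = xs,
    y = ys,
    z = zs,
    valid = vs
  )
}

#' Raster plot of a height field
#'
#' @param object A `height_field`.
#' @param ... Unused.
#' @return A ggplot object (filled raster of elevation in mm, equal-axis).
#' @exportS3Method ggplot2::autoplot
autoplot.height_field <- function(object, ...) {
  df <- as_tibble.height_field(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "z (mm)")
}
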
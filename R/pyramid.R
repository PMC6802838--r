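#' Gaussian-Laplacian pyramid configuration
#'
#' Settings for the multi-resolution decomposition used to strip the global
#' forearm curvature (coarse levels) and fine skin texture / sensor noise
#' (fine levels) from a height map, leaving the band that carries the wheals.
#'
#' @param n_levels Number of pyramid stages (levels `0..n_levels`); default 7.
#' @param reduce_kernel Separable 1D low-pass taps `g` applied before
#'   decimation; must sum to 1. Default 5-tap binomial `(1,4,6,4,1)/16`.
#' @param expand_kernel Separable 1D interpolation taps `h` applied after
#'   zero-insertion; must sum to 2 so that a constant survives upsampling.
#'   Default: `2 * reduce_kernel`.
#' @param keep_levels Integer set of Laplacian levels (0-based, in units of
#'   the full-resolution pyramid) retained when collapsing; default `2:5`,
#'   the band in which wheal-sized structure (roughly 3-14 mm across at
#'   typical pitches) lives.
#' @param border Border extension rule for all convolutions: `"linear"`
#'   (default) extends the surface gradient-preservingly (antisymmetric
#'   reflection about the edge sample), so the sloped arm flank leaves no
#'   crease at the grid border; `"reflect"` is plain symmetric reflection,
#'   which on sloped surfaces folds the slope back and creates edge ridges
#'   that masquerade as blobs.
#' @return An object of class `pyramid_config`.
#' @export
pyramid_config <- function(n_levels = 7, reduce_kernel = c(1, 4, 6, 4, 1) / 16,
                           expand_kernel = NULL, keep_levels = 2:5,
                           border = c("linear", "reflect")) {
  if (n_levels < 1) stop("`n_levels` must be >= 1")
  if (length(reduce_kernel) %% 2 != 1L)
    stop("`reduce_kernel` must have odd length")
  if (abs(sum(reduce_kernel) - 1) > 1e-12)
    stop("`reduce_kernel` taps must sum to 1")
  expand_kernel <- expand_kernel %||% (2 * reduce_kernel)
  if (length(expand_kernel) %% 2 != 1L)
    stop("`expand_kernel` must have odd length")
  if (abs(sum(expand_kernel) - 2) > 1e-12)
    stop("`expand_kernel` taps must sum to 2 (zero-insertion upsampling)")
  border <- match.arg(border)
  keep_levels <- sort(unique(as.integer(keep_levels)))
  if (any(keep_levels < 0) || any(keep_levels > n_levels))
    stop("`keep_levels` must lie in {0..n_levels}")
  structure(
    list(n_levels = as.integer(n_levels), reduce_kernel = reduce_kernel,
         expand_kernel = expand_kernel, keep_levels = keep_levels,
         border = border),
    class = "pyramid_config"
  )
}

## ---- separable convolution with reflective borders -------------------------

# Fold arbitrary (possibly far out-of-range) indices back into 1..n by
# symmetric reflection (edge sample repeated): ... 2 1 | 1 2 .. n | n n-1 ...
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Border extension down the columns by p rows on each side.
# "linear" (gradient-preserving, antisymmetric about the edge sample,
# pad = 2 x[edge] - x[mirror]) continues ramps exactly, so a sloped surface
# (e.g. the arm flank) produces no crease at the border; "reflect" is the
# plain symmetric extension.
pad_axis <- function(m, p, mode = c("linear", "reflect")) {
  mode <- match.arg(mode)
  if (p == 0L) return(m)
  n <- nrow(m)
  it <- seq.int(1L - p, 0L)          # positions above the top edge
  ib <- seq.int(n + 1L, n + p)       # positions below the bottom edge
  if (mode == "reflect") {
    top <- m[reflect_index(it, n), , drop = FALSE]
    bot <- m[reflect_index(ib, n), , drop = FALSE]
  } else {
    top <- 2 * m[rep(1L, p), , drop = FALSE] -
      m[reflect_index(2L - it, n), , drop = FALSE]
    bot <- 2 * m[rep(n, p), , drop = FALSE] -
      m[reflect_index(2L * n - ib, n), , drop = FALSE]
  }
  rbind(top, m, bot)
}

# FIR filter of length-k odd taps along one axis (1 = down columns, 2 = along
# rows) with border extension. stats::filter does the C-level work.
filter_axis <- function(m, taps, axis = 1L, border = "linear") {
  k <- length(taps)
  p <- (k - 1L) %/% 2L
  if (axis == 2L) return(t(filter_axis(t(m), taps, 1L, border)))
  n <- nrow(m)
  m <- pad_axis(m, p, border)
  out <- stats::filter(m, taps, method = "convolution", sides = 2L)
  attributes(out) <- list(dim = dim(out))
  if (p > 0L) out <- out[(p + 1L):(p + n), , drop = FALSE]
  out
}

sep_filter <- function(m, taps, border = "linear") {
  filter_axis(filter_axis(m, taps, 1L, border), taps, 2L, border)
}

## ---- reduce / expand -------------------------------------------------------

#' Pyramid reduce: low-pass filter and decimate by 2
#'
#' Convolves the grid separably with the reduce kernel `g` (reflective
#' borders) and keeps every other sample, yielding a grid of `ceil(n/2)`
#' rows and columns.
#'
#' @param level Numeric matrix (heights in mm).
#' @param config A [pyramid_config()].
#' @return Matrix of size `ceiling(dim(level) / 2)`.
#' @export
pyramid_reduce <- function(level, config = pyramid_config()) {
  level <- as.matrix(level)
  if (length(level) == 0L) stop("empty grid")
  if (nrow(level) < 2L || ncol(level) < 2L) stop("grid must be at least 2x2")
  sm <- sep_filter(level, config$reduce_kernel, config$border)
  sm[seq(1L, nrow(sm), by = 2L), seq(1L, ncol(sm), by = 2L), drop = FALSE]
}

#' Pyramid expand: zero-insertion upsample to a target shape and smooth
#'
#' Places the coarse samples on the even lattice of a `target_shape` grid of
#' zeros and convolves separably with the expand kernel `h` (taps summing to
#' 2 per axis, so constants are preserved).
#'
#' @param level Numeric matrix (coarse level).
#' @param target_shape Integer length-2, shape of the next-finer level; must
#'   satisfy `ceiling(target_shape / 2) == dim(level)`.
#' @param config A [pyramid_config()].
#' @return Matrix of shape `target_shape`.
#' @export
pyramid_expand <- function(level, target_shape, config = pyramid_config()) {
  level <- as.matrix(level)
  target_shape <- as.integer(target_shape)
  if (!identical(as.integer(ceiling(target_shape / 2)), as.integer(dim(level))))
    stop("`target_shape` is not compatible with the 2x decimation of `level`")
  out <- expand_axis(level, target_shape[1], config$expand_kernel, config$border)
  t(expand_axis(t(out), target_shape[2], config$expand_kernel, config$border))
}

# Upsample one axis (down the columns) from m = ceil(n/2) to n samples:
# reflect-pad the *coarse* signal (so the sample/zero parity of the
# interleaved lattice stays consistent at the borders), zero-insert with
# coarse sample j at fine position 2j - 1, convolve with the expand taps and
# crop to the target length.
expand_axis <- function(m_coarse, n, taps, border = "linear") {
  m <- nrow(m_coarse)
  k <- length(taps)
  p <- (k - 1L) %/% 2L
  pc <- p # coarse-side padding covers the fine-side kernel support
  ext <- pad_axis(m_coarse, pc, border)
  up <- matrix(0, 2L * (m + 2L * pc), ncol(m_coarse))
  up[seq(1L, nrow(up), by = 2L), ] <- ext
  conv <- stats::filter(up, taps, method = "convolution", sides = 2L)
  attributes(conv) <- list(dim = dim(conv))
  conv[(2L * pc + 1L):(2L * pc + n), , drop = FALSE]
}

## ---- decompose / collapse --------------------------------------------------

#' Decompose a height field into a Gaussian-Laplacian pyramid
#'
#' Builds Gaussian levels `G_0 = S`, `G_(l+1) = reduce(G_l)` and Laplacian
#' detail levels `L_l = G_l - expand(G_(l+1))` for `l < n`, with
#' `L_n = G_n` holding the residual coarse structure (here, the global arm
#' curvature). Invalid cells are infilled by normalized convolution before
#' decomposition (the pyramid needs a dense grid); the mask is kept so it can
#' be reapplied after collapse.
#'
#' If the grid is too small for `n_levels` (either dimension below
#' `2^n_levels`), the number of levels is lowered to the largest feasible
#' value with a warning.
#'
#' @param S A [height_field()].
#' @param config A [pyramid_config()].
#' @return An object of class `surface_pyramid` with elements
#'   `gaussian_levels`, `laplacian_levels` (lists of matrices for levels
#'   `0..n`), `level_shapes`, `config`, and the field's `pitch`, `origin`,
#'   `mask`.
#' @export
pyramid_decompose <- function(S, config = pyramid_config()) {
  stopifnot_height_field(S)
  d <- dim(S$heights)
  n <- config$n_levels
  max_n <- max(1L, floor(log2(min(d))))
  if (min(d) < 2^n) {
    warning(sprintf("grid %dx%d too small for %d pyramid levels; using %d",
                    d[1], d[2], n, max_n))
    n <- max_n
  }
  h <- S$heights
  if (!all(S$mask)) h <- infill_invalid(h, S$mask)

  gl <- vector("list", n + 1L)
  ll <- vector("list", n + 1L)
  gl[[1L]] <- h
  for (l in seq_len(n)) gl[[l + 1L]] <- pyramid_reduce(gl[[l]], config)
  for (l in seq_len(n)) {
    ll[[l]] <- gl[[l]] - pyramid_expand(gl[[l + 1L]], dim(gl[[l]]), config)
  }
  ll[[n + 1L]] <- gl[[n + 1L]]
  structure(
    list(gaussian_levels = gl, laplacian_levels = ll,
         level_shapes = lapply(gl, dim),
         config = config, n_levels = n,
         pitch = S$pitch, origin = S$origin, mask = S$mask),
    class = "surface_pyramid"
  )
}

#' @export
print.surface_pyramid <- function(x, ...) {
  shp <- vapply(x$level_shapes, function(d) paste(d, collapse = "x"), "")
  cat(sprintf("<surface_pyramid> levels 0..%d: %s\n", x$n_levels,
              paste(shp, collapse = " > ")))
  invisible(x)
}

#' Collapse a pyramid keeping only selected Laplacian levels
#'
#' Zeroes every Laplacian level not in `keep_levels` and reconstructs coarse
#' to fine (`R_n = L~_n`; `R_l = L~_l + expand(R_(l+1))`). Keeping all levels
#' reproduces the input field (perfect reconstruction); keeping the
#' mid-frequency band isolates wheal-scale structure.
#'
#' `keep_levels` is interpreted in units of the full-resolution pyramid: if
#' the decomposition used fewer levels than requested, kept levels beyond the
#' top are absent and a warning is given.
#'
#' @param pyramid A `surface_pyramid` from [pyramid_decompose()].
#' @param keep_levels Integer set of levels (0-based) to retain; defaults to
#'   the configuration's `keep_levels`.
#' @return A [height_field()] (mask reapplied from the source field).
#' @export
pyramid_collapse <- function(pyramid, keep_levels = NULL) {
  if (!inherits(pyramid, "surface_pyramid")) stop("expected a `surface_pyramid`")
  cfg <- pyramid$config
  keep_levels <- sort(unique(as.integer(keep_levels %||% cfg$keep_levels)))
  n <- pyramid$n_levels
  if (any(keep_levels < 0)) stop("`keep_levels` must be >= 0")
  if (any(keep_levels > n)) {
    absent <- keep_levels[keep_levels > n]
    if (any(absent > cfg$n_levels))
      stop("`keep_levels` must lie in {0..n_levels}")
    warning("kept levels ", paste(absent, collapse = ", "),
            " are absent from this ", n, "-level decomposition")
    keep_levels <- keep_levels[keep_levels <= n]
  }
  ll <- pyramid$laplacian_levels
  r <- if ((n) %in% keep_levels) ll[[n + 1L]] else
    matrix(0, pyramid$level_shapes[[n + 1L]][1], pyramid$level_shapes[[n + 1L]][2])
  for (l in rev(seq_len(n) - 1L)) { # n-1 .. 0
    r <- pyramid_expand(r, pyramid$level_shapes[[l + 1L]], cfg)
    if (l %in% keep_levels) r <- r + ll[[l + 1L]]
  }
  r[!pyramid$mask] <- NA_real_
  height_field(r, pitch = pyramid$pitch, origin = pyramid$origin,
               mask = pyramid$mask)
}

#' Remove the global arm surface from a height map
#'
#' Band-pass filters a forearm height map by Gaussian-Laplacian pyramid
#' decomposition followed by band-selective collapse: the coarse levels
#' (global forearm curvature) and the finest levels (sensor noise, pores,
#' follicles, fine wrinkles) are zeroed, retaining the wheal-scale band.
#'
#' @param S A [height_field()].
#' @param config A [pyramid_config()]; `config$keep_levels` (default `2:5`)
#'   selects the retained band.
#' @return A [height_field()] `S'` with the same shape, pitch, origin and
#'   mask as `S`.
#' @export
remove_global_surface <- function(S, config = pyramid_config()) {
  pyramid_collapse(pyramid_decompose(S, config), config$keep_levels)
}

# Normalized-convolution infill of invalid cells: smooth (heights * mask) and
# mask with the reduce kernel, take the ratio where the support is
# sufficient, iterate until every hole is filled.
infill_invalid <- function(h, mask, max_iter = 1000L) {
  taps <- c(1, 4, 6, 4, 1) / 16
  h[!mask] <- 0
  w <- mask * 1
  for (i in seq_len(max_iter)) {
    if (all(w > 0)) break
    hs <- sep_filter(h * (w > 0), taps)
    ws <- sep_filter((w > 0) * 1, taps)
    newly <- w == 0 & ws > 1e-6
    h[newly] <- hs[newly] / ws[newly]
    w[newly] <- 1
  }
  if (!all(w > 0)) stop("could not infill invalid cells")
  h
}
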
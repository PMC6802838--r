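#' Wheal detection configuration
#'
#' Settings for the multi-scale scale-normalized Laplacian-of-Gaussian (LoG)
#' blob detector that finds wheal candidates in the band-passed surface.
#' A blob of radius `r` responds maximally near `sigma = r / sqrt(2)`, so the
#' default ladder `sigma` in `[1, 5]` mm covers wheal diameters of roughly
#' 3-14 mm.
#'
#' @param sigma_min,sigma_max Smallest / largest filter scale in mm
#'   (defaults 1 and 5).
#' @param n_scales Number of geometrically spaced scales (default 12).
#' @param response_threshold Minimum scale-normalized LoG response in mm
#'   (default 0.03); for a Gaussian bump the centre response at the matched
#'   scale is half the bump height, so this admits bumps upward of ~0.06 mm.
#' @param overlap_threshold Fraction in `[0, 1]` (default 0.5): of two
#'   detections whose `sigma * sqrt(2)` circles overlap by more than this
#'   fraction of the smaller circle, the weaker is pruned.
#' @param patch_halfwidth_factor Dimensionless `k` (default 2): patches are
#'   cut with half-width `round(k * sigma * sqrt(2) / pitch)` pixels.
#' @param edge_ratio Principal-curvature ratio bound (default 10) of the
#'   Hessian edge test: candidates whose response Hessian at the detected
#'   scale is ridge-like (`trace^2 / det > (edge_ratio + 1)^2 / edge_ratio`,
#'   or `det <= 0`) are rejected. Wheals are compact blobs; elongated
#'   responses come from residual curvature structure (the band-passed
#'   pedestal of the arm's global shape) and skin creases, not wheals.
#'   `Inf` disables the test.
#' @param ridge_background Per-scale response normalization:
#'   `"long_axis_median"` (default) subtracts from each response plane its
#'   running median along the grid's long axis (per short-axis position).
#'   The band-pass residual of the arm's global curvature is constant along
#'   the arm, so this cancels it exactly while leaving localized blob
#'   responses untouched (a wheal occupies a small fraction of the arm's
#'   length); `"none"` disables it.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(sigma_min = 1.0, sigma_max = 5.0, n_scales = 12,
                             response_threshold = 0.03, overlap_threshold = 0.5,
                             patch_halfwidth_factor = 2.0, edge_ratio = 10,
                             ridge_background = c("long_axis_median", "none")) {
  if (!(sigma_min > 0 && sigma_min < sigma_max)) stop("need 0 < sigma_min < sigma_max")
  if (n_scales < 2) stop("`n_scales` must be >= 2")
  if (response_threshold < 0 || overlap_threshold < 0)
    stop("thresholds must be >= 0")
  structure(
    list(sigma_min = sigma_min, sigma_max = sigma_max,
         n_scales = as.integer(n_scales),
         response_threshold = response_threshold,
         overlap_threshold = overlap_threshold,
         patch_halfwidth_factor = patch_halfwidth_factor,
         edge_ratio = edge_ratio,
         ridge_background = match.arg(ridge_background)),
    class = "detection_config"
  )
}

gaussian_taps <- function(sigma_px) {
  r <- max(1L, ceiling(3.5 * sigma_px))
  t <- exp(-(seq.int(-r, r))^2 / (2 * sigma_px^2))
  t / sum(t)
}

#' Scale-normalized Laplacian-of-Gaussian response
#'
#' Smooths the band-passed surface with an isotropic Gaussian of standard
#' deviation `sigma` (mm) and applies the (sign-flipped, scale-normalized)
#' Laplacian, `-sigma^2 * del^2 (G_sigma * S')`, so that raised bumps give
#' positive peaks and responses are comparable across scales. Units are mm.
#' Invalid cells are treated as zero height and their response is set to
#' `NA`.
#'
#' @param S_prime A [height_field()], typically from
#'   [remove_global_surface()].
#' @param sigma Scale in mm; must be at least half a pixel.
#' @param border Border extension rule (see [pyramid_config()]).
#' @return Numeric matrix of responses (mm).
#' @export
log_response <- function(S_prime, sigma, border = "linear") {
  stopifnot_height_field(S_prime)
  if (sigma <= 0 || sigma / S_prime$pitch < 0.5)
    stop("`sigma` must be positive and at least half a pixel pitch")
  h <- S_prime$heights
  h[!S_prime$mask] <- 0
  sm <- sep_filter(h, gaussian_taps(sigma / S_prime$pitch), border)
  lap <- (filter_axis(sm, c(1, -2, 1), 1L, border) +
            filter_axis(sm, c(1, -2, 1), 2L, border)) / S_prime$pitch^2
  resp <- -sigma^2 * lap
  resp[!S_prime$mask] <- NA_real_
  resp
}

#' Detect wheal candidates as scale-space maxima
#'
#' Builds the stack of scale-normalized LoG responses over a geometric
#' `sigma` ladder, keeps strict 3x3x3 scale-space maxima with response at or
#' above the threshold, prunes overlapping detections (the weaker of any pair
#' whose `sigma * sqrt(2)` circles overlap by more than the configured
#' fraction of the smaller circle), and returns the survivors sorted by
#' descending response.
#'
#' @param S_prime A [height_field()] after global-surface removal.
#' @param config A [detection_config()].
#' @return A tibble of class `blob_candidates`, one row per candidate:
#'   `row`, `col` (grid indices), `x_mm`, `y_mm` (physical centre),
#'   `scale_sigma` (mm), `response` (mm).
#' @export
detect_wheals <- function(S_prime, config = detection_config()) {
  stopifnot_height_field(S_prime)
  sigmas <- exp(seq(log(config$sigma_min), log(config$sigma_max),
                    length.out = config$n_scales))
  d <- dim(S_prime$heights)
  # spectral scale ladder: one forward FFT of the (linearly extended)
  # surface, then per scale an analytic scale-normalized LoG transfer
  # multiply and inverse FFT
  h <- S_prime$heights
  h[!S_prime$mask] <- 0
  pitch <- S_prime$pitch
  stack <- array(NA_real_, c(d, config$n_scales))
  pad <- as.integer(ceiling(3.5 * max(sigmas) / pitch))
  n1 <- stats::nextn(d[1] + 2L * pad, c(2, 3, 5))
  n2 <- stats::nextn(d[2] + 2L * pad, c(2, 3, 5))
  hp <- pad_axis_asym(h, pad, n1 - d[1] - pad)
  hp <- t(pad_axis_asym(t(hp), pad, n2 - d[2] - pad))
  FS <- stats::fft(hp)
  f1 <- freq_cpp(n1); f2 <- freq_cpp(n2)
  f2tot <- outer(f1^2, f2^2, `+`)
  for (k in seq_along(sigmas)) {
    sp2 <- (sigmas[k] / pitch)^2
    H <- 4 * pi^2 * sp2 * f2tot * exp(-2 * pi^2 * sp2 * f2tot)
    plane <- Re(stats::fft(FS * H, inverse = TRUE)) / (n1 * n2)
    plane <- plane[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2])]
    plane[!S_prime$mask] <- NA_real_
    if (config$ridge_background == "long_axis_median") {
      if (d[1] >= d[2]) {
        plane <- plane - rep(apply(plane, 2, stats::median, na.rm = TRUE),
                             each = d[1])
      } else {
        plane <- plane - apply(plane, 1, stats::median, na.rm = TRUE)
      }
    }
    stack[, , k] <- plane
  }
  stack[is.na(stack)] <- -Inf

  cand <- which(stack >= config$response_threshold, arr.ind = TRUE)
  empty <- tibble::tibble(row = integer(), col = integer(),
                          x_mm = double(), y_mm = double(),
                          scale_sigma = double(), response = double())
  class(empty) <- c("blob_candidates", class(empty))
  if (nrow(cand) == 0L) return(empty)

  # strict local maxima over the 26-neighbourhood (existing neighbours only
  # at spatial borders and at the first/last scale)
  nr <- d[1]; nc <- d[2]; nk <- config$n_scales
  lin <- function(r, c, k) r + (c - 1L) * nr + (k - 1L) * (nr * nc)
  v <- stack[lin(cand[, 1], cand[, 2], cand[, 3])]
  keep <- rep(TRUE, nrow(cand))
  for (dr in -1:1) for (dc in -1:1) for (dk in -1:1) {
    if (dr == 0L && dc == 0L && dk == 0L) next
    r2 <- cand[, 1] + dr; c2 <- cand[, 2] + dc; k2 <- cand[, 3] + dk
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc & k2 >= 1L & k2 <= nk
    idx <- which(keep & ok)
    if (!length(idx)) next
    nb <- stack[lin(r2[idx], c2[idx], k2[idx])]
    keep[idx] <- v[idx] > nb
  }
  cand <- cand[keep, , drop = FALSE]
  v <- v[keep]
  if (nrow(cand) == 0L) return(empty)

  # Hessian edge test on the response plane at the detected scale: keep only
  # compact (blob-like) maxima
  if (is.finite(config$edge_ratio)) {
    er <- config$edge_ratio
    ok <- vapply(seq_len(nrow(cand)), function(i) {
      r <- cand[i, 1]; c <- cand[i, 2]; k <- cand[i, 3]
      if (r <= 1L || r >= nr || c <= 1L || c >= nc) return(FALSE)
      dxx <- stack[r, c + 1L, k] - 2 * stack[r, c, k] + stack[r, c - 1L, k]
      dyy <- stack[r + 1L, c, k] - 2 * stack[r, c, k] + stack[r - 1L, c, k]
      dxy <- (stack[r + 1L, c + 1L, k] - stack[r + 1L, c - 1L, k] -
                stack[r - 1L, c + 1L, k] + stack[r - 1L, c - 1L, k]) / 4
      det <- dxx * dyy - dxy^2
      det > 0 && (dxx + dyy)^2 / det <= (er + 1)^2 / er
    }, logical(1))
    cand <- cand[ok, , drop = FALSE]
    v <- v[ok]
    if (nrow(cand) == 0L) return(empty)
  }

  ord <- order(v, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; v <- v[ord]
  res <- tibble::tibble(
    row = as.integer(cand[, 1]), col = as.integer(cand[, 2]),
    x_mm = S_prime$origin[1] + (cand[, 2] - 1) * S_prime$pitch,
    y_mm = S_prime$origin[2] + (cand[, 1] - 1) * S_prime$pitch,
    scale_sigma = sigmas[cand[, 3]], response = v
  )

  # greedy overlap pruning, strongest first
  kept <- integer(0)
  for (i in seq_len(nrow(res))) {
    ok <- TRUE
    for (j in kept) {
      ov <- circle_overlap_fraction(
        sqrt((res$x_mm[i] - res$x_mm[j])^2 + (res$y_mm[i] - res$y_mm[j])^2),
        res$scale_sigma[i] * sqrt(2), res$scale_sigma[j] * sqrt(2))
      if (ov > config$overlap_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  res <- res[kept, ]
  class(res) <- c("blob_candidates", class(res))
  res
}

# frequency grid in cycles per pixel for an n-point DFT
freq_cpp <- function(n) {
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  f[seq_len(n)]
}

# asymmetric gradient-preserving padding (p1 rows before, p2 after)
pad_axis_asym <- function(m, p1, p2) {
  n <- nrow(m)
  it <- seq.int(1L - p1, 0L)
  ib <- seq.int(n + 1L, n + p2)
  top <- 2 * m[rep(1L, p1), , drop = FALSE] -
    m[reflect_index(2L - it, n), , drop = FALSE]
  bot <- 2 * m[rep(n, p2), , drop = FALSE] -
    m[reflect_index(2L * n - ib, n), , drop = FALSE]
  rbind(top, m, bot)
}

# Area of intersection of two circles at centre distance d, as a fraction of
# the smaller circle's area.
circle_overlap_fraction <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  rmin <- min(r1, r2); rmax <- max(r1, r2)
  if (d <= rmax - rmin) return(1)
  a1 <- r1^2 * acos(pmin(1, pmax(-1, (d^2 + r1^2 - r2^2) / (2 * d * r1))))
  a2 <- r2^2 * acos(pmin(1, pmax(-1, (d^2 + r2^2 - r1^2) / (2 * d * r2))))
  a3 <- 0.5 * sqrt(pmax(0, (-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2)))
  (a1 + a2 - a3) / (pi * rmin^2)
}

#' Cut surface patches around detected candidates
#'
#' Extracts a square window of half-width `round(k * sigma * sqrt(2) / pitch)`
#' pixels around each candidate, clipped at the field borders (clipped
#' patches are flagged, not rejected).
#'
#' @param S_prime The [height_field()] the candidates were detected in.
#' @param candidates A `blob_candidates` tibble from [detect_wheals()].
#' @param config A [detection_config()] (supplies `k`).
#' @return A list of `wheal_patch` objects with elements `surface` (matrix,
#'   mm), `pitch`, `origin_global` ((x, y) mm of the patch corner), `source`
#'   (the candidate row), and `clipped`.
#' @export
extract_patches <- function(S_prime, candidates, config = detection_config()) {
  stopifnot_height_field(S_prime)
  purrr::pmap(as.list(tibble::as_tibble(candidates)), function(row, col, x_mm, y_mm,
                                                               scale_sigma, response, ...) {
    hw <- round(config$patch_halfwidth_factor * scale_sigma * sqrt(2) / S_prime$pitch)
    cut_patch(S_prime, list(row = row, col = col, x_mm = x_mm, y_mm = y_mm,
                            scale_sigma = scale_sigma, response = response), hw)
  })
}

# Cut one square window of half-width `hw` pixels around a candidate.
cut_patch <- function(S_prime, source, hw) {
  d <- dim(S_prime$heights)
  r0 <- max(1L, source$row - hw); r1 <- min(d[1], source$row + hw)
  c0 <- max(1L, source$col - hw); c1 <- min(d[2], source$col + hw)
  structure(
    list(
      surface = S_prime$heights[r0:r1, c0:c1, drop = FALSE],
      pitch = S_prime$pitch,
      origin_global = c(S_prime$origin[1] + (c0 - 1) * S_prime$pitch,
                        S_prime$origin[2] + (r0 - 1) * S_prime$pitch),
      source = source,
      clipped = (r1 - r0 != 2L * hw) || (c1 - c0 != 2L * hw)
    ),
    class = "wheal_patch"
  )
}

#' @export
print.wheal_patch <- function(x, ...) {
  cat(sprintf("<wheal_patch> %dx%d px at (%.2f, %.2f) mm, sigma %.2f mm%s%s\n",
              nrow(x$surface), ncol(x$surface),
              x$source$x_mm, x$source$y_mm, x$source$scale_sigma,
              if (x$clipped) ", clipped" else "",
              if (!is.null(x$points_centered)) ", centered" else ""))
  invisible(x)
}
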
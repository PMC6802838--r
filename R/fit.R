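#' Fit settings for parametric wheal models
#'
#' @param model Which surface model to fit: `"super_gaussian"` (2D
#'   super-Gaussian, the default), `"paraboloid"` (inverted elliptical
#'   paraboloid), or `"both"`.
#' @param max_iter Maximum optimizer iterations (default 500).
#' @param tol Parameter and cost tolerance (default 1e-8).
#' @param support_fraction For the paraboloid model, residuals are evaluated
#'   only on cells above this fraction of the patch peak (default 0.05) plus
#'   a one-pixel annulus: the paraboloid diverges to minus infinity, so an
#'   unweighted full-patch fit would let the flat background dominate and
#'   shrink the ellipse.
#' @param fallback_range_mm Plausible diameter range in mm (default
#'   `c(1, 20)`); a non-converged fit or a diameter outside this range falls
#'   back to the detection scale (`2 * sqrt(2) * sigma`).
#' @param smoothing_sigma Standard deviation in mm of the Gaussian the model
#'   is convolved with before computing residuals. A patch cut from the
#'   band-passed surface has lost the finest pyramid levels, i.e. it is the
#'   true skin relief smoothed by the level-cut kernel; fitting the smoothed
#'   model recovers the parameters of the unsmoothed wheal. `NULL` (the
#'   default) means "decide at pipeline level": [measure_spt()] substitutes
#'   the cut width implied by its pyramid configuration
#'   ([pyramid_cut_sigma()]); a standalone [fit_wheal()] call treats it
#'   as 0 (no smoothing).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(model = c("super_gaussian", "paraboloid", "both"),
                       max_iter = 500, tol = 1e-8,
                       support_fraction = 0.05,
                       fallback_range_mm = c(1, 20),
                       smoothing_sigma = NULL) {
  structure(
    list(model = match.arg(model), max_iter = as.integer(max_iter), tol = tol,
         support_fraction = support_fraction,
         fallback_range_mm = fallback_range_mm,
         smoothing_sigma = smoothing_sigma),
    class = "fit_config"
  )
}

#' Effective smoothing width of the discarded fine pyramid levels
#'
#' Collapsing a Laplacian pyramid without its levels below `min(keep_levels)`
#' returns the surface low-pass filtered by the cascade of reduce and expand
#' kernels down to that level. This returns the standard deviation (mm) of
#' the equivalent Gaussian, from the second moments of the kernels:
#' `var = (var_g + var_h) * (1 + 4 + ... + 4^(kmin-1))` in pixels squared.
#'
#' @param config A [pyramid_config()].
#' @param pitch Pixel pitch in mm.
#' @return Smoothing SD in mm (0 if level 0 is kept).
#' @export
pyramid_cut_sigma <- function(config = pyramid_config(), pitch) {
  kmin <- min(config$keep_levels)
  if (kmin == 0L) return(0)
  tap_var <- function(t) {
    i <- seq_along(t) - (length(t) + 1) / 2
    sum(t * i^2) / sum(t)
  }
  vg <- tap_var(config$reduce_kernel)
  vh <- tap_var(config$expand_kernel)
  pitch * sqrt((vg + vh) * sum(4^(seq_len(kmin) - 1)))
}

#' Centre a wheal patch at its centre of mass
#'
#' Converts the patch grid to `(x, y, z)` points, removes the local skin
#' baseline, subtracts the `(x, y)` centroid weighted by `max(z, 0)`, and
#' sets the initial rotation angle from the principal axis of the
#' weight-weighted second-moment matrix (mapped to `[-pi/2, pi/2)`).
#'
#' The baseline is a plane least-squares fitted to the patch's outer ring
#' (cells beyond 80% of the patch half-width, trimmed of the highest fifth
#' so a neighbouring bump cannot tilt it). Band-selective pyramid collapse
#' leaves a smooth pedestal wherever the arm's global surface is curved
#' (the band-pass of a curved surface retains a term proportional to its
#' local curvature); both parametric models assume the skin rests at
#' `z = 0`, so the locally constant-plus-tilt pedestal must be taken out
#' before fitting.
#'
#' @param patch A `wheal_patch` from [extract_patches()].
#' @param baseline `"ring_plane"` (default) removes the ring-fitted plane;
#'   `"none"` disables baseline removal.
#' @return The patch with `points_centered` (tibble `x`, `y`, `z`; mm),
#'   `centroid_global` ((x, y) mm), `theta_init` (radians), `peak` (mm) and
#'   `baseline` (plane coefficients) filled in. Elevated cells that belong
#'   to a *different* connected component than the candidate centre (the
#'   flank of a neighbouring wheal caught by a large window) are excluded
#'   from the points.
#' @export
center_patch <- function(patch, baseline = c("ring_plane", "none")) {
  if (!inherits(patch, "wheal_patch")) stop("expected a `wheal_patch`")
  baseline <- match.arg(baseline)
  z <- patch$surface
  d <- dim(z)
  x <- patch$origin_global[1] + (rep(seq_len(d[2]), each = d[1]) - 1) * patch$pitch
  y <- patch$origin_global[2] + (rep(seq_len(d[1]), times = d[2]) - 1) * patch$pitch
  zv <- as.vector(z)
  ok <- is.finite(zv)
  if (!any(ok)) stop("degenerate patch: no finite heights")

  bl <- c(0, 0, 0)
  if (baseline == "ring_plane") {
    cx0 <- mean(range(x[ok])); cy0 <- mean(range(y[ok]))
    half <- max(abs(c(x[ok] - cx0, y[ok] - cy0)))
    ring <- ok & pmax(abs(x - cx0), abs(y - cy0)) >= 0.8 * half
    if (sum(ring) >= 12L) {
      keep <- ring & zv <= stats::quantile(zv[ring], 0.8)
      A <- cbind(1, x[keep] - cx0, y[keep] - cy0)
      bl <- qr.coef(qr(A), zv[keep])
      bl[is.na(bl)] <- 0
      zv <- zv - (bl[1] + bl[2] * (x - cx0) + bl[3] * (y - cy0))
    }
  }
  patch$baseline <- bl

  peak0 <- max(zv[ok])
  if (!is.finite(peak0) || peak0 <= 0) stop("degenerate patch: no positive heights")

  # connected elevated component around the candidate centre; other elevated
  # components are neighbouring wheals leaking into the window
  zm <- matrix(zv, d[1], d[2])
  zm[!ok] <- -Inf
  el <- zm > 0.05 * peak0
  sr <- round((patch$source$y_mm - patch$origin_global[2]) / patch$pitch) + 1L
  sc <- round((patch$source$x_mm - patch$origin_global[1]) / patch$pitch) + 1L
  sr <- min(max(sr, 1L), d[1]); sc <- min(max(sc, 1L), d[2])
  primary <- flood_component(el, sr, sc)
  drop_cells <- as.vector(el & !primary)

  sel <- ok & !drop_cells
  x <- x[sel]; y <- y[sel]; zv2 <- zv[sel]

  # second baseline stage: the band-passed pedestal of a curved arm is
  # locally quadratic, not planar; fit a quadratic surface to the
  # non-elevated background cells and remove it
  if (baseline == "ring_plane") {
    bg <- sel & !as.vector(el)
    if (sum(bg) >= max(20L, 0.25 * sum(sel))) {
      xb <- x[bg[sel]] - mean(x); yb <- y[bg[sel]] - mean(y)
      A2 <- cbind(1, xb, yb, xb^2, xb * yb, yb^2)
      q <- qr.coef(qr(A2), zv[bg])
      q[is.na(q)] <- 0
      xa <- x - mean(x); ya <- y - mean(y)
      zv2 <- zv2 - (q[1] + q[2] * xa + q[3] * ya + q[4] * xa^2 +
                      q[5] * xa * ya + q[6] * ya^2)
      patch$baseline_quad <- q
    }
  }
  peak <- max(zv2)
  if (!is.finite(peak) || peak <= 0) stop("degenerate patch: no positive heights")
  usable <- zv2 > 0.1 * peak
  if (sum(usable) < 8L) stop("degenerate patch: fewer than 8 usable points")
  w <- pmax(zv2, 0)
  cx <- sum(w * x) / sum(w)
  cy <- sum(w * y) / sum(w)
  xc <- x - cx; yc <- y - cy
  cxx <- sum(w * xc^2); cyy <- sum(w * yc^2); cxy <- sum(w * xc * yc)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
  v <- ev$vectors[, 1]
  theta <- wrap_half_pi(atan2(v[2], v[1]))
  patch$points_centered <- tibble::tibble(x = xc, y = yc, z = zv2)
  patch$cell_index <- which(sel) # linear indices of the points in the grid
  patch$grid_centered <- list(
    dim = d,
    x = patch$origin_global[1] + (seq_len(d[2]) - 1) * patch$pitch - cx,
    y = patch$origin_global[2] + (seq_len(d[1]) - 1) * patch$pitch - cy)
  patch$centroid_global <- c(cx, cy)
  patch$theta_init <- theta
  patch$peak <- peak
  # second-moment SDs along the principal axes, for initialization
  patch$moment_sd <- sqrt(pmax(ev$values, 1e-12) / sum(w))
  patch
}

# Connected component (8-neighbourhood) of `mask` containing (r0, c0); if
# that cell is not set, seeded from the nearest set cell within 10 pixels
# (else from the global maximum is unnecessary - return the empty mask and
# let the caller treat everything as primary).
flood_component <- function(mask, r0, c0) {
  d <- dim(mask)
  if (!mask[r0, c0]) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(mask & FALSE)
    dist2 <- (idx[, 1] - r0)^2 + (idx[, 2] - c0)^2
    if (min(dist2) > 100) return(mask) # nothing near the centre: keep all
    j <- which.min(dist2)
    r0 <- idx[j, 1]; c0 <- idx[j, 2]
  }
  comp <- matrix(FALSE, d[1], d[2])
  comp[r0, c0] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-d[1], ]
    grown[-d[1], ] <- grown[-d[1], ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -d[2]]
    grown[, -d[2]] <- grown[, -d[2]] | comp[, -1]
    grown[-1, -1] <- grown[-1, -1] | comp[-d[1], -d[2]]
    grown[-1, -d[2]] <- grown[-1, -d[2]] | comp[-d[1], -1]
    grown[-d[1], -1] <- grown[-d[1], -1] | comp[-1, -d[2]]
    grown[-d[1], -d[2]] <- grown[-d[1], -d[2]] | comp[-1, -1]
    grown <- grown & mask
    if (identical(grown, comp)) return(comp)
    comp <- grown
  }
}

wrap_half_pi <- function(theta) {
  ((theta + pi / 2) %% pi) - pi / 2
}

#' Evaluate a parametric wheal surface model
#'
#' Coordinates are first rotated clockwise by the model's angle `theta`
#' (`x' = x cos(theta) - y sin(theta)`, `y' = x sin(theta) + y cos(theta)`),
#' then the surface is evaluated:
#' * `"paraboloid"` (model 1, inverted elliptical paraboloid):
#'   `f1 = -(1/c) * ((x'-x0')^2 / wx^2 + (y'-y0')^2 / wy^2) + beta`.
#'   Its `f1 = 0` level set is an ellipse with semi-axes
#'   `a = wx * sqrt(beta c)`, `b = wy * sqrt(beta c)`.
#' * `"super_gaussian"` (model 2):
#'   `f2 = gamma * exp(-((x'-x0')^2 / (2 sigma_x^2))^beta_x -
#'   ((y'-y0')^2 / (2 sigma_y^2))^beta_y)`; the exponents flatten the top
#'   (`beta > 1`), matching the typically flat-topped wheal profile.
#'
#' @param kind `"paraboloid"` or `"super_gaussian"`.
#' @param params Named list of model parameters: `x0p`, `y0p`, `theta`, plus
#'   `wx`, `wy`, `c`, `beta` (paraboloid) or `sigma_x`, `sigma_y`, `beta_x`,
#'   `beta_y`, `gamma` (super-Gaussian).
#' @param x,y Numeric vectors of coordinates in mm (patch-centered frame).
#' @return Numeric vector of surface heights in mm.
#' @export
eval_model <- function(kind, params, x, y) {
  kind <- match.arg(kind, c("paraboloid", "super_gaussian"))
  p <- params
  xr <- x * cos(p$theta) - y * sin(p$theta)
  yr <- x * sin(p$theta) + y * cos(p$theta)
  if (kind == "paraboloid") {
    if (p$wx <= 0 || p$wy <= 0) stop("invalid params: widths must be positive")
    -(1 / p$c) * ((xr - p$x0p)^2 / p$wx^2 + (yr - p$y0p)^2 / p$wy^2) + p$beta
  } else {
    if (p$sigma_x <= 0 || p$sigma_y <= 0 || p$gamma <= 0)
      stop("invalid params: sigma and gamma must be positive")
    p$gamma * exp(-((xr - p$x0p)^2 / (2 * p$sigma_x^2))^p$beta_x -
                    ((yr - p$y0p)^2 / (2 * p$sigma_y^2))^p$beta_y)
  }
}

#' Longest wheal diameter implied by a fitted model
#'
#' Model 1: the zero-level ellipse of the paraboloid has semi-axes
#' `a = wx * sqrt(beta c)` and `b = wy * sqrt(beta c)`; the diameter is
#' `max(2a, 2b)` (requires `beta * c > 0` for a real ellipse). Model 2: the
#' longest side of the effective bounding box, `max(4 sigma_x, 4 sigma_y)`.
#'
#' @inheritParams eval_model
#' @return Diameter in mm.
#' @export
wheal_diameter <- function(kind, params) {
  kind <- match.arg(kind, c("paraboloid", "super_gaussian"))
  p <- params
  if (kind == "paraboloid") {
    if (p$beta * p$c <= 0)
      stop("no real zero-level ellipse: beta * c must be positive")
    s <- sqrt(p$beta * p$c)
    max(2 * p$wx * s, 2 * p$wy * s)
  } else {
    max(4 * p$sigma_x, 4 * p$sigma_y)
  }
}

#' Fit a parametric surface model to a centered wheal patch
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box
#' constraints) over the model parameters including the rotation angle,
#' initialized from the patch statistics (peak height, weighted second
#' moments, principal-axis angle). For the paraboloid model the residuals
#' are restricted to the elevated support (see [fit_config()]). After the
#' fit, the axis-swap degeneracy is resolved by relabelling so the x width
#' is the larger one. A non-converged fit, or a diameter outside the
#' plausible range, falls back to the detection-scale diameter
#' `2 sqrt(2) sigma`.
#'
#' @param patch A centered `wheal_patch` (see [center_patch()]).
#' @param kind `"paraboloid"` or `"super_gaussian"`.
#' @param config A [fit_config()].
#' @return An object of class `wheal_fit`: `model_kind`, `params`,
#'   `diameter_mm`, `rms_residual` (mm), `converged`, `n_points`,
#'   `fallback_used`.
#' @export
fit_wheal <- function(patch, kind = c("super_gaussian", "paraboloid"),
                      config = fit_config()) {
  kind <- match.arg(kind)
  if (is.null(patch$points_centered))
    stop("patch is not centered; call `center_patch()` first")
  pts <- patch$points_centered
  peak <- patch$peak
  half_extent <- max(abs(c(pts$x, pts$y)))

  support <- rep(TRUE, nrow(pts))
  if (kind == "paraboloid") {
    support <- paraboloid_support(pts, patch$peak, config$support_fraction)
  }
  n_par <- if (kind == "paraboloid") 7L else 8L
  if (sum(support) < 2L * n_par)
    stop("too few points in fit support (", sum(support), ")")
  xs <- pts$x[support]; ys <- pts$y[support]; zs <- pts$z[support]

  sd1 <- max(patch$moment_sd[1], 0.26); sd2 <- max(patch$moment_sd[2], 0.26)
  # theta_init is the bump's principal-axis angle in the grid frame; the
  # model rotates coordinates clockwise by theta, so the matching model
  # angle is its negative
  theta0 <- wrap_half_pi(-patch$theta_init)
  if (kind == "super_gaussian") {
    start <- c(x0p = 0, y0p = 0, sigma_x = sd1, sigma_y = sd2,
               beta_x = 1, beta_y = 1, gamma = peak, theta = theta0)
    lower <- c(-half_extent, -half_extent, 0.25, 0.25, 0.5, 0.5, 1e-4, -pi / 2)
    upper <- c(half_extent, half_extent, 15, 15, 10, 10, 2 * peak, pi / 2 - 1e-9)
  } else {
    s0 <- mean(c(sd1, sd2))
    start <- c(x0p = 0, y0p = 0, wx = sd1, wy = sd2,
               c = 1 / s0, beta = peak, theta = theta0)
    lower <- c(-half_extent, -half_extent, 0.25, 0.25, 1e-3, 1e-6, -pi / 2)
    upper <- c(half_extent, half_extent, 15, 15, 1e3, 2 * peak, pi / 2 - 1e-9)
  }

  smooth_sigma <- config$smoothing_sigma %||% 0
  if (smooth_sigma > 0) {
    gd <- patch$grid_centered
    xg_full <- rep(gd$x, each = gd$dim[1])
    yg_full <- rep(gd$y, times = gd$dim[2])
    taps <- gaussian_taps(smooth_sigma / patch$pitch)
    sup_cells <- patch$cell_index[support]
  }
  run <- function(st) {
    # rotated frame: the centre (x0p, y0p) lives in rotated coordinates, so
    # the parameterization is exactly eval_model's. With smoothing, the
    # model is evaluated on the full patch grid and convolved with the
    # pyramid level-cut kernel before the residuals are taken.
    resid_fn <- function(par) {
      p <- as.list(par)
      if (smooth_sigma > 0) {
        f <- matrix(eval_model(kind, p, xg_full, yg_full), gd$dim[1], gd$dim[2])
        sep_filter(f, taps)[sup_cells] - zs
      } else {
        eval_model(kind, p, xs, ys) - zs
      }
    }
    minpack.lm::nls.lm(
      par = st, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = config$max_iter, ftol = config$tol, ptol = config$tol))
  }
  fit <- run(start)
  converged <- fit$info %in% 1:4
  if (!converged) {
    start2 <- start
    start2["theta"] <- wrap_half_pi(start["theta"] + pi / 4)
    fit2 <- run(start2)
    if (fit2$info %in% 1:4 && fit2$deviance < fit$deviance) {
      fit <- fit2
      converged <- TRUE
    }
  }

  params <- canonicalize_params(kind, as.list(fit$par))
  diam <- tryCatch(wheal_diameter(kind, params), error = function(e) NA_real_)
  fallback <- FALSE
  if (!converged || !is.finite(diam) ||
      diam < config$fallback_range_mm[1] || diam > config$fallback_range_mm[2]) {
    diam <- 2 * sqrt(2) * patch$source$scale_sigma
    fallback <- TRUE
    converged <- FALSE
  }
  rms <- if (smooth_sigma > 0) {
    f <- matrix(eval_model(kind, params, xg_full, yg_full), gd$dim[1], gd$dim[2])
    sqrt(mean((sep_filter(f, taps)[sup_cells] - zs)^2))
  } else {
    sqrt(mean((eval_model(kind, params, xs, ys) - zs)^2))
  }
  structure(
    list(model_kind = kind, params = params, diameter_mm = diam,
         rms_residual = rms, converged = converged,
         n_points = length(zs), fallback_used = fallback,
         centroid_global = patch$centroid_global, source = patch$source),
    class = "wheal_fit"
  )
}

# Elevated support for the paraboloid fit: points above the height fraction
# of the peak, dilated by one grid step (8-neighbourhood in mm).
paraboloid_support <- function(pts, peak, fraction) {
  el <- pts$z > fraction * peak
  if (!any(el)) return(el)
  step <- 1.5 * min(diff(sort(unique(pts$x))))
  sup <- el
  ex <- pts$x[el]; ey <- pts$y[el]
  for (i in which(!el)) {
    if (any(abs(ex - pts$x[i]) <= step & abs(ey - pts$y[i]) <= step)) sup[i] <- TRUE
  }
  sup
}

# Canonical form: larger width on the x axis (relabel + 90 degree rotation if
# needed), theta wrapped to [-pi/2, pi/2).
canonicalize_params <- function(kind, p) {
  p$theta <- wrap_half_pi(p$theta)
  wx_name <- if (kind == "paraboloid") "wx" else "sigma_x"
  wy_name <- if (kind == "paraboloid") "wy" else "sigma_y"
  if (p[[wx_name]] < p[[wy_name]]) {
    tmp <- p[[wx_name]]; p[[wx_name]] <- p[[wy_name]]; p[[wy_name]] <- tmp
    if (kind == "super_gaussian") {
      tmp <- p$beta_x; p$beta_x <- p$beta_y; p$beta_y <- tmp
    }
    tmp <- p$x0p; p$x0p <- p$y0p; p$y0p <- -tmp
    p$theta <- wrap_half_pi(p$theta + pi / 2)
  }
  p
}

#' @export
print.wheal_fit <- function(x, ...) {
  cat(sprintf("<wheal_fit> %s: d = %.2f mm, rms %.4f mm, %s%s\n",
              x$model_kind, x$diameter_mm, x$rms_residual,
              if (x$converged) "converged" else "not converged",
              if (x$fallback_used) " (fallback diameter)" else ""))
  invisible(x)
}

#' Tidy a fitted wheal model
#'
#' @param x A `wheal_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter (`term`, `estimate`).
#' @exportS3Method generics::tidy
tidy.wheal_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = as.numeric(unlist(x$params)))
}

#' One-row summary of a fitted wheal model
#'
#' @param x A `wheal_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model_kind`, `diameter_mm`, `rms_residual`,
#'   `converged`, `fallback_used`, `n_points`.
#' @exportS3Method generics::glance
glance.wheal_fit <- function(x, ...) {
  tibble::tibble(model_kind = x$model_kind, diameter_mm = x$diameter_mm,
                 rms_residual = x$rms_residual, converged = x$converged,
                 fallback_used = x$fallback_used, n_points = x$n_points)
}
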
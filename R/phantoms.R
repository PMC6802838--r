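#' Phantom forearm configuration
#'
#' Parameters of the synthetic forearm generator. Defaults emulate the
#' imaging conditions of a wide-field fringe-projection scan of the volar
#' forearm: a cylindrical arm of ~40 mm radius, wheals 3-12 mm across and
#' 0.1-0.5 mm high with flat-topped super-Gaussian profiles, fine skin
#' texture at sub-millimetre scales, and white sensor noise with SD 0.01 mm
#' (the depth accuracy of such systems).
#'
#' @param grid_shape Integer (rows, cols); default `c(900, 320)` pixels,
#'   i.e. 180 mm along the arm by 64 mm across at the default pitch (the
#'   grid must stay on the cylinder flank, so its width is below the arm
#'   diameter).
#' @param pitch Pixel pitch in mm (default 0.2).
#' @param arm_radius Cylinder radius in mm (default 40).
#' @param noise_sd White sensor-noise SD in mm (default 0.01).
#' @param texture_amplitude SD in mm of band-limited fine skin texture
#'   (pores, follicles, fine wrinkles) at scales the pyramid discards
#'   (default 0.02).
#' @param n_wheals Number of wheals (default 8).
#' @param diameter_range Wheal longest-diameter range in mm (default
#'   `c(3, 12)`).
#' @param height_range Wheal peak-height range in mm (default `c(0.1, 0.5)`).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(900, 320), pitch = 0.2,
                           arm_radius = 40, noise_sd = 0.01,
                           texture_amplitude = 0.02, n_wheals = 8,
                           diameter_range = c(3, 12),
                           height_range = c(0.1, 0.5)) {
  stopifnot(all(grid_shape >= 2), pitch > 0, arm_radius > 0,
            noise_sd >= 0, texture_amplitude >= 0, n_wheals >= 0,
            all(diameter_range > 0), all(height_range > 0))
  if (grid_shape[2] * pitch >= 2 * arm_radius)
    stop("grid width must be smaller than the arm diameter ",
         "(the surface must stay single-valued on the cylinder flank)")
  structure(
    list(grid_shape = as.integer(grid_shape), pitch = pitch,
         arm_radius = arm_radius, noise_sd = noise_sd,
         texture_amplitude = texture_amplitude, n_wheals = as.integer(n_wheals),
         diameter_range = diameter_range, height_range = height_range),
    class = "phantom_config"
  )
}

# Sample a wheal ground-truth table: centres with pairwise separation >= 15 mm
# and >= 10 mm border margin (margin may be length 2: across-arm x, along-arm
# y), longest diameters and heights uniform in the configured ranges, mild
# elongation, flat tops (exponents in [1, 3]).
sample_wheals <- function(config, min_sep = 15, margin = 10, max_tries = 5000L) {
  n <- config$n_wheals
  margin <- rep(margin, length.out = 2L)
  ext_x <- (config$grid_shape[2] - 1) * config$pitch
  ext_y <- (config$grid_shape[1] - 1) * config$pitch
  if (n == 0L) return(empty_wheals())
  if (ext_x <= 2 * margin[1] || ext_y <= 2 * margin[2])
    stop("grid too small for the border margin")
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("grid too small to place ", n, " wheals at ", min_sep,
           " mm separation")
    x <- stats::runif(1, margin[1], ext_x - margin[1])
    y <- stats::runif(1, margin[2], ext_y - margin[2])
    if (!length(xs) || all(sqrt((xs - x)^2 + (ys - y)^2) >= min_sep)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  d <- stats::runif(n, config$diameter_range[1], config$diameter_range[2])
  aspect <- stats::runif(n, 0.6, 1)
  tibble::tibble(
    id = seq_len(n), x = xs, y = ys,
    sigma_x = d / 4, sigma_y = aspect * d / 4,
    beta_x = stats::runif(n, 1, 3), beta_y = stats::runif(n, 1, 3),
    gamma = stats::runif(n, config$height_range[1], config$height_range[2]),
    theta = stats::runif(n, -pi / 2, pi / 2),
    true_diameter = d
  )
}

empty_wheals <- function() {
  tibble::tibble(id = integer(), x = double(), y = double(),
                 sigma_x = double(), sigma_y = double(),
                 beta_x = double(), beta_y = double(), gamma = double(),
                 theta = double(), true_diameter = double())
}

# Sum of super-Gaussian bumps over the grid (vectorized per wheal).
render_wheals <- function(wheals, xg, yg) {
  z <- matrix(0, length(yg), length(xg))
  if (nrow(wheals) == 0L) return(z)
  X <- matrix(xg, length(yg), length(xg), byrow = TRUE)
  Y <- matrix(yg, length(yg), length(xg))
  for (i in seq_len(nrow(wheals))) {
    w <- wheals[i, ]
    p <- list(x0p = 0, y0p = 0, sigma_x = w$sigma_x, sigma_y = w$sigma_y,
              beta_x = w$beta_x, beta_y = w$beta_y, gamma = w$gamma,
              theta = w$theta)
    z <- z + eval_model("super_gaussian", p, as.vector(X) - w$x,
                        as.vector(Y) - w$y)
  }
  z
}

#' Generate a synthetic forearm scan with known wheal ground truth
#'
#' The surface is a cylindrical section along the grid's long axis
#' (`z = sqrt(R^2 - (x - xc)^2) - R`, the global curvature to be removed),
#' plus a sum of super-Gaussian wheal bumps, band-limited fine texture and
#' white sensor noise. Bit-identical for equal seeds.
#'
#' @param config A [phantom_config()].
#' @param seed Integer RNG seed.
#' @param wheals Optional ground-truth wheal table (as returned in
#'   `$wheals`); when supplied it is rendered as-is instead of sampling a
#'   fresh set — used to re-render one wheal constellation under several
#'   poses.
#' @return A list with `field` (a [height_field()]) and `wheals` (tibble:
#'   `id`, `x`, `y` mm, `sigma_x`, `sigma_y`, `beta_x`, `beta_y`, `gamma`,
#'   `theta`, `true_diameter = max(4 sigma_x, 4 sigma_y)`).
#' @export
make_forearm <- function(config = phantom_config(), seed = 0L, wheals = NULL) {
  withr::with_seed(as.integer(seed), {
    if (is.null(wheals)) wheals <- sample_wheals(config)
    nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
    xg <- (seq_len(nc) - 1) * config$pitch
    yg <- (seq_len(nr) - 1) * config$pitch
    xc <- mean(range(xg))
    cyl <- sqrt(config$arm_radius^2 - (xg - xc)^2) - config$arm_radius
    z <- matrix(cyl, nr, nc, byrow = TRUE)
    z <- z + render_wheals(wheals, xg, yg)
    if (config$texture_amplitude > 0) {
      tex <- sep_filter(matrix(stats::rnorm(nr * nc), nr, nc),
                        gaussian_taps(0.75))
      z <- z + tex * (config$texture_amplitude / stats::sd(tex))
    }
    if (config$noise_sd > 0)
      z <- z + matrix(stats::rnorm(nr * nc, sd = config$noise_sd), nr, nc)
    list(field = height_field(z, pitch = config$pitch), wheals = wheals)
  })
}

#' Rigidly re-pose a wheal constellation
#'
#' Rotates the wheal centres in-plane about the constellation centroid and
#' translates them; each wheal's own orientation is rotated by the same
#' angle. Used to emulate placing the forearm at a different position and
#' orientation in the field of view.
#'
#' @param wheals Ground-truth wheal table (see [make_forearm()]).
#' @param dx,dy Translation in mm.
#' @param rot_deg In-plane rotation in degrees.
#' @return The transformed wheal table.
#' @export
transform_wheals <- function(wheals, dx = 0, dy = 0, rot_deg = 0) {
  if (nrow(wheals) == 0L) return(wheals)
  phi <- rot_deg * pi / 180
  cx <- mean(wheals$x); cy <- mean(wheals$y)
  xr <- cx + (wheals$x - cx) * cos(phi) - (wheals$y - cy) * sin(phi) + dx
  yr <- cy + (wheals$x - cx) * sin(phi) + (wheals$y - cy) * cos(phi) + dy
  out <- wheals
  out$x <- xr; out$y <- yr
  # grid-frame rotation by phi corresponds to shifting the model's clockwise
  # rotation parameter by -phi
  out$theta <- wrap_half_pi(wheals$theta - phi)
  out
}

#' Generate a grid of spherical-cap validation objects
#'
#' Each cap is a sphere section standing on the `z = 0` plane over a base
#' circle of the given diameter: with base radius `r` and cap height `h`,
#' the sphere radius is `R = (r^2 + h^2) / (2h)` (chord-sagitta relation)
#' and `z = sqrt(R^2 - rho^2) - (R - h)` for `rho <= r`, else 0.
#'
#' @param base_diameters Base-circle diameters in mm.
#' @param cap_height Cap height in mm (default 2).
#' @param pitch Pixel pitch in mm (default 0.1).
#' @param noise_sd White-noise SD in mm (default 0).
#' @param seed RNG seed (default 0).
#' @param centers Optional tibble/data frame with columns `x`, `y` (mm)
#'   giving the cap centres; defaults to a single row with generous margins.
#'   Overlapping caps are an error.
#' @return A list with `field` (a [height_field()]) and `caps` (tibble:
#'   `id`, `x`, `y`, `base_diameter`, `cap_height`, `sphere_radius`).
#' @export
make_spherical_caps <- function(base_diameters, cap_height = 2, pitch = 0.1,
                                noise_sd = 0, seed = 0L, centers = NULL) {
  stopifnot(all(base_diameters > 0), cap_height > 0, pitch > 0)
  n <- length(base_diameters)
  r_base <- base_diameters / 2
  margin <- 4
  if (is.null(centers)) {
    xs <- cumsum(c(margin + r_base[1],
                   if (n > 1) r_base[-n] + r_base[-1] + 2 * margin))
    # snap centres onto grid nodes so each cap peaks exactly at cap_height
    centers <- tibble::tibble(x = round(xs / pitch) * pitch,
                              y = round((margin + max(r_base)) / pitch) * pitch)
  }
  centers <- tibble::as_tibble(centers)
  if (nrow(centers) != n) stop("need one centre per cap")
  if (n > 1) {
    dd <- as.matrix(stats::dist(cbind(centers$x, centers$y)))
    rr <- outer(r_base, r_base, `+`)
    diag(dd) <- Inf
    if (any(dd <= rr)) stop("overlapping caps on the grid")
  }
  R <- (r_base^2 + cap_height^2) / (2 * cap_height)
  ext_x <- max(centers$x + r_base) + margin
  ext_y <- max(centers$y + r_base) + margin
  nc <- ceiling(ext_x / pitch) + 1L
  nr <- ceiling(ext_y / pitch) + 1L
  xg <- (seq_len(nc) - 1) * pitch
  yg <- (seq_len(nr) - 1) * pitch
  z <- matrix(0, nr, nc)
  X <- matrix(xg, nr, nc, byrow = TRUE)
  Y <- matrix(yg, nr, nc)
  for (i in seq_len(n)) {
    rho2 <- (X - centers$x[i])^2 + (Y - centers$y[i])^2
    inside <- rho2 <= r_base[i]^2
    z[inside] <- sqrt(R[i]^2 - rho2[inside]) - (R[i] - cap_height)
  }
  withr::with_seed(as.integer(seed), {
    if (noise_sd > 0) z <- z + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
  })
  list(field = height_field(z, pitch = pitch),
       caps = tibble::tibble(id = seq_len(n), x = centers$x, y = centers$y,
                             base_diameter = base_diameters,
                             cap_height = cap_height, sphere_radius = R))
}

#' Generate a staircase validation object
#'
#' Equal-width vertical bands (along columns) at the given heights, plus
#' white noise. The first height must be 0 (the reference band R0).
#'
#' @param step_heights Non-decreasing band heights in mm, first entry 0.
#' @param pitch Pixel pitch in mm (default 0.1).
#' @param noise_sd White-noise SD in mm (default 0).
#' @param seed RNG seed (default 0).
#' @param band_shape Integer (rows, cols) of each band in pixels (default
#'   `c(120, 60)`, i.e. 7200 cells per band).
#' @return A list with `field` (a [height_field()]) and `regions` (integer
#'   matrix of band labels `0..k`).
#' @export
make_steps <- function(step_heights, pitch = 0.1, noise_sd = 0, seed = 0L,
                       band_shape = c(120, 60)) {
  if (length(step_heights) < 2L) stop("need at least 2 steps")
  if (step_heights[1] != 0) stop("first step height must be 0 (reference R0)")
  if (is.unsorted(step_heights)) stop("step heights must be non-decreasing")
  k <- length(step_heights)
  nr <- band_shape[1]; nc <- band_shape[2] * k
  labels <- matrix(rep(seq_len(k) - 1L, each = band_shape[2]), nr, nc,
                   byrow = TRUE)
  z <- matrix(step_heights[labels + 1L], nr, nc)
  withr::with_seed(as.integer(seed), {
    if (noise_sd > 0) z <- z + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
  })
  list(field = height_field(z, pitch = pitch), regions = labels)
}

#' Measure a spherical cap's base diameter
#'
#' Least-squares sphere fit to the cells with height above 10% of the local
#' peak near `center_hint`, followed by intersection with the `z = 0` plane:
#' the reported base diameter is `2 * sqrt(R^2 - d0^2)` where `d0` is the
#' fitted centre's distance to the plane. Fitting a sphere (rather than
#' thresholding the footprint) keeps the estimate unbiased under noise.
#'
#' @param field A [height_field()] containing a cap-like region.
#' @param center_hint (x, y) position in mm near the cap centre.
#' @param window_mm Radius in mm of the search window around the hint
#'   (default 12).
#' @return Base-circle diameter in mm.
#' @export
measure_cap_diameter <- function(field, center_hint, window_mm = 12) {
  stopifnot_height_field(field)
  df <- as_tibble.height_field(field)
  inwin <- df$valid &
    (df$x - center_hint[1])^2 + (df$y - center_hint[2])^2 <= window_mm^2
  if (!any(inwin)) stop("no valid cells near the centre hint")
  peak <- max(df$z[inwin])
  if (!is.finite(peak) || peak - min(df$z[inwin]) < 0.05)
    stop("sphere fit ill-conditioned: no cap-like relief near the hint")
  # support: the connected elevated region containing the local peak, so a
  # neighbouring cap inside the window cannot contaminate the fit
  el <- matrix(FALSE, nrow(field$heights), ncol(field$heights))
  el[cbind(df$row[inwin], df$col[inwin])] <- df$z[inwin] > 0.1 * peak
  ipk <- which(inwin)[which.max(df$z[inwin])]
  comp <- flood_component(el, df$row[ipk], df$col[ipk])
  sup <- df[df$valid & as.vector(comp)[df$row + (df$col - 1L) * nrow(field$heights)], ]
  if (nrow(sup) < 20L) stop("sphere fit ill-conditioned: too few support cells")
  # algebraic sphere fit: x^2+y^2+z^2 = 2ax + 2by + 2cz + d
  A <- cbind(2 * sup$x, 2 * sup$y, 2 * sup$z, 1)
  b <- sup$x^2 + sup$y^2 + sup$z^2
  qr_A <- qr(A)
  if (qr_A$rank < 4L) stop("sphere fit ill-conditioned: rank-deficient system")
  coef <- qr.coef(qr_A, b)
  R2 <- coef[4] + coef[1]^2 + coef[2]^2 + coef[3]^2
  if (!is.finite(R2) || R2 <= coef[3]^2)
    stop("sphere fit ill-conditioned: no real intersection with z = 0")
  R <- sqrt(R2)
  if (R > 1e3) stop("sphere fit ill-conditioned: flat region")
  unname(2 * sqrt(R2 - coef[3]^2))
}

#' Measure staircase step heights relative to the reference band
#'
#' @param field A [height_field()] from [make_steps()].
#' @param regions Integer matrix of band labels; label 0 is the reference
#'   band R0.
#' @return Numeric vector: mean height of each non-reference band (in label
#'   order) minus the mean of R0.
#' @export
measure_step_heights <- function(field, regions) {
  stopifnot_height_field(field)
  if (!identical(dim(regions), dim(field$heights)))
    stop("`regions` must match the field's shape")
  labs <- sort(unique(as.vector(regions)))
  means <- vapply(labs, function(l) {
    sel <- regions == l & field$mask
    if (!any(sel)) stop("empty region: ", l)
    mean(field$heights[sel])
  }, 0)
  unname(means[-1] - means[1])
}
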
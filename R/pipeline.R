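#' Full pipeline configuration
#'
#' Bundles the pyramid, detection and fit settings with the clinical
#' positivity threshold.
#'
#' @param pyramid A [pyramid_config()].
#' @param detect A [detection_config()].
#' @param fit A [fit_config()].
#' @param positive_mm Positivity threshold on the longest diameter in mm
#'   (default 3, the standard SPT reading guideline). It is a report flag,
#'   not a filter: all detected wheals are reported, including sub-visual
#'   ones.
#' @param axial_background Subtract the running long-axis median from the
#'   band-passed surface before detection and fitting (default `TRUE`).
#'   Band-selective pyramid collapse keeps a smooth pedestal proportional to
#'   the local curvature of the arm's global shape; since the forearm is
#'   curved across its axis but nearly straight along it, that pedestal is
#'   close to constant along the arm and the per-position median (over the
#'   long axis) estimates it robustly while localized wheals leave it
#'   untouched.
#' @param verbose Emit one status line per pipeline stage (default `FALSE`).
#' @return An object of class `spt_config`.
#' @export
spt_config <- function(pyramid = pyramid_config(), detect = detection_config(),
                       fit = fit_config(), positive_mm = 3,
                       axial_background = TRUE, verbose = FALSE) {
  structure(
    list(pyramid = pyramid, detect = detect, fit = fit,
         positive_mm = positive_mm,
         axial_background = isTRUE(axial_background), verbose = isTRUE(verbose)),
    class = "spt_config"
  )
}

# Subtract the per-short-axis-position median over the long axis: the
# residual pedestal of the arm's curvature is axially near-constant.
remove_axial_background <- function(field) {
  h <- field$heights
  d <- dim(h)
  if (d[1] >= d[2]) {
    h <- h - rep(apply(h, 2, stats::median, na.rm = TRUE), each = d[1])
  } else {
    h <- h - apply(h, 1, stats::median, na.rm = TRUE)
  }
  height_field(h, pitch = field$pitch, origin = field$origin,
               mask = field$mask)
}

#' Measure all skin-prick-test wheals on a forearm height map
#'
#' Runs the full automated reading workflow: global-surface removal
#' (band-selective pyramid collapse), multi-scale LoG wheal detection, patch
#' extraction, centre-of-mass centering, bounded nonlinear least-squares
#' model fitting, and longest-diameter computation. Deterministic for a
#' fixed input and configuration. Candidates whose patch is degenerate are
#' dropped with a warning.
#'
#' @param S A [height_field()] of the forearm surface (mm).
#' @param config An [spt_config()]. `config$fit$model = "both"` fits both
#'   parametric models to every wheal, producing paired rows.
#' @return A tibble of class `spt_measurements`, one row per wheal (and per
#'   model in `"both"` mode): `id`, `x_mm`, `y_mm` (fitted centre, global
#'   frame), `diameter_mm`, `model`, `positive` (`diameter_mm >=
#'   positive_mm`), `rms_residual`, `converged`, `fallback_used`,
#'   `scale_sigma`, `response`, `clipped`.
#' @export
measure_spt <- function(S, config = spt_config()) {
  stopifnot_height_field(S)
  say <- function(fmt, ...) if (config$verbose) message(sprintf(fmt, ...))
  t0 <- proc.time()[3]
  S_prime <- remove_global_surface(S, config$pyramid)
  if (config$axial_background) S_prime <- remove_axial_background(S_prime)
  say("surface_removal: %dx%d px, %.2fs", nrow(S$heights), ncol(S$heights),
      proc.time()[3] - t0)

  t1 <- proc.time()[3]
  cands <- detect_wheals(S_prime, config$detect)
  say("detection: %d candidates, %.2fs", nrow(cands), proc.time()[3] - t1)

  patches <- extract_patches(S_prime, cands, config$detect)
  models <- if (config$fit$model == "both") c("paraboloid", "super_gaussian")
            else config$fit$model
  fit_cfg <- config$fit
  if (is.null(fit_cfg$smoothing_sigma))
    fit_cfg$smoothing_sigma <- pyramid_cut_sigma(config$pyramid, S$pitch)

  t2 <- proc.time()[3]
  rows <- list()
  next_id <- 1L
  for (patch in patches) {
    cp <- tryCatch(center_patch(patch), error = function(e) {
      warning("dropping candidate at (",
              sprintf("%.1f, %.1f", patch$source$x_mm, patch$source$y_mm),
              ") mm: ", conditionMessage(e))
      NULL
    })
    if (is.null(cp)) next
    # the detected scale underestimates large band-passed wheals; once the
    # bump extent is known, re-cut the window to ~2x the measured radius so
    # the fit sees both the whole bump and enough background
    cp <- tryCatch(adapt_patch_window(S_prime, cp), error = function(e) cp)
    for (kind in models) {
      fit <- tryCatch(fit_wheal(cp, kind, fit_cfg), error = function(e) {
        warning("fit failed for candidate at (",
                sprintf("%.1f, %.1f", patch$source$x_mm, patch$source$y_mm),
                ") mm: ", conditionMessage(e))
        NULL
      })
      if (is.null(fit)) next
      ctr <- fitted_center_global(fit)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = next_id, x_mm = ctr[1], y_mm = ctr[2],
        diameter_mm = fit$diameter_mm, model = fit$model_kind,
        positive = fit$diameter_mm >= config$positive_mm,
        rms_residual = fit$rms_residual, converged = fit$converged,
        fallback_used = fit$fallback_used,
        scale_sigma = patch$source$scale_sigma,
        response = patch$source$response, clipped = patch$clipped
      )
    }
    next_id <- next_id + 1L
  }
  say("fitting: %d wheals x %d model(s), %.2fs", next_id - 1L, length(models),
      proc.time()[3] - t2)
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    id = integer(), x_mm = double(), y_mm = double(), diameter_mm = double(),
    model = character(), positive = logical(), rms_residual = double(),
    converged = logical(), fallback_used = logical(), scale_sigma = double(),
    response = double(), clipped = logical())
  class(out) <- c("spt_measurements", class(out))
  out
}

# Re-extract the patch if the measured bump shoulder (cells above 30% of the
# peak) comes close to the window edge: target half-width = 2.6x the
# shoulder radius (so the fit sees ample zero background around the bump),
# floored at 5 mm and capped at 14 mm.
adapt_patch_window <- function(S_prime, cp) {
  pts <- cp$points_centered
  sh <- pts$z > 0.3 * cp$peak
  if (!any(sh)) return(cp)
  r30 <- stats::quantile(sqrt(pts$x[sh]^2 + pts$y[sh]^2), 0.98)
  want <- min(max(2.6 * r30, 5), 14)
  half_now <- max(abs(c(pts$x, pts$y)))
  if (half_now >= 0.95 * want) return(cp)
  hw <- as.integer(round(want / S_prime$pitch))
  center_patch(cut_patch(S_prime, cp$source, hw))
}

# Fitted centre mapped back from the rotated patch frame to global mm.
fitted_center_global <- function(fit) {
  p <- fit$params
  x <- p$x0p * cos(p$theta) + p$y0p * sin(p$theta)
  y <- -p$x0p * sin(p$theta) + p$y0p * cos(p$theta)
  c(fit$centroid_global[1] + x, fit$centroid_global[2] + y)
}

#' Coefficient of variation of repeated measurements
#'
#' `CV = 100 * SD / mean`, with the unbiased (n-1 denominator) standard
#' deviation — the reproducibility statistic used for repeated wheal
#' diameter estimates.
#'
#' @param values Numeric vector of at least 2 measurements with non-zero
#'   mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined")
  100 * stats::sd(values) / m
}

#' Limits of agreement from a mean difference and SD
#'
#' The Bland-Altman 95% limits: `mean_diff -/+ 1.96 * sd`.
#'
#' @param mean_diff Mean paired difference (mm).
#' @param sd Standard deviation of the paired differences (mm); must be
#'   non-negative.
#' @return Numeric length-2 `c(low, high)`.
#' @export
limits_of_agreement <- function(mean_diff, sd) {
  if (sd < 0) stop("`sd` must be non-negative")
  c(low = mean_diff - 1.96 * sd, high = mean_diff + 1.96 * sd)
}

#' Bland-Altman agreement between reference and estimated diameters
#'
#' Paired differences are computed as `reference - estimated`, so a negative
#' mean difference means the estimates exceed the reference on average.
#' Reports the mean difference, its unbiased SD, and the 1.96-SD limits of
#' agreement.
#'
#' @param reference,estimated Equal-length numeric vectors (mm), length >= 2.
#' @return An object of class `spt_agreement` with fields `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n`, plus the per-pair `differences`
#'   and pair `means`.
#' @export
agreement_stats <- function(reference, estimated) {
  if (length(reference) != length(estimated))
    stop("`reference` and `estimated` must have equal length")
  if (length(reference) < 2L) stop("need at least 2 pairs")
  d <- reference - estimated
  md <- mean(d); sdd <- stats::sd(d)
  loa <- limits_of_agreement(md, sdd)
  structure(
    list(mean_diff = md, sd_diff = sdd,
         loa_low = unname(loa[1]), loa_high = unname(loa[2]),
         n = length(d), differences = d, means = (reference + estimated) / 2),
    class = "spt_agreement"
  )
}

#' @export
print.spt_agreement <- function(x, ...) {
  cat(sprintf(
    "<spt_agreement> n = %d: mean diff %.3f mm (SD %.3f); 95%% LoA [%.2f, %.2f] mm\n",
    x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Tidy per-pair Bland-Altman data
#'
#' @param x An `spt_agreement`.
#' @param ... Unused.
#' @return A tibble with one row per pair: `mean` and `difference` (mm).
#' @exportS3Method generics::tidy
tidy.spt_agreement <- function(x, ...) {
  tibble::tibble(mean = x$means, difference = x$differences)
}

#' One-row agreement summary
#'
#' @param x An `spt_agreement`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`.
#' @exportS3Method generics::glance
glance.spt_agreement <- function(x, ...) {
  tibble::tibble(n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high)
}

#' Bland-Altman plot
#'
#' @param object An `spt_agreement`.
#' @param ... Unused.
#' @return A ggplot object: per-pair differences against pair means with the
#'   mean difference and 95% limits of agreement.
#' @exportS3Method ggplot2::autoplot
autoplot.spt_agreement <- function(object, ...) {
  df <- tidy.spt_agreement(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of methods (mm)",
                  y = "reference - estimate (mm)")
}

#' Ratio statistics between two sets of diameters
#'
#' Mean, SD and CV of the per-wheal ratio `reference / estimated`.
#'
#' @param reference,estimated Equal-length numeric vectors (mm).
#' @return A one-row tibble: `mean_ratio`, `sd_ratio`, `cv_pct`, `n`.
#' @export
ratio_stats <- function(reference, estimated) {
  if (length(reference) != length(estimated))
    stop("`reference` and `estimated` must have equal length")
  r <- reference / estimated
  tibble::tibble(mean_ratio = mean(r), sd_ratio = stats::sd(r),
                 cv_pct = coefficient_of_variation(r), n = length(r))
}

#' Overlay measured wheals on a height map
#'
#' @param field The [height_field()] that was measured (raw or band-passed).
#' @param measurements An `spt_measurements` tibble from [measure_spt()].
#' @return A ggplot object: elevation raster with one circle of the fitted
#'   diameter per wheal.
#' @export
plot_wheals <- function(field, measurements) {
  p <- autoplot.height_field(field)
  if (nrow(measurements) == 0L) return(p)
  ang <- seq(0, 2 * pi, length.out = 90)
  circ <- tidyr::crossing(measurements, tibble::tibble(.ang = ang)) |>
    dplyr::mutate(cx = .data$x_mm + .data$diameter_mm / 2 * cos(.data$.ang),
                  cy = .data$y_mm + .data$diameter_mm / 2 * sin(.data$.ang))
  p + ggplot2::geom_path(
    data = circ, inherit.aes = FALSE,
    ggplot2::aes(x = .data$cx, y = .data$cy,
                 group = interaction(.data$id, .data$model)),
    colour = "red")
}
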
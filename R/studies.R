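#' Re-posing reproducibility study on a synthetic forearm
#'
#' Samples one wheal constellation, renders it under several rigid poses
#' (in-plane rotation of the constellation, translation along and across
#' the arm, fresh sensor-noise draws), runs the full measurement pipeline on
#' each pose, matches measurements back to ground truth in the reference
#' frame, and reports the per-wheal coefficient of variation of the
#' estimated diameters across poses.
#'
#' @param config A [phantom_config()] (sets grid, wheal count and ranges).
#' @param seed Integer seed; drives the constellation, the poses and the
#'   per-pose noise.
#' @param n_poses Number of poses (default 5).
#' @param max_shift_mm Length-2 maximum absolute translation in mm along the
#'   arm and across it (default `c(20, 6)`; the across-arm headroom is
#'   limited by the grid staying on the cylinder flank).
#' @param max_rot_deg Maximum absolute in-plane rotation in degrees
#'   (default 10).
#' @param spt An [spt_config()] used for the per-pose measurement.
#' @param match_radius_mm Centre-matching radius in mm (default 2).
#' @return A list: `per_wheal` (tibble `id`, `true_diameter`, `n_poses`,
#'   `mean_diameter`, `sd_diameter`, `cv_pct`), `measurements` (all matched
#'   per-pose rows), `wheals` (the base ground truth).
#' @export
pose_reproducibility <- function(config = phantom_config(n_wheals = 6,
                                                         diameter_range = c(4, 11)),
                                 seed = 0L, n_poses = 5,
                                 max_shift_mm = c(20, 6), max_rot_deg = 10,
                                 spt = spt_config(),
                                 match_radius_mm = 2) {
  # placement margins leave room for the rigid pose sweep: across the arm for
  # the translation plus the rotation of the along-arm extent, along the arm
  # for the translation plus a small rotation allowance
  ext_x <- (config$grid_shape[2] - 1) * config$pitch
  ext_y <- (config$grid_shape[1] - 1) * config$pitch
  phi <- max_rot_deg * pi / 180
  my <- 10 + max_shift_mm[1] + 4
  mx <- 10 + max_shift_mm[2] + sin(phi) * (ext_y / 2 - my) + 1
  if (2 * mx >= ext_x || 2 * my >= ext_y)
    stop("grid too small for the requested pose sweep")
  draws <- withr::with_seed(as.integer(seed), {
    base <- sample_wheals(config, margin = c(mx, my))
    list(
      base = base,
      dx_arm = stats::runif(n_poses, -max_shift_mm[1], max_shift_mm[1]),
      dx_across = stats::runif(n_poses, -max_shift_mm[2], max_shift_mm[2]),
      rot = stats::runif(n_poses, -max_rot_deg, max_rot_deg),
      noise_seeds = sample.int(.Machine$integer.max - 1L, n_poses)
    )
  })
  base <- draws$base
  all_rows <- list()
  for (p in seq_len(n_poses)) {
    posed <- transform_wheals(base, dx = draws$dx_across[p],
                              dy = draws$dx_arm[p], rot_deg = draws$rot[p])
    scan <- make_forearm(config, seed = draws$noise_seeds[p], wheals = posed)
    meas <- measure_spt(scan$field, spt)
    if (nrow(meas) == 0L) next
    idx <- match_centers(meas$x_mm, meas$y_mm, posed$x, posed$y,
                         match_radius_mm)
    meas$true_id <- posed$id[idx]
    meas$pose <- p
    all_rows[[p]] <- meas[!is.na(meas$true_id), ]
  }
  matched <- dplyr::bind_rows(all_rows)
  per_wheal <- matched |>
    dplyr::group_by(.data$true_id, .data$model) |>
    dplyr::summarise(
      n_poses = dplyr::n(),
      mean_diameter = mean(.data$diameter_mm),
      sd_diameter = stats::sd(.data$diameter_mm),
      cv_pct = coefficient_of_variation(.data$diameter_mm),
      .groups = "drop") |>
    dplyr::rename(id = "true_id") |>
    dplyr::left_join(base[, c("id", "true_diameter")], by = "id") |>
    dplyr::relocate("id", "true_diameter")
  list(per_wheal = per_wheal, measurements = matched, wheals = base)
}

# Nearest-truth matching within a radius; NA where no truth centre is close
# enough. One-to-one is not enforced (duplicates are rare at wheal spacing).
match_centers <- function(x, y, tx, ty, radius) {
  vapply(seq_along(x), function(i) {
    d2 <- (tx - x[i])^2 + (ty - y[i])^2
    j <- which.min(d2)
    if (length(j) && d2[j] <= radius^2) j else NA_integer_
  }, integer(1))
}

#' Detector recall and precision over seeded phantom fields
#'
#' Generates a batch of synthetic forearm fields with known wheal centres,
#' runs surface removal and blob detection on each, and scores the detected
#' candidates against ground truth by centre distance.
#'
#' @param n_fields Number of phantom fields.
#' @param config A [phantom_config()] template; the wheal count per field is
#'   drawn uniformly from `n_wheals_range`.
#' @param n_wheals_range Integer range of wheals per field (default
#'   `c(4, 8)`).
#' @param seed Integer seed.
#' @param pyramid,detect Pipeline stage configurations.
#' @param match_radius_mm Centre-matching radius in mm (default 2).
#' @return A one-row tibble: `n_fields`, `n_true`, `n_detected`,
#'   `true_positives`, `recall`, `precision`.
#' @export
detection_performance <- function(n_fields = 200,
                                  config = phantom_config(),
                                  n_wheals_range = c(4, 8),
                                  seed = 0L,
                                  pyramid = pyramid_config(),
                                  detect = detection_config(),
                                  match_radius_mm = 2) {
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L, n_fields + 1L))
  n_per <- withr::with_seed(seeds[n_fields + 1L],
                            sample(n_wheals_range[1]:n_wheals_range[2],
                                   n_fields, replace = TRUE))
  n_true <- 0L; n_det <- 0L; tp <- 0L
  for (i in seq_len(n_fields)) {
    cfg_i <- config
    cfg_i$n_wheals <- n_per[i]
    scan <- make_forearm(cfg_i, seed = seeds[i])
    sp <- remove_global_surface(scan$field, pyramid)
    cands <- detect_wheals(sp, detect)
    n_true <- n_true + nrow(scan$wheals)
    n_det <- n_det + nrow(cands)
    if (nrow(cands)) {
      idx <- match_centers(cands$x_mm, cands$y_mm, scan$wheals$x,
                           scan$wheals$y, match_radius_mm)
      # count each true wheal at most once
      tp <- tp + length(unique(idx[!is.na(idx)]))
    }
  }
  tibble::tibble(n_fields = n_fields, n_true = n_true, n_detected = n_det,
                 true_positives = tp,
                 recall = tp / n_true, precision = tp / n_det)
}
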
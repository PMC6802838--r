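test_that("reduce preserves constants, halves sizes with the ceil convention", {
  cfg <- pyramid_config()
  r <- pyramid_reduce(matrix(3, 8, 8), cfg)
  expect_equal(dim(r), c(4L, 4L))
  expect_equal(max(abs(r - 3)), 0, tolerance = 1e-12)
  expect_equal(ncol(pyramid_reduce(matrix(0, 8, 257), cfg)), 129L)
  expect_error(pyramid_reduce(matrix(1, 1, 5), cfg), "2x2")
})

test_that("reduce and expand match the brute-force direct-convolution oracle", {
  cfg <- pyramid_config()
  set.seed(11)
  for (dims in list(c(8, 8), c(9, 13), c(16, 10))) {
    m <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    expect_equal(pyramid_reduce(m, cfg),
                 oracle_reduce(m, cfg$reduce_kernel, "linear"),
                 tolerance = 1e-12)
    cm <- pyramid_reduce(m, cfg)
    expect_equal(pyramid_expand(cm, dims, cfg),
                 oracle_expand(cm, dims, cfg$expand_kernel, "linear"),
                 tolerance = 1e-12)
  }
  # impulse through reduce equals direct convolution + decimation
  imp <- matrix(0, 8, 8); imp[4, 5] <- 1
  expect_equal(pyramid_reduce(imp, cfg),
               oracle_reduce(imp, cfg$reduce_kernel, "linear"),
               tolerance = 1e-14)
})

test_that("symmetric-reflection border mode also matches its oracle", {
  cfg <- pyramid_config(border = "reflect")
  set.seed(12)
  m <- matrix(rnorm(9 * 11), 9, 11)
  expect_equal(pyramid_reduce(m, cfg),
               oracle_reduce(m, cfg$reduce_kernel, "reflect"),
               tolerance = 1e-12)
})

test_that("expand preserves constants and hits exact odd target shapes", {
  cfg <- pyramid_config()
  e <- pyramid_expand(matrix(2.5, 5, 5), c(9, 9), cfg)
  expect_equal(dim(e), c(9L, 9L))
  expect_equal(max(abs(e - 2.5)), 0, tolerance = 1e-12)
  expect_error(pyramid_expand(matrix(0, 5, 5), c(12, 9), cfg), "compatible")
})

test_that("expand(reduce(.)) closely reproduces a band-limited field", {
  cfg <- pyramid_config()
  g <- seq(0, 1, length.out = 64)
  m <- outer(sin(2 * pi * g), cos(2 * pi * g)) # one cycle across: far below Nyquist/2
  rec <- pyramid_expand(pyramid_reduce(m, cfg), dim(m), cfg)
  expect_lt(sqrt(mean((rec - m)^2)) / sqrt(mean(m^2)), 0.05)
})

test_that("decompose yields the documented level shapes and constant-field details", {
  cfg <- pyramid_config()
  hf <- height_field(matrix(7.25, 256, 256), pitch = 0.2)
  pyr <- pyramid_decompose(hf, cfg)
  expect_equal(vapply(pyr$level_shapes, `[`, 0L, 1), c(256L, 128L, 64L, 32L, 16L, 8L, 4L, 2L))
  for (l in 0:6) expect_lt(max(abs(pyr$laplacian_levels[[l + 1]])), 1e-9)
  expect_equal(max(abs(pyr$laplacian_levels[[8]] - 7.25)), 0, tolerance = 1e-9)
})

test_that("small grids lower the level count with a warning", {
  hf <- height_field(matrix(rnorm(40 * 40), 40), pitch = 0.2)
  expect_warning(pyr <- pyramid_decompose(hf, pyramid_config(n_levels = 7)),
                 "too small")
  expect_equal(pyr$n_levels, 5L)
})

test_that("perfect reconstruction: collapsing all levels reproduces the input", {
  set.seed(21)
  hf <- height_field(matrix(rnorm(256 * 256), 256), pitch = 0.2)
  pyr <- pyramid_decompose(hf)
  rec <- pyramid_collapse(pyr, 0:7)
  expect_lt(max(abs(rec$heights - hf$heights)), 1e-9)
  # and on a non-power-of-two grid
  hf2 <- height_field(matrix(rnorm(200 * 175), 200), pitch = 0.3)
  rec2 <- pyramid_collapse(pyramid_decompose(hf2), 0:7)
  expect_lt(max(abs(rec2$heights - hf2$heights)), 1e-9)
})

test_that("keeping no levels returns a zero field; band energy is monotone", {
  set.seed(22)
  hf <- height_field(matrix(rnorm(128 * 128), 128), pitch = 0.2)
  pyr <- pyramid_decompose(hf)
  expect_equal(max(abs(pyramid_collapse(pyr, integer(0))$heights)), 0)
  energy <- function(keep) sum(pyramid_collapse(pyr, keep)$heights^2)
  # adding detail levels grows the reconstructed energy (near-orthogonal
  # bands); the terminal residual level is excluded: it is anti-correlated
  # with the detail sum by construction (L6 subtracts the expanded G7), so
  # completing the set can lower the energy while restoring the input
  keeps <- list(integer(0), 2L, c(2L, 3L), 2:4, 2:5, c(0L, 2:5), 0:6)
  e <- vapply(keeps, energy, 0)
  expect_true(all(diff(e) >= -1e-9))
  expect_equal(energy(0:7), sum(hf$heights^2), tolerance = 1e-9)
})

test_that("band-selective collapse removes a plane and keeps a wheal-scale bump", {
  pitch <- 0.2
  n <- 256
  g <- (seq_len(n) - 1) * pitch
  plane <- outer(rep(1, n), 0.05 * g) + 0.3
  bump <- 0.3 * exp(-(outer((g - 25)^2, (g - 25)^2, `+`)) / (2 * 1.5^2))
  hf_plane <- height_field(plane, pitch)
  hf_both <- height_field(plane + bump, pitch)
  sp_plane <- pyramid_collapse(pyramid_decompose(hf_plane), 2:5)
  sp_both <- pyramid_collapse(pyramid_decompose(hf_both), 2:5)
  # plane attenuated by far more than 95% in RMS
  expect_lt(sqrt(mean(sp_plane$heights^2)) / sqrt(mean(plane^2)), 0.05)
  # bump peak retained within [60%, 100%]
  peak <- max(sp_both$heights - sp_plane$heights)
  expect_gt(peak, 0.6 * 0.3)
  expect_lt(peak, 1.0 * 0.3 + 1e-9)
})

test_that("remove_global_surface is linear and maps zero to zero", {
  set.seed(23)
  pitch <- 0.2
  m1 <- matrix(rnorm(128 * 140), 128)
  m2 <- matrix(rnorm(128 * 140), 128)
  f <- function(m) remove_global_surface(height_field(m, pitch))$heights
  lhs <- f(2 * m1 - 0.5 * m2)
  rhs <- 2 * f(m1) - 0.5 * f(m2)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  expect_equal(max(abs(f(matrix(0, 130, 130)))), 0)
})

test_that("the arm cylinder is fully removed once the axial background is taken out", {
  cfg <- phantom_config(n_wheals = 0, noise_sd = 0, texture_amplitude = 0)
  scan <- make_forearm(cfg, seed = 1)
  sp <- sptread:::remove_axial_background(remove_global_surface(scan$field))
  expect_lt(sqrt(mean(sp$heights^2)), 0.02)
})

test_that("band-passed surface of cylinder + wheals shows exactly the wheal maxima", {
  wh <- tibble::tibble(
    id = 1:4, x = c(20, 44, 20, 44), y = c(40, 70, 100, 140),
    sigma_x = c(1.2, 1.5, 2, 2.5), sigma_y = c(1, 1.4, 1.8, 2),
    beta_x = 2, beta_y = 2, gamma = c(0.2, 0.3, 0.4, 0.25),
    theta = 0, true_diameter = c(4.8, 6, 8, 10))
  cfg <- phantom_config(n_wheals = 4, noise_sd = 0, texture_amplitude = 0)
  scan <- make_forearm(cfg, seed = 1, wheals = wh)
  sp <- sptread:::remove_axial_background(remove_global_surface(scan$field))
  h <- sp$heights
  # strict interior local maxima above 0.05 mm
  nr <- nrow(h); nc <- ncol(h)
  core <- h[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > 0.05
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & core > h[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  expect_equal(sum(is_max), 4L)
})

test_that("masked cells are infilled for decomposition and stay masked after", {
  set.seed(25)
  m <- matrix(rnorm(130 * 130, sd = 0.05), 130)
  m[60:64, 70:74] <- NA
  hf <- height_field(m, 0.2)
  sp <- remove_global_surface(hf)
  expect_identical(sp$mask, hf$mask)
  expect_true(all(is.na(sp$heights[!sp$mask])))
  expect_true(all(is.finite(sp$heights[sp$mask])))
})
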
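test_that("a wheal-free noiseless phantom is the exact analytic cylinder", {
  cfg <- phantom_config(grid_shape = c(200, 150), n_wheals = 0,
                        noise_sd = 0, texture_amplitude = 0)
  scan <- make_forearm(cfg, seed = 3)
  xg <- (seq_len(150) - 1) * cfg$pitch
  xc <- mean(range(xg))
  cyl <- sqrt(cfg$arm_radius^2 - (xg - xc)^2) - cfg$arm_radius
  expect_lt(max(abs(sweep(scan$field$heights, 2, cyl))), 1e-12)
})

test_that("the forearm generator is bit-identical for equal seeds", {
  cfg <- phantom_config(grid_shape = c(300, 200), n_wheals = 3)
  a <- make_forearm(cfg, seed = 9)
  b <- make_forearm(cfg, seed = 9)
  expect_identical(a$field$heights, b$field$heights)
  expect_identical(as.data.frame(a$wheals), as.data.frame(b$wheals))
  c_ <- make_forearm(cfg, seed = 10)
  expect_false(identical(a$field$heights, c_$field$heights))
})

test_that("ground truth is self-consistent: each wheal peaks at gamma on grid", {
  cfg <- phantom_config(n_wheals = 8, noise_sd = 0, texture_amplitude = 0)
  scan <- make_forearm(cfg, seed = 0)
  w <- scan$wheals
  expect_equal(nrow(w), 8L)
  expect_equal(w$true_diameter, pmax(4 * w$sigma_x, 4 * w$sigma_y))
  # every true centre has a grid cell within pitch/2
  col <- round(w$x / cfg$pitch) + 1
  row <- round(w$y / cfg$pitch) + 1
  expect_lt(max(abs((col - 1) * cfg$pitch - w$x)), cfg$pitch / 2 + 1e-12)
  # summed bump height at each centre equals gamma (tails of neighbours at
  # >= 15 mm separation are negligible)
  bumps <- sptread:::render_wheals(w, (seq_len(cfg$grid_shape[2]) - 1) * cfg$pitch,
                                   (seq_len(cfg$grid_shape[1]) - 1) * cfg$pitch)
  at_centers <- vapply(seq_len(nrow(w)), function(i) {
    p <- list(x0p = 0, y0p = 0, sigma_x = w$sigma_x[i], sigma_y = w$sigma_y[i],
              beta_x = w$beta_x[i], beta_y = w$beta_y[i], gamma = w$gamma[i],
              theta = w$theta[i])
    bumps[row[i], col[i]] - eval_model("super_gaussian", p,
                                       (col[i] - 1) * cfg$pitch - w$x[i],
                                       (row[i] - 1) * cfg$pitch - w$y[i])
  }, 0)
  expect_lt(max(abs(at_centers)), 1e-9)
})

test_that("wheal placement respects separation and margins or fails loudly", {
  cfg <- phantom_config(n_wheals = 6)
  w <- withr::with_seed(4, sptread:::sample_wheals(cfg))
  dd <- as.matrix(dist(cbind(w$x, w$y))); diag(dd) <- Inf
  expect_gte(min(dd), 15)
  expect_gte(min(w$x), 10); expect_gte(min(w$y), 10)
  tiny <- phantom_config(grid_shape = c(150, 150), n_wheals = 10)
  expect_error(withr::with_seed(1, sptread:::sample_wheals(tiny)), "grid too small")
})

test_that("spherical caps follow the chord-sagitta geometry", {
  caps <- make_spherical_caps(9.08, cap_height = 2, pitch = 0.1)
  # implied sphere radius R = (r^2 + h^2) / (2h)
  expect_equal(caps$caps$sphere_radius, (4.54^2 + 2^2) / (2 * 2))
  expect_equal(caps$caps$sphere_radius, 6.1529, tolerance = 1e-4)
  # peak height exactly the cap height at the centre cell
  ctr <- c(round(caps$caps$y / 0.1) + 1, round(caps$caps$x / 0.1) + 1)
  expect_equal(caps$field$heights[ctr[1], ctr[2]], 2, tolerance = 1e-9)
  # footprint: cells above zero form a disc of the base radius
  df <- as_tibble(caps$field)
  on <- df[df$z > 0, ]
  rr <- sqrt((on$x - caps$caps$x)^2 + (on$y - caps$caps$y)^2)
  expect_lt(max(rr), 4.54 + 0.1)
  expect_gt(max(rr), 4.54 - 0.1)
  expect_error(
    make_spherical_caps(c(8, 8), centers = tibble::tibble(x = c(10, 15), y = 10)),
    "overlapping")
})

test_that("cap diameters are recovered to hundredths of a mm without noise", {
  for (d in c(9.08, 5.50)) {
    caps <- make_spherical_caps(d, cap_height = 2, pitch = 0.1, noise_sd = 0)
    est <- measure_cap_diameter(caps$field, c(caps$caps$x, caps$caps$y))
    expect_lt(abs(est - d), 0.02)
  }
  flat <- height_field(matrix(0, 100, 100), 0.1)
  expect_error(measure_cap_diameter(flat, c(5, 5)), "ill-conditioned")
})

test_that("staircase heights and their averaging behave as constructed", {
  st <- make_steps(c(0, 0.1, 0.2, 0.3), pitch = 0.1)
  expect_equal(measure_step_heights(st$field, st$regions), c(0.1, 0.2, 0.3))
  # with noise, band means of >= 5000 cells are accurate to ~1e-3 mm
  stn <- make_steps(c(0, 0.1, 0.2, 0.3), pitch = 0.1, noise_sd = 0.01,
                    seed = 5, band_shape = c(120, 60))
  expect_equal(prod(c(120, 60)), 7200)
  h <- measure_step_heights(stn$field, stn$regions)
  expect_lt(max(abs(h - c(0.1, 0.2, 0.3))), 0.001)
  # empirical SE of a band mean matches 0.01 / sqrt(n)
  b0 <- stn$field$heights[stn$regions == 0]
  expect_equal(sd(b0) / sqrt(length(b0)), 0.01 / sqrt(7200), tolerance = 0.05)
  # determinism and label-order (not spatial-order) reporting
  st2 <- make_steps(c(0, 0.1, 0.2, 0.3), pitch = 0.1, noise_sd = 0.01, seed = 5)
  expect_identical(stn$field$heights, st2$field$heights)
  perm <- stn$regions
  perm[stn$regions == 1L] <- 3L
  perm[stn$regions == 3L] <- 1L
  hp <- measure_step_heights(stn$field, perm)
  expect_equal(hp, h[c(3, 2, 1)], tolerance = 1e-12)
  expect_error(make_steps(0.1), "at least 2")
  expect_error(make_steps(c(0.05, 0.1)), "must be 0")
})

test_that("transform_wheals applies a rigid motion about the centroid", {
  w <- tibble::tibble(id = 1:2, x = c(10, 20), y = c(10, 10),
                      sigma_x = 1, sigma_y = 1, beta_x = 1, beta_y = 1,
                      gamma = 0.2, theta = 0, true_diameter = 4)
  t1 <- transform_wheals(w, dx = 3, dy = -2, rot_deg = 90)
  # pairwise distance preserved
  expect_equal(sqrt(diff(t1$x)^2 + diff(t1$y)^2), 10)
  # centroid translated by (dx, dy)
  expect_equal(c(mean(t1$x), mean(t1$y)), c(15 + 3, 10 - 2))
  # wheal orientation follows the scene rotation
  expect_equal(t1$theta, sptread:::wrap_half_pi(w$theta - pi / 2))
})
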
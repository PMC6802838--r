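sg_params <- function(x0p = 0, y0p = 0, sigma_x = 1.25, sigma_y = 1,
                      beta_x = 1.5, beta_y = 1.5, gamma = 0.3, theta = 0) {
  list(x0p = x0p, y0p = y0p, sigma_x = sigma_x, sigma_y = sigma_y,
       beta_x = beta_x, beta_y = beta_y, gamma = gamma, theta = theta)
}

pb_params <- function(x0p = 0, y0p = 0, wx = 1, wy = 1, c = 1, beta = 1,
                      theta = 0) {
  list(x0p = x0p, y0p = y0p, wx = wx, wy = wy, c = c, beta = beta,
       theta = theta)
}

test_that("model evaluation matches closed forms at special points", {
  p <- sg_params(sigma_x = 1.2, sigma_y = 1.2, beta_x = 1, beta_y = 1,
                 gamma = 0.4)
  expect_equal(eval_model("super_gaussian", p, 0, 0), 0.4)
  # isotropic Gaussian at r = 2 sigma: gamma e^-2
  expect_equal(eval_model("super_gaussian", p, 2 * 1.2, 0), 0.4 * exp(-2))
  expect_equal(eval_model("super_gaussian", p, 0, 2 * 1.2), 0.4 * exp(-2))

  q <- pb_params(wx = 1.3, wy = 0.9, c = 2, beta = 0.25)
  expect_equal(eval_model("paraboloid", q, 0, 0), 0.25)
  a <- q$wx * sqrt(q$beta * q$c)
  expect_equal(eval_model("paraboloid", q, a, 0), 0, tolerance = 1e-12)
  # against the independent oracle on a grid of points
  set.seed(41)
  xs <- rnorm(50); ys <- rnorm(50)
  p2 <- sg_params(sigma_x = 2, sigma_y = 1.1, beta_x = 2.5, beta_y = 1.2,
                  gamma = 0.27, theta = 0.6)
  expect_equal(eval_model("super_gaussian", p2, xs, ys),
               oracle_super_gaussian(xs, ys, 0, 0, 2, 1.1, 2.5, 1.2, 0.27, 0.6),
               tolerance = 1e-12)
})

test_that("diameters follow the zero-ellipse and 4-sigma rules", {
  expect_equal(wheal_diameter("paraboloid", pb_params()), 2)
  d <- wheal_diameter("paraboloid", pb_params(wx = 2, wy = 1, c = 0.5, beta = 0.8))
  expect_equal(d, 2 * 2 * sqrt(0.8 * 0.5)) # ~2.5298
  # numerical root of f1 = 0 along the major axis as the oracle
  q <- pb_params(wx = 2, wy = 1, c = 0.5, beta = 0.8)
  root <- stats::uniroot(function(x) eval_model("paraboloid", q, x, 0),
                         c(0.01, 10))$root
  expect_equal(d, 2 * root, tolerance = 1e-6)
  expect_equal(wheal_diameter("super_gaussian", sg_params(sigma_x = 1.5, sigma_y = 1)), 6)
  expect_error(wheal_diameter("paraboloid", pb_params(beta = -1)), "positive")
})

test_that("diameter is invariant to rotation, translation and axis swap", {
  set.seed(42)
  for (i in 1:20) {
    sx <- runif(1, 0.8, 3); sy <- runif(1, 0.8, 3)
    th <- runif(1, -pi / 2, pi / 2 - 1e-6)
    p <- sg_params(x0p = rnorm(1), y0p = rnorm(1), sigma_x = sx, sigma_y = sy,
                   beta_x = runif(1, 1, 3), beta_y = runif(1, 1, 3),
                   gamma = runif(1, 0.1, 0.5), theta = th)
    d0 <- wheal_diameter("super_gaussian", p)
    p_rot <- p; p_rot$theta <- sptread:::wrap_half_pi(th + 0.7)
    expect_equal(wheal_diameter("super_gaussian", p_rot), d0)
    p_swap <- p
    p_swap$sigma_x <- sy; p_swap$sigma_y <- sx
    expect_equal(wheal_diameter("super_gaussian", p_swap), d0)
    # paraboloid: f1 at (x0 + a, y0) is always 0
    q <- pb_params(x0p = rnorm(1), y0p = rnorm(1), wx = runif(1, 0.5, 3),
                   wy = runif(1, 0.5, 3), c = runif(1, 0.2, 3),
                   beta = runif(1, 0.05, 0.5), theta = th)
    a <- q$wx * sqrt(q$beta * q$c)
    # the ellipse point lives in the rotated frame; feed rotated-back coords
    xr <- q$x0p + a; yr <- q$y0p
    xy <- c(cos(th) * xr + sin(th) * yr, -sin(th) * xr + cos(th) * yr)
    expect_equal(eval_model("paraboloid", q, xy[1], xy[2]), 0, tolerance = 1e-10)
  }
})

test_that("model-2 diameter increases strictly with the dominant sigma", {
  d <- vapply(seq(1.5, 3, by = 0.25), function(sx)
    wheal_diameter("super_gaussian", sg_params(sigma_x = sx, sigma_y = 1)), 0)
  expect_true(all(diff(d) > 0))
})

test_that("center_patch finds the centroid and principal-axis angle", {
  # symmetric bump: centroid at the true centre
  p <- make_model_patch("super_gaussian", sg_params(), 6, 0.15)
  cp <- center_patch(p)
  expect_lt(sqrt(sum(cp$centroid_global^2)), 0.15 / 2)
  expect_true(is.finite(cp$theta_init))

  # elongated bump rotated 30 degrees: theta_init within 2 degrees.
  # eval_model rotates coordinates clockwise by theta, so the long axis of
  # the rendered bump lies along -theta in the grid frame.
  th <- -30 * pi / 180
  p2 <- make_model_patch("super_gaussian",
                         sg_params(sigma_x = 2, sigma_y = 1, theta = th), 8, 0.15)
  cp2 <- center_patch(p2)
  expect_lt(abs(cp2$theta_init - 30 * pi / 180), 2 * pi / 180)

  # all-zero patch is degenerate
  p3 <- p; p3$surface[] <- 0
  expect_error(center_patch(p3), "degenerate")
})

test_that("noiseless surfaces of both models are recovered to 0.1% and 5.00 mm", {
  p_true <- sg_params(sigma_x = 1.25, sigma_y = 1, beta_x = 1.5, beta_y = 1.5,
                      gamma = 0.3, theta = 0)
  patch <- make_model_patch("super_gaussian", p_true, 6, 0.15)
  fit <- fit_wheal(center_patch(patch, baseline = "none"), "super_gaussian")
  expect_true(fit$converged)
  for (nm in c("sigma_x", "sigma_y", "beta_x", "beta_y", "gamma"))
    expect_rel_error(fit$params[[nm]], p_true[[nm]], 1e-3)
  expect_equal(fit$diameter_mm, 5, tolerance = 1e-2)

  # rotation invariance: same surface at 30 degrees
  p_rot <- p_true; p_rot$theta <- 30 * pi / 180
  fit_rot <- fit_wheal(center_patch(make_model_patch("super_gaussian", p_rot,
                                                     6, 0.15),
                                    baseline = "none"), "super_gaussian")
  expect_lt(abs(fit_rot$diameter_mm - fit$diameter_mm), 1e-2)
  th_err <- abs(sptread:::wrap_half_pi(fit_rot$params$theta - p_rot$theta))
  expect_lt(min(th_err, abs(th_err - pi / 2)), 0.05)

  # paraboloid (clipped at the skin plane): recover the identifiable
  # quantities a, b, beta, theta
  q_true <- pb_params(wx = 1.6, wy = 1.1, c = 0.4, beta = 0.3, theta = 0.4)
  qfit <- fit_wheal(center_patch(make_model_patch("paraboloid", q_true, 6, 0.15),
                                 baseline = "none"), "paraboloid")
  expect_true(qfit$converged)
  a_true <- q_true$wx * sqrt(q_true$beta * q_true$c)
  b_true <- q_true$wy * sqrt(q_true$beta * q_true$c)
  a_fit <- qfit$params$wx * sqrt(qfit$params$beta * qfit$params$c)
  b_fit <- qfit$params$wy * sqrt(qfit$params$beta * qfit$params$c)
  expect_rel_error(a_fit, a_true, 1e-3)
  expect_rel_error(b_fit, b_true, 1e-3)
  expect_rel_error(qfit$params$beta, q_true$beta, 1e-3)
  expect_equal(qfit$diameter_mm, 2 * a_true, tolerance = 1e-3)
})

test_that("diameter estimates stay unbiased and tight under sensor noise", {
  p_true <- sg_params(sigma_x = 1.25, sigma_y = 1, beta_x = 1.5, beta_y = 1.5,
                      gamma = 0.3, theta = 0)
  set.seed(77)
  seeds <- sample.int(1e6, 50)
  d <- vapply(seeds, function(s) {
    patch <- make_model_patch("super_gaussian", p_true, 6, 0.15,
                              noise_sd = 0.01, seed = s)
    fit_wheal(center_patch(patch, baseline = "none"), "super_gaussian")$diameter_mm
  }, 0)
  expect_lt(abs(mean(d) - 5) / 5, 0.01) # bias < 1%
  expect_lt(100 * sd(d) / mean(d), 2)   # CV < 2%
})

test_that("non-physical fits fall back to the detection-scale diameter", {
  patch <- make_model_patch("super_gaussian", sg_params(), 6, 0.15)
  cp <- center_patch(patch, baseline = "none")
  fit <- fit_wheal(cp, "super_gaussian", fit_config(fallback_range_mm = c(8, 20)))
  expect_true(fit$fallback_used)
  expect_false(fit$converged)
  expect_equal(fit$diameter_mm, 2 * sqrt(2) * cp$source$scale_sigma)
})

test_that("fitted models expose tidy() and glance() summaries", {
  fit <- fit_wheal(center_patch(make_model_patch("super_gaussian", sg_params(),
                                                 6, 0.15),
                               baseline = "none"), "super_gaussian")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("sigma_x", "gamma", "theta") %in% td$term))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$converged)
})
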
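# Independent brute-force oracles and fixture builders shared by the tests.
# These deliberately re-derive the arithmetic with plain loops / closed forms
# so they cannot inherit a bug from the package's vectorized implementations.

# index lookup with gradient-preserving ("linear") or symmetric ("reflect")
# border extension, re-derived from the definition
oracle_border_value <- function(v, i, mode = "linear") {
  n <- length(v)
  fold <- function(j) {
    while (j < 1 || j > n) {
      if (j < 1) j <- 2 - j
      if (j > n) j <- 2 * n - j
    }
    j
  }
  if (i >= 1 && i <= n) return(v[i])
  if (mode == "reflect") {
    # half-sample symmetric: ... v2 v1 | v1 v2 ... (edge repeated)
    j <- i
    while (j < 1 || j > n) {
      if (j < 1) j <- 1 - j
      if (j > n) j <- 2 * n + 1 - j
    }
    return(v[j])
  }
  if (i < 1) return(2 * v[1] - v[fold(2 - i)])
  2 * v[n] - v[fold(2 * n - i)]
}

# direct 2D separable convolution with border extension, O(n^2 k^2) loops
oracle_sep_conv <- function(m, taps, mode = "linear") {
  k <- length(taps)
  p <- (k - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  get <- function(r, c) {
    # extend rows first, then columns, matching separable filtering
    col_vals <- vapply(seq_len(nc), function(cc) oracle_border_value(m[, cc], r, mode), 0)
    oracle_border_value(col_vals, c, mode)
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (dr in -p:p) for (dc in -p:p) {
      acc <- acc + taps[dr + p + 1] * taps[dc + p + 1] * get(r + dr, c + dc)
    }
    out[r, c] <- acc
  }
  out
}

oracle_reduce <- function(m, taps, mode = "linear") {
  sm <- oracle_sep_conv(m, taps, mode)
  sm[seq(1, nrow(sm), by = 2), seq(1, ncol(sm), by = 2), drop = FALSE]
}

# direct zero-insertion expand with coarse-side border extension
oracle_expand <- function(coarse, target, taps, mode = "linear") {
  p <- (length(taps) - 1) %/% 2
  expand_1d_col <- function(mat, n_out) {
    m <- nrow(mat)
    out <- matrix(0, n_out, ncol(mat))
    for (cc in seq_len(ncol(mat))) {
      v <- mat[, cc]
      for (i in seq_len(n_out)) {
        acc <- 0
        for (dt in -p:p) {
          pos <- i + dt # fine position under tap
          if (pos %% 2 == 1) { # coarse samples sit at odd fine positions
            j <- (pos + 1) / 2
            acc <- acc + taps[dt + p + 1] * oracle_border_value(v, j, mode)
          }
        }
        out[i, cc] <- acc
      }
    }
    out
  }
  out <- expand_1d_col(coarse, target[1])
  t(expand_1d_col(t(out), target[2]))
}

# super-Gaussian / paraboloid surfaces evaluated with independent arithmetic
oracle_super_gaussian <- function(x, y, x0, y0, sx, sy, bx, by, g, th) {
  xr <- x * cos(th) - y * sin(th)
  yr <- x * sin(th) + y * cos(th)
  g * exp(-((xr - x0)^2 / (2 * sx^2))^bx - ((yr - y0)^2 / (2 * sy^2))^by)
}

# build a wheal_patch directly from a model surface sampled on a grid
# centred at (0, 0); bypasses detection so the fit can be tested in isolation
make_model_patch <- function(kind, params, halfwidth_mm, pitch,
                             noise_sd = 0, seed = NULL) {
  g <- seq(-halfwidth_mm, halfwidth_mm, by = pitch)
  n <- length(g)
  X <- rep(g, each = n)
  Y <- rep(g, times = n)
  z <- eval_model(kind, params, X, Y)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    z <- z + rnorm(length(z), sd = noise_sd)
  }
  structure(
    list(surface = matrix(z, n, n), pitch = pitch,
         origin_global = c(-halfwidth_mm, -halfwidth_mm),
         source = list(row = (n + 1) / 2, col = (n + 1) / 2,
                       x_mm = 0, y_mm = 0,
                       scale_sigma = halfwidth_mm / (2 * sqrt(2)),
                       response = 1),
         clipped = FALSE),
    class = "wheal_patch"
  )
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
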
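# Shared fixtures and independent oracles for the suite.

# sample points on a rotated ellipse, optional isotropic jitter
sample_ellipse <- function(n, cx, cy, a, b, angle_deg, jitter_sd = 0,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  th <- angle_deg * pi / 180
  u <- a * cos(t); v <- b * sin(t)
  x <- cx + u * cos(th) - v * sin(th)
  y <- cy + u * sin(th) + v * cos(th)
  if (jitter_sd > 0) {
    x <- x + rnorm(n, sd = jitter_sd)
    y <- y + rnorm(n, sd = jitter_sd)
  }
  cbind(x = x, y = y)
}

# brute-force geometric-distance ellipse fit: coarse parameter grid around
# the data, refined by Nelder-Mead on the radial-distance SSE.  Independent
# of the algebraic direct fit under test.
oracle_fit_ellipse <- function(points) {
  sse <- function(par) fetalbw:::ellipse_radial_sse(par, points)
  cx0 <- mean(points[, 1]); cy0 <- mean(points[, 2])
  rx <- diff(range(points[, 1])) / 2; ry <- diff(range(points[, 2])) / 2
  amax <- max(rx, ry) * 1.3
  grid <- expand.grid(a = seq(amax * 0.4, amax, length.out = 10),
                      b = seq(amax * 0.2, amax, length.out = 10),
                      th = seq(0, pi, length.out = 13)[-13])
  grid <- grid[grid$a >= grid$b, ]
  vals <- apply(grid, 1, function(g) sse(c(cx0, cy0, g[1], g[2], g[3])))
  g0 <- as.numeric(grid[which.min(vals), ])
  opt <- optim(c(cx0, cy0, g0[1], g0[2], g0[3]), sse,
               control = list(maxit = 5000, reltol = 1e-12))
  p <- opt$par
  a <- max(p[3], p[4]); b <- min(p[3], p[4])
  ang <- if (p[3] >= p[4]) p[5] else p[5] + pi / 2
  list(cx = p[1], cy = p[2], semi_major = a, semi_minor = b,
       angle_deg = (ang * 180 / pi) %% 180)
}

# shoelace polygon area
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

angle_diff_180 <- function(a, b) {
  d <- abs((a - b) %% 180)
  min(d, 180 - d)
}
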
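#' Direct least-squares ellipse fit
#'
#' Fits the algebraic conic `a x^2 + b xy + c y^2 + d x + e y + f = 0` to a
#' set of boundary points under the ellipse constraint `4ac - b^2 = 1`
#' (Fitzgibbon's direct least-squares fit, in the numerically stable
#' partitioned form of Halir & Flusser).  The fit is deterministic, exact on
#' noise-free ellipse samples, and always returns an ellipse (never a
#' hyperbola or parabola).
#'
#' @param points Matrix with columns `x`, `y`; at least 5 non-collinear
#'   points are required.
#' @return An `ellipse_fit` object: list with `cx`, `cy` (centre, pixels),
#'   `semi_major`, `semi_minor` (semi-axes, `semi_major >= semi_minor`), and
#'   `angle_deg` (major-axis orientation, degrees CCW from +x, in
#'   \[0, 180)).
#' @examples
#' t <- seq(0, 2 * pi, length.out = 41)[-41]
#' pts <- cbind(x = 50 * cos(t), y = 30 * sin(t))
#' fit_ellipse(pts)
#' @export
fit_ellipse <- function(points) {
  stopifnot(is.matrix(points) || is.data.frame(points))
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  points <- points[!duplicated(points), , drop = FALSE]
  if (nrow(points) < 5L)
    stop("ellipse fitting needs at least 5 distinct points")
  # centre & scale for conditioning
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  s <- mean(abs(cbind(points[, 1] - mx, points[, 2] - my))) + .Machine$double.eps
  x <- (points[, 1] - mx) / s
  y <- (points[, 2] - my) / s

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12) stop("degenerate point configuration")
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  # premultiply by inv(C), C the constraint matrix of 4ac - b^2
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) stop("degenerate point configuration (no ellipse solution)")
  a1 <- evec[, ok[1]]
  coef <- c(a1, Tm %*% a1) # (A, B, C, D, E, F) in scaled frame
  geom <- conic_to_ellipse(coef)
  # undo the normalisation
  list_fit(cx = geom$cx * s + mx, cy = geom$cy * s + my,
           semi_major = geom$a * s, semi_minor = geom$b * s,
           angle_deg = geom$angle_deg)
}

list_fit <- function(cx, cy, semi_major, semi_minor, angle_deg) {
  structure(list(cx = cx, cy = cy, semi_major = semi_major,
                 semi_minor = semi_minor, angle_deg = angle_deg %% 180),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "ellipse_fit: centre (%.2f, %.2f), semi-axes %.2f x %.2f px, %.1f deg\n",
    x$cx, x$cy, x$semi_major, x$semi_minor, x$angle_deg))
  invisible(x)
}

# conic (A,B,C,D,E,F), B the full xy coefficient -> geometric parameters
conic_to_ellipse <- function(k) {
  if (k[1] + k[3] < 0) k <- -k  # fix the conic's overall sign
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("conic is not an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  ax1 <- -sqrt(num * (A + C + sqrt((A - C)^2 + B^2))) / den
  ax2 <- -sqrt(num * (A + C - sqrt((A - C)^2 + B^2))) / den
  a <- max(ax1, ax2); b <- min(ax1, ax2)
  # major axis = eigenvector of the quadratic form's smaller eigenvalue
  e <- eigen(matrix(c(A, B / 2, B / 2, C), 2, 2), symmetric = TRUE)
  vmin <- e$vectors[, 2]
  th <- atan2(vmin[2], vmin[1])
  list(cx = cx, cy = cy, a = a, b = b, angle_deg = (th * 180 / pi) %% 180)
}

#' Ellipse circumference (Ramanujan's second approximation)
#'
#' `pi (a + b) (1 + 3h / (10 + sqrt(4 - 3h)))` with
#' `h = ((a - b) / (a + b))^2`.  Relative error is below 0.05% for all axis
#' ratios that occur in fetal biometry, which is why it is used in the
#' measurement hot path instead of iterative quadrature
#' (see [ellipse_perimeter_exact()] for the reference integral).
#'
#' @param semi_major,semi_minor Semi-axes, `semi_major >= semi_minor > 0`.
#' @return Circumference in the same units as the axes.
#' @examples
#' ellipse_circumference(10, 10)  # 2*pi*10
#' @export
ellipse_circumference <- function(semi_major, semi_minor) {
  a <- semi_major; b <- semi_minor
  if (b <= 0 || a < b) stop("need semi_major >= semi_minor > 0")
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# sum of squared geometric (point-to-ellipse) distances, approximated by the
# radial distance along each point's direction from the centre; used by the
# test-suite grid-search oracle and by nothing in the fitting hot path
ellipse_radial_sse <- function(par, points) {
  cx <- par[1]; cy <- par[2]; a <- par[3]; b <- par[4]; th <- par[5]
  x <- points[, 1] - cx; y <- points[, 2] - cy
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  r <- sqrt(u^2 + v^2)
  phi <- atan2(v / b, u / a)
  re <- sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
  sum((r - re)^2)
}
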
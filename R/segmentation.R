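#' Adaptive (local-mean) threshold segmentation
#'
#' Labels a pixel foreground iff its intensity exceeds the mean over a
#' square neighbourhood by more than `offset`.  Local-mean thresholding is
#' robust to the smooth illumination gradients common in ultrasound images,
#' where a global threshold would fail.
#'
#' @param image An [image2d()] or numeric matrix.
#' @param window_px Odd window side length in pixels (>= 3), default 51.
#' @param offset Intensity margin above the local mean (fraction of the
#'   \[0, 1\] range), default 0.02.
#' @return Logical matrix of the same shape, `TRUE` on foreground.
#' @examples
#' ph <- generate_phantom(phantom_truth("head"))
#' mask <- segment_adaptive(ph$image)
#' @export
segment_adaptive <- function(image, window_px = 51, offset = 0.02) {
  m <- if (inherits(image, "image2d")) as_matrix(image) else image
  stopifnot(is.matrix(m))
  if (window_px %% 2 != 1 || window_px < 3)
    stop("'window_px' must be odd and >= 3")
  if (window_px > min(dim(m)))
    stop("window larger than image")
  m > box_mean_replicate(m, window_px) + offset
}

# largest connected foreground component; ties broken by centroid distance
# to the image centre.  Returns logical mask (or NULL if mask is empty).
largest_component <- function(mask) {
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    ctr <- (dim(mask) + 1) / 2
    d <- vapply(best, function(k) {
      ij <- which(lab == k, arr.ind = TRUE)
      sum((colMeans(ij) - ctr)^2)
    }, numeric(1))
    best <- best[which.min(d)]
  }
  lab == best[1]
}

#' Extract a closed outer contour from a binary mask
#'
#' Detects the edges of the largest foreground component (gradient-magnitude
#' edge detection with hysteresis thresholds on the normalised gradient),
#' closes any broken arcs by taking the convex hull of the edge points, and
#' returns the hull boundary as a closed, densely sampled polygon.  The
#' convex-hull closure step is what makes the pipeline tolerant of
#' discontinuous edges: a rim with a missing arc still yields a closed
#' contour enclosing nearly the full shape.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param canny_low,canny_high Hysteresis thresholds as fractions of the
#'   maximum gradient magnitude (defaults 0.1 and 0.3).
#' @param step Approximate arc-length spacing (pixels) of the returned
#'   polygon samples.
#' @return A matrix with columns `x`, `y` (pixel coordinates, x = column,
#'   y = row); the first and last rows coincide (closed contour).
#' @export
extract_closed_contour <- function(mask, canny_low = 0.1, canny_high = 0.3,
                                   step = 1) {
  mask <- mask > 0
  if (!any(mask)) stop("no object found (empty mask)")
  comp <- largest_component(mask)
  edges <- gradient_edges(comp, canny_low, canny_high) & comp # object-side edge
  pts <- which(edges, arr.ind = TRUE) # (row, col)
  if (nrow(pts) < 3L) stop("no object found (component too small)")
  xy <- cbind(x = pts[, 2], y = pts[, 1])
  hull <- xy[grDevices::chull(xy), , drop = FALSE]
  densify_polygon(hull, step = step)
}

# Sobel gradient magnitude + hysteresis on a (binary or grayscale) image.
# On a binary mask this reduces to marking boundary pixels.
gradient_edges <- function(m, low = 0.1, high = 0.3) {
  m <- m * 1
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- conv3(m, kx)
  gy <- conv3(m, t(kx))
  g <- sqrt(gx^2 + gy^2)
  mx <- max(g)
  if (mx == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  g <- g / mx
  strong <- g >= high
  weak <- g >= low
  if (!any(strong)) return(weak)
  # keep weak pixels connected to a strong pixel
  lab <- EBImage::bwlabel(weak * 1)
  lab <- matrix(as.integer(lab), nrow = nrow(m))
  keep <- unique(lab[strong])
  weak & (lab %in% keep)
}

# 3x3 convolution with replicate padding
conv3 <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(1L, seq_len(nr), nr); ci <- c(1L, seq_len(nc), nc)
  p <- m[ri, ci]
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + k[dr + 1, dc + 1] * p[dr + seq_len(nr), dc + seq_len(nc)]
  out
}

# resample a polygon's edges at ~step spacing; returns closed polygon
densify_polygon <- function(poly, step = 1) {
  n <- nrow(poly)
  if (n < 3L) stop("degenerate polygon")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- poly[i, ]; q <- poly[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((q - p)^2))
    k <- max(1L, ceiling(len / step))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out[[i]] <- cbind(x = p[1] + t * (q[1] - p[1]),
                      y = p[2] + t * (q[2] - p[2]))
  }
  pts <- do.call(rbind, out)
  rbind(pts, pts[1, , drop = FALSE])
}

#' Minimum-area rotated rectangle of a point set
#'
#' Rotating-calipers search over the convex hull: the minimum-area enclosing
#' rectangle has one side collinear with a hull edge, so each hull edge
#' orientation is tried and the smallest bounding box kept.
#'
#' @param points Matrix with columns `x`, `y`.
#' @return List with `center` (x, y), `length` (longer side), `width`
#'   (shorter side) and `angle_deg` (orientation of the long side, degrees
#'   CCW from +x, normalised to \[0, 180)).
#' @export
min_area_rect <- function(points) {
  stopifnot(is.matrix(points), ncol(points) >= 2, nrow(points) >= 3)
  xy <- points[, 1:2, drop = FALSE]
  hull <- xy[grDevices::chull(xy), , drop = FALSE]
  n <- nrow(hull)
  best <- NULL
  for (i in seq_len(n)) {
    e <- hull[if (i == n) 1L else i + 1L, ] - hull[i, ]
    th <- atan2(e[2], e[1])
    u <- hull %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    dx <- diff(range(u[, 1])); dy <- diff(range(u[, 2]))
    if (is.null(best) || dx * dy < best$area) {
      cu <- c(mean(range(u[, 1])), mean(range(u[, 2])))
      # rotate centre back to image frame
      ctr <- c(cu[1] * cos(th) - cu[2] * sin(th),
               cu[1] * sin(th) + cu[2] * cos(th))
      long <- max(dx, dy); short <- min(dx, dy)
      ang <- if (dx >= dy) th else th + pi / 2
      best <- list(area = dx * dy, center = ctr, length = long,
                   width = short, angle_deg = (ang * 180 / pi) %% 180)
    }
  }
  best$area <- NULL
  best
}
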
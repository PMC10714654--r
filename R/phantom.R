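#' Ground-truth specification for a synthetic ultrasound phantom
#'
#' Describes the geometry, intensity levels, speckle noise and calibration of
#' a synthetic test image with exactly known ground truth.  Three structures
#' are supported: `"head"` and `"abdomen"` render a bright elliptical rim
#' (skull / abdominal wall cross-section) of a given thickness on a darker
#' background; `"femur"` renders a bright rotated bar (ossified shaft).
#'
#' Speckle, the granular multiplicative interference noise characteristic of
#' ultrasound, is emulated by the first-order surrogate
#' `pixel * (1 + speckle_sigma * G)` with `G` i.i.d. standard normal, clipped
#' to \[0, 1\].  `speckle_sigma = 0` gives the clean reference image, so the
#' clean counterpart of any phantom is recoverable by regenerating with the
#' same geometry and seed.
#'
#' @param kind `"head"`, `"abdomen"` or `"femur"`.
#' @param semi_major_px,semi_minor_px Ellipse semi-axes in pixels
#'   (head/abdomen); `semi_major_px >= semi_minor_px > 0`.
#' @param rim_thickness_px Wall thickness in pixels (head/abdomen); must be
#'   smaller than `semi_minor_px`.
#' @param bar_length_px,bar_width_px,bar_angle_deg Femur bar geometry:
#'   length, width (pixels) and orientation (degrees CCW from +x).
#' @param angle_deg Ellipse orientation, degrees CCW from +x (head/abdomen).
#' @param center Length-2 vector `(x, y)` in pixels; default canvas centre.
#' @param canvas Length-2 vector `(width, height)` in pixels.
#' @param speckle_sigma Speckle noise scale, >= 0 (0 = clean).
#' @param background_level,foreground_level Intensities in \[0, 1\].
#' @param mm_per_pixel Physical pixel size in millimetres.
#' @param seed Integer seed; the same spec and seed always yield a
#'   bit-identical image.
#' @return A `phantom_truth` object (a list with the above fields).
#' @seealso [generate_phantom()], [phantom_truth_mm()]
#' @examples
#' tr <- phantom_truth("head", semi_major_px = 60, semi_minor_px = 45)
#' phantom_truth_mm(tr)
#' @export
phantom_truth <- function(kind = c("head", "abdomen", "femur"),
                          semi_major_px = 60, semi_minor_px = 45,
                          rim_thickness_px = 6,
                          bar_length_px = 80, bar_width_px = 10,
                          bar_angle_deg = 0,
                          angle_deg = 0,
                          center = NULL,
                          canvas = c(512L, 512L),
                          speckle_sigma = 0,
                          background_level = 0.1, foreground_level = 0.9,
                          mm_per_pixel = 0.2,
                          seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(length(canvas) == 2L, all(canvas >= 16))
  if (is.null(center)) center <- (canvas + 1) / 2
  stopifnot(length(center) == 2L)
  if (speckle_sigma < 0) stop("'speckle_sigma' must be >= 0")
  if (background_level < 0 || background_level > 1 ||
      foreground_level < 0 || foreground_level > 1)
    stop("intensity levels must lie in [0, 1]")
  if (mm_per_pixel <= 0) stop("'mm_per_pixel' must be > 0")
  if (kind %in% c("head", "abdomen")) {
    if (!(semi_major_px >= semi_minor_px && semi_minor_px > 0))
      stop("need semi_major_px >= semi_minor_px > 0")
    if (rim_thickness_px <= 0 || rim_thickness_px >= semi_minor_px)
      stop("'rim_thickness_px' must be in (0, semi_minor_px)")
  } else {
    if (bar_length_px <= 0 || bar_width_px <= 0)
      stop("bar dimensions must be positive")
  }
  structure(list(kind = kind,
                 semi_major_px = semi_major_px, semi_minor_px = semi_minor_px,
                 rim_thickness_px = rim_thickness_px,
                 bar_length_px = bar_length_px, bar_width_px = bar_width_px,
                 bar_angle_deg = bar_angle_deg, angle_deg = angle_deg,
                 center = as.numeric(center), canvas = as.integer(canvas),
                 speckle_sigma = speckle_sigma,
                 background_level = background_level,
                 foreground_level = foreground_level,
                 mm_per_pixel = mm_per_pixel, seed = as.integer(seed)),
            class = "phantom_truth")
}

#' Generate a synthetic phantom image from its ground-truth spec
#'
#' Renders the structure described by a [phantom_truth()] as a hard binary
#' shape (no anti-aliasing, so ground-truth boundaries are unambiguous for
#' recall metrics) and applies multiplicative speckle when
#' `truth$speckle_sigma > 0`.  The generator is deterministic: the same spec
#' and seed produce a pixel-identical image.
#'
#' @param truth A [phantom_truth()] object.
#' @return A list with components `image` (an [image2d()] carrying the
#'   phantom's `mm_per_pixel`) and `truth` (the spec, echoed back).
#' @examples
#' ph <- generate_phantom(phantom_truth("head", speckle_sigma = 0.2, seed = 7))
#' range(ph$image)
#' @export
generate_phantom <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  w <- truth$canvas[1]; h <- truth$canvas[2]
  cx <- truth$center[1]; cy <- truth$center[2]
  margin <- 4
  if (truth$kind %in% c("head", "abdomen")) {
    # loose bound: rotated ellipse fits inside circle of radius a
    r <- truth$semi_major_px
    if (cx - r < margin || cx + r > w - margin ||
        cy - r < margin || cy + r > h - margin)
      stop("shape exceeds canvas (ellipse radius too large for centre)")
  } else {
    r <- sqrt(truth$bar_length_px^2 + truth$bar_width_px^2) / 2
    if (cx - r < margin || cx + r > w - margin ||
        cy - r < margin || cy + r > h - margin)
      stop("shape exceeds canvas (bar too long for centre)")
  }

  xs <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE) - cx
  ys <- matrix(seq_len(h), nrow = h, ncol = w) - cy
  img <- matrix(truth$background_level, nrow = h, ncol = w)

  if (truth$kind %in% c("head", "abdomen")) {
    th <- truth$angle_deg * pi / 180
    u <-  xs * cos(th) + ys * sin(th)
    v <- -xs * sin(th) + ys * cos(th)
    a <- truth$semi_major_px; b <- truth$semi_minor_px
    ai <- a - truth$rim_thickness_px; bi <- b - truth$rim_thickness_px
    inside_outer <- (u / a)^2 + (v / b)^2 <= 1
    inside_inner <- (u / ai)^2 + (v / bi)^2 < 1
    img[inside_outer & !inside_inner] <- truth$foreground_level
  } else {
    th <- truth$bar_angle_deg * pi / 180
    u <-  xs * cos(th) + ys * sin(th)
    v <- -xs * sin(th) + ys * cos(th)
    inside <- abs(u) <= truth$bar_length_px / 2 &
              abs(v) <= truth$bar_width_px / 2
    img[inside] <- truth$foreground_level
  }

  if (truth$speckle_sigma > 0) {
    img <- with_preserved_rng(truth$seed, {
      g <- matrix(stats::rnorm(h * w), nrow = h, ncol = w)
      img * (1 + truth$speckle_sigma * g)
    })
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  list(image = image2d(img, mm_per_pixel = truth$mm_per_pixel), truth = truth)
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Exact ellipse perimeter by numeric quadrature
#'
#' Computes the complete elliptic arc-length integral
#' `4 a E(e)` with eccentricity `e = sqrt(1 - (b/a)^2)` using adaptive
#' quadrature.  Serves as the ground-truth perimeter for phantom ellipses and
#' as the reference the fast Ramanujan approximation
#' ([ellipse_circumference()]) is validated against.
#'
#' @param semi_major,semi_minor Semi-axes, `semi_major >= semi_minor > 0`.
#' @return Perimeter in the same units as the axes.
#' @examples
#' ellipse_perimeter_exact(10, 10) / (2 * pi)   # a circle: radius back
#' @export
ellipse_perimeter_exact <- function(semi_major, semi_minor) {
  if (semi_minor <= 0 || semi_major < semi_minor)
    stop("need semi_major >= semi_minor > 0")
  a <- semi_major; b <- semi_minor
  e2 <- 1 - (b / a)^2
  f <- function(t) sqrt(1 - e2 * sin(t)^2)
  4 * a * stats::integrate(f, 0, pi / 2, rel.tol = 1e-12)$value
}

#' Ground-truth biometry of a phantom in millimetres
#'
#' Converts a phantom's geometry into the millimetre measurements the image
#' pipeline is expected to recover: head/abdomen circumference is the exact
#' elliptic perimeter of the outer rim boundary; the outer-to-outer
#' biparietal diameter is twice the semi-minor axis; the outer-to-inner
#' diameter subtracts one rim thickness; femur length is the bar length.
#'
#' @param truth A [phantom_truth()].
#' @return Named list: for ellipse kinds `circumference_mm`,
#'   `bpd_outer_outer_mm`, `bpd_outer_inner_mm`; for femur `fl_mm`.
#' @export
phantom_truth_mm <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  mpp <- truth$mm_per_pixel
  if (truth$kind == "femur")
    return(list(fl_mm = truth$bar_length_px * mpp))
  per <- ellipse_perimeter_exact(truth$semi_major_px, truth$semi_minor_px)
  list(circumference_mm = per * mpp,
       bpd_outer_outer_mm = 2 * truth$semi_minor_px * mpp,
       bpd_outer_inner_mm = (2 * truth$semi_minor_px - truth$rim_thickness_px) * mpp)
}

#' Binary mask of the true phantom foreground
#'
#' Regenerates the clean phantom and thresholds it halfway between the
#' background and foreground levels, yielding the exact ground-truth mask of
#' rim (or bar) pixels for segmentation recall metrics.
#'
#' @param truth A [phantom_truth()].
#' @return Logical matrix, `TRUE` on true foreground pixels.
#' @export
phantom_truth_mask <- function(truth) {
  clean <- truth
  clean$speckle_sigma <- 0
  img <- generate_phantom(clean)$image
  as_matrix(img) > (clean$background_level + clean$foreground_level) / 2
}
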
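#' Tunable parameters of the biometry measurement pipeline
#'
#' Collects every threshold and convention used by [measure_head()],
#' [measure_abdomen()] and [measure_femur()].  Defaults follow standard
#' practice for obstetric ultrasound image analysis; all are configurable.
#'
#' @param denoise Apply wavelet soft-threshold denoising before
#'   segmentation (default `TRUE`; see [denoise_wavelet()]).
#' @param wavelet,level Wavelet family and decomposition depth for the
#'   denoiser.
#' @param window_px,offset Adaptive-threshold window (odd, pixels) and
#'   offset (intensity fraction); see [segment_adaptive()].
#' @param canny_low,canny_high Edge-detection hysteresis thresholds as
#'   fractions of the gradient range.
#' @param tophat_radius_px Disc radius (pixels) of the white top-hat
#'   structuring element used in the abdomen pipeline; it must exceed the
#'   wall thickness so the bright rim survives the opening residue.
#' @param bpd_convention `"outer_to_inner"` (default): biparietal diameter
#'   is the full minor diameter of the outer skull ellipse minus one
#'   estimated rim thickness, measuring from the outer edge of the near
#'   wall to the inner edge of the far wall.  `"minor_axis"`: the full
#'   minor diameter of the fitted ellipse.
#' @param max_axis_ratio Plausibility gate: an ellipse fit with
#'   `semi_major/semi_minor` above this is flagged (not rejected).
#' @param min_area_frac Plausibility gate: a segmented object smaller than
#'   this fraction of the image is flagged.
#' @return A list of class `biometry_params`.
#' @export
biometry_params <- function(denoise = TRUE, wavelet = "db4", level = 3,
                            window_px = 51, offset = 0.02,
                            canny_low = 0.1, canny_high = 0.3,
                            tophat_radius_px = 15,
                            bpd_convention = c("outer_to_inner", "minor_axis"),
                            max_axis_ratio = 2.5, min_area_frac = 0.005) {
  structure(list(denoise = denoise, wavelet = wavelet, level = level,
                 window_px = window_px, offset = offset,
                 canny_low = canny_low, canny_high = canny_high,
                 tophat_radius_px = tophat_radius_px,
                 bpd_convention = match.arg(bpd_convention),
                 max_axis_ratio = max_axis_ratio,
                 min_area_frac = min_area_frac),
            class = "biometry_params")
}

#' Biometry measurements for one subject or image
#'
#' Container for the four fetal biometrics in millimetres; any subset may be
#' present.  `provenance` records whether the values came from a physician's
#' manual measurement or from the image-processing pipeline.
#'
#' @param hc_mm,bpd_mm,ac_mm,fl_mm Head circumference, biparietal diameter,
#'   abdominal circumference, femur length (millimetres, > 0), or `NA`.
#' @param provenance `"image_algorithm"` or `"physician"`.
#' @return A `biometry_set` list.
#' @export
biometry_set <- function(hc_mm = NA_real_, bpd_mm = NA_real_,
                         ac_mm = NA_real_, fl_mm = NA_real_,
                         provenance = c("image_algorithm", "physician")) {
  vals <- c(hc_mm = hc_mm, bpd_mm = bpd_mm, ac_mm = ac_mm, fl_mm = fl_mm)
  bad <- !is.na(vals) & vals <= 0
  if (any(bad)) stop("biometry values must be positive: ",
                     paste(names(vals)[bad], collapse = ", "))
  if (!is.na(hc_mm) && !is.na(bpd_mm) && hc_mm <= bpd_mm)
    stop("head circumference must exceed biparietal diameter")
  structure(c(as.list(vals), list(provenance = match.arg(provenance))),
            class = "biometry_set")
}

# shared front end: grayscale (already done by image2d) + optional denoise
prep_image <- function(image, params) {
  if (params$denoise)
    denoise_wavelet(image, wavelet = params$wavelet, level = params$level)
  else image
}

segment_object <- function(img, params) {
  mask <- segment_adaptive(img, params$window_px, params$offset)
  comp <- largest_component(mask)
  if (is.null(comp)) stop("no object found (empty segmentation)")
  comp
}

# rim thickness from ring area: solving pi*t^2 - pi*(a+b)*t + area = 0,
# the exact relation for a concentric elliptical ring of equal wall thickness
estimate_rim_thickness <- function(area_px, semi_major, semi_minor) {
  s <- semi_major + semi_minor
  disc <- s^2 - 4 * area_px / pi
  if (disc < 0) return(NA_real_)
  (s - sqrt(disc)) / 2
}

finish_fit <- function(fit, comp, params) {
  flags <- character(0)
  if (fit$semi_major / fit$semi_minor > params$max_axis_ratio)
    flags <- c(flags, "implausible fit: axis ratio")
  if (sum(comp) < params$min_area_frac * length(comp))
    flags <- c(flags, "implausible fit: object too small")
  flags
}

#' Measure head circumference and biparietal diameter
#'
#' Full head pipeline: denoise, adaptive local-mean segmentation, closed
#' contour via convex hull + edge detection, direct least-squares ellipse
#' fit to the outer skull boundary.  HC is the Ramanujan circumference of
#' the fitted ellipse times the pixel size.  BPD follows the configured
#' convention (see [biometry_params()]): the default outer-to-inner reading
#' subtracts one estimated rim thickness (from the ring-area relation) from
#' the full minor diameter.
#'
#' @param image An [image2d()] with a `mm_per_pixel` calibration.
#' @param params A [biometry_params()].
#' @return List with `biometry` (a [biometry_set()] with `hc_mm`,
#'   `bpd_mm`), `fit` (the `ellipse_fit`), `rim_thickness_px` and `flags`
#'   (character vector of plausibility warnings, empty when clean).
#' @examples
#' ph <- generate_phantom(phantom_truth("head"))
#' measure_head(ph$image)$biometry
#' @export
measure_head <- function(image, params = biometry_params()) {
  mpp <- require_mpp(image)
  img <- prep_image(image, params)
  comp <- segment_object(img, params)
  contour <- extract_closed_contour(comp, params$canny_low, params$canny_high)
  fit <- fit_ellipse(contour)
  # pixel-footprint compensation: foreground pixel centres lie inside the
  # true boundary, so the fitted outer ellipse is ~half a pixel small
  fit$semi_major <- fit$semi_major + 0.5
  fit$semi_minor <- fit$semi_minor + 0.5
  rim <- estimate_rim_thickness(sum(comp), fit$semi_major, fit$semi_minor)
  bpd_px <- if (params$bpd_convention == "outer_to_inner" && !is.na(rim))
    2 * fit$semi_minor - rim else 2 * fit$semi_minor
  hc <- ellipse_circumference(fit$semi_major, fit$semi_minor) * mpp
  list(biometry = biometry_set(hc_mm = hc, bpd_mm = bpd_px * mpp),
       fit = fit, rim_thickness_px = rim, flags = finish_fit(fit, comp, params))
}

#' Measure abdominal circumference
#'
#' Abdomen pipeline: denoise, white top-hat (morphological opening residue,
#' which suppresses broad soft-tissue glare while keeping the thin bright
#' wall), linear contrast stretch to the full range, adaptive segmentation,
#' convex-hull contour closure and ellipse fit.  AC is the fitted ellipse
#' circumference times the pixel size.
#'
#' @inheritParams measure_head
#' @return List with `biometry` (`ac_mm`), `fit` and `flags`.
#' @export
measure_abdomen <- function(image, params = biometry_params()) {
  mpp <- require_mpp(image)
  img <- prep_image(image, params)
  m <- as_matrix(img)
  kern <- EBImage::makeBrush(2L * params$tophat_radius_px + 1L, shape = "disc")
  m <- EBImage::whiteTopHat(m, kern)
  m <- matrix(as.numeric(m), nrow = nrow(img))
  rng <- range(m)
  if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng)  # contrast stretch
  img2 <- image2d(m, mm_per_pixel = mpp)
  comp <- segment_object(img2, params)
  contour <- extract_closed_contour(comp, params$canny_low, params$canny_high)
  fit <- fit_ellipse(contour)
  fit$semi_major <- fit$semi_major + 0.5  # pixel-footprint compensation
  fit$semi_minor <- fit$semi_minor + 0.5
  ac <- ellipse_circumference(fit$semi_major, fit$semi_minor) * mpp
  list(biometry = biometry_set(ac_mm = ac), fit = fit,
       flags = finish_fit(fit, comp, params))
}

#' Measure femur length
#'
#' Femur pipeline: denoise, adaptive segmentation, largest component, and a
#' minimum-area rotated rectangle fitted to the component's pixels.  FL is
#' the rectangle's longer side times the pixel size, making the measurement
#' invariant to the bone's orientation.
#'
#' @inheritParams measure_head
#' @return List with `biometry` (`fl_mm`), `box` (the
#'   [min_area_rect()] descriptor) and `flags`.
#' @export
measure_femur <- function(image, params = biometry_params()) {
  mpp <- require_mpp(image)
  img <- prep_image(image, params)
  comp <- segment_object(img, params)
  pts <- which(comp, arr.ind = TRUE)
  box <- min_area_rect(cbind(x = pts[, 2], y = pts[, 1]))
  box$length <- box$length + 1  # pixel footprint: centres span (n-1) px
  box$width <- box$width + 1
  flags <- character(0)
  if (sum(comp) < params$min_area_frac * length(comp))
    flags <- "implausible fit: object too small"
  list(biometry = biometry_set(fl_mm = box$length * mpp), box = box,
       flags = flags)
}
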
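#' 2-D image container
#'
#' An `image2d` is a plain numeric matrix of intensities in \[0, 1\] with an
#' optional millimetre-per-pixel calibration attached as an attribute.  Rows
#' index y (top to bottom), columns index x (left to right): the origin is the
#' top-left pixel, x increases along columns, y along rows, and angles are in
#' degrees counter-clockwise from the +x axis.  This convention is used by
#' every function in the package.
#'
#' @param pixels Numeric matrix (or array with one or three channels; colour
#'   input is converted with [to_grayscale()]).  Integer inputs in 0--255 are
#'   rescaled to \[0, 1\].
#' @param mm_per_pixel Optional physical pixel size in millimetres (> 0).
#' @return An `image2d` object: a numeric matrix with class `"image2d"` and a
#'   `mm_per_pixel` attribute (possibly `NULL`).
#' @examples
#' img <- image2d(matrix(runif(64), 8, 8), mm_per_pixel = 0.2)
#' mm_per_pixel(img)
#' @export
image2d <- function(pixels, mm_per_pixel = NULL) {
  if (is.array(pixels) && length(dim(pixels)) == 3L)
    pixels <- to_grayscale(pixels)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix or an HxWx3 array")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("image intensities must be finite")
  if (max(pixels) > 1 + 1e-9) # integer-coded input
    pixels <- pixels / 255
  if (!is.null(mm_per_pixel)) {
    stopifnot(is.numeric(mm_per_pixel), length(mm_per_pixel) == 1L)
    if (!is.finite(mm_per_pixel) || mm_per_pixel <= 0)
      stop("'mm_per_pixel' must be a positive finite number")
  }
  structure(unclass(pixels), mm_per_pixel = mm_per_pixel, class = "image2d")
}

#' @rdname image2d
#' @param x An `image2d` (or any object carrying a `mm_per_pixel` attribute).
#' @export
mm_per_pixel <- function(x) attr(x, "mm_per_pixel", exact = TRUE)

#' @export
print.image2d <- function(x, ...) {
  mpp <- mm_per_pixel(x)
  cat(sprintf("image2d: %d x %d px, intensity [%.3f, %.3f], %s\n",
              nrow(x), ncol(x), min(x), max(x),
              if (is.null(mpp)) "uncalibrated"
              else sprintf("%.4g mm/px", mpp)))
  invisible(x)
}

# strip class/attrs -> bare matrix
as_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "mm_per_pixel") <- NULL
  m
}

require_mpp <- function(img) {
  mpp <- mm_per_pixel(img)
  if (is.null(mpp))
    stop("image has no mm_per_pixel calibration; supply one via image2d()")
  mpp
}
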
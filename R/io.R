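#' Read an image file into an image2d
#'
#' Reads PNG, TIFF or JPEG, converts colour input to grayscale with the
#' 0.299/0.587/0.114 luma weights and attaches an optional mm-per-pixel
#' calibration.  Pixel size is not stored by these formats, so the
#' calibration must come from acquisition metadata or user configuration.
#'
#' @param path File path; format inferred from the extension
#'   (`.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg`).
#' @param mm_per_pixel Optional pixel size in millimetres.
#' @return An [image2d()].
#' @export
read_image <- function(path, mm_per_pixel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, " (use PNG, TIFF or JPEG)"))
  if (is.array(px) && length(dim(px)) == 3L && dim(px)[3] == 4L)
    px <- px[, , 1:3] # drop alpha
  image2d(to_grayscale(px), mm_per_pixel = mm_per_pixel)
}

#' Write an image2d to disk
#'
#' @param image An [image2d()] or numeric matrix in \[0, 1\].
#' @param path Output path; `.png` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  m <- if (inherits(image, "image2d")) as_matrix(image) else image
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, path),
    tif = , tiff = tiff::writeTIFF(m, path),
    stop("unsupported output format: .", ext, " (use PNG or TIFF)"))
  invisible(path)
}
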
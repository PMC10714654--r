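#' Convert a colour raster to grayscale
#'
#' Applies the ITU-R BT.601 luma weights 0.299/0.587/0.114 to an RGB raster.
#' A single-channel input passes through unchanged, so the conversion is safe
#' to apply unconditionally at the head of a pipeline.
#'
#' @param raster A numeric matrix (already grayscale) or an H x W x 3 array.
#' @return A numeric matrix of the same height and width.
#' @examples
#' rgb <- array(c(1, 0, 0), dim = c(1, 1, 3))
#' to_grayscale(rgb)  # 0.299
#' @export
to_grayscale <- function(raster) {
  if (is.matrix(raster)) return(raster)
  d <- dim(raster)
  if (length(d) == 3L && d[3] == 1L) return(raster[, , 1])
  if (length(d) != 3L || d[3] != 3L)
    stop("input must have 1 or 3 channels")
  0.299 * raster[, , 1] + 0.587 * raster[, , 2] + 0.114 * raster[, , 3]
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(data_range^2 / MSE)` in decibels.  Identical images have
#' zero mean-squared error; rather than failing, the function returns `Inf`,
#' since pipelines may legitimately compare an image with itself.  PSNR is
#' symmetric in its two arguments.
#'
#' @param reference,test Images ([image2d()] or numeric matrices) of
#'   identical shape.
#' @param data_range Dynamic range of the data (default 1 for \[0, 1\]
#'   intensities; use 255 for 8-bit integer scales).
#' @return PSNR in dB (`Inf` for identical images).
#' @examples
#' psnr(matrix(0, 4, 4), matrix(10, 4, 4), data_range = 255)  # 28.13 dB
#' @export
psnr <- function(reference, test, data_range = 1) {
  a <- if (inherits(reference, "image2d")) as_matrix(reference) else reference
  b <- if (inherits(test, "image2d")) as_matrix(test) else test
  if (!identical(dim(a), dim(b))) stop("images must have identical shape")
  if (data_range <= 0) stop("'data_range' must be > 0")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Structural similarity index (mean SSIM)
#'
#' Mean local structural similarity over a square sliding window (default
#' 7 x 7, uniform weights) with the standard stabilising constants
#' `C1 = (k1 * data_range)^2`, `C2 = (k2 * data_range)^2`, `k1 = 0.01`,
#' `k2 = 0.03`.  Local means, variances and covariance use sample
#' (unbiased) normalisation; the SSIM map is evaluated on the valid interior
#' where the window fits entirely.
#'
#' @inheritParams psnr
#' @param window Odd window side length in pixels (default 7).
#' @param data_range Dynamic range (default 1).
#' @return Mean SSIM in \[-1, 1\]; 1 for identical images (including the
#'   degenerate case of two equal constant images, by the stabilisers).
#' @examples
#' m <- matrix(runif(400), 20, 20)
#' ssim(m, m)  # 1
#' @export
ssim <- function(reference, test, window = 7, data_range = 1) {
  a <- if (inherits(reference, "image2d")) as_matrix(reference) else reference
  b <- if (inherits(test, "image2d")) as_matrix(test) else test
  if (!identical(dim(a), dim(b))) stop("images must have identical shape")
  if (window %% 2 != 1 || window < 3) stop("'window' must be odd and >= 3")
  if (nrow(a) < window || ncol(a) < window)
    stop("image smaller than the SSIM window")
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  np <- window^2
  cov_norm <- np / (np - 1)
  mu_a <- box_mean(a, window); mu_b <- box_mean(b, window)
  e_aa <- box_mean(a * a, window); e_bb <- box_mean(b * b, window)
  e_ab <- box_mean(a * b, window)
  var_a <- cov_norm * (e_aa - mu_a^2)
  var_b <- cov_norm * (e_bb - mu_b^2)
  cov_ab <- cov_norm * (e_ab - mu_a * mu_b)
  num <- (2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2)
  mean(num / den)
}

# local mean over w x w windows, valid region only ((nr-w+1) x (nc-w+1)),
# via summed-area table
box_mean <- function(m, w) {
  S <- rbind(0, apply(m, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  nr <- nrow(m); nc <- ncol(m)
  i <- seq_len(nr - w + 1); j <- seq_len(nc - w + 1)
  (S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
     S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]) / (w * w)
}

# local mean with replicate padding, same-size output (adaptive threshold)
box_mean_replicate <- function(m, w) {
  r <- (w - 1) / 2
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  box_mean(m[ri, ci, drop = FALSE], w)
}
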
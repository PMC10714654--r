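# Periodized orthogonal discrete wavelet transform.
#
# Analysis convention: a[i] = sum_k h[k] x[(2(i-1)+k-1) mod n + 1], i.e. the
# analysis operator rows are the filters circularly shifted by two samples.
# With orthonormal Daubechies filters and even n >= filter length the
# operator is orthogonal, so synthesis is its transpose and reconstruction
# is exact to machine precision (asserted in the test suite).

wavelet_filters <- function(name = c("db4", "db2", "haar")) {
  name <- match.arg(name)
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.48296291314469025, 0.836516303737469,
            0.22414386804185735, -0.12940952255092145),
    db4 = c(0.23037781330885523, 0.7148465705525415,
            0.6308807679295904, -0.02798376941698385,
            -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278))
  L <- length(h)
  list(h = h, g = rev(h) * (-1)^(seq_len(L) - 1), L = L)
}

# dense analysis operators for signal length n (rows: n/2 shifted filters)
wavelet_operators <- function(n, f) {
  L <- f$L
  if (n %% 2L != 0L || n < L)
    stop("signal length must be even and >= filter length at every level")
  H <- matrix(0, n / 2, n)
  G <- matrix(0, n / 2, n)
  for (i in seq_len(n / 2)) {
    idx <- ((2 * (i - 1)) + seq_len(L) - 1) %% n + 1
    H[i, idx] <- H[i, idx] + f$h
    G[i, idx] <- G[i, idx] + f$g
  }
  list(H = H, G = G)
}

# one separable 2-D analysis step: returns LL and the three detail bands
dwt2_step <- function(m, f) {
  oc <- wavelet_operators(nrow(m), f)   # columns (rows of matrix)
  orr <- wavelet_operators(ncol(m), f)  # rows
  lo <- oc$H %*% m; hi <- oc$G %*% m
  list(LL = lo %*% t(orr$H), LH = lo %*% t(orr$G),
       HL = hi %*% t(orr$H), HH = hi %*% t(orr$G))
}

idwt2_step <- function(bands, f) {
  oc <- wavelet_operators(2L * nrow(bands$LL), f)
  orr <- wavelet_operators(2L * ncol(bands$LL), f)
  lo <- bands$LL %*% orr$H + bands$LH %*% orr$G
  hi <- bands$HL %*% orr$H + bands$HH %*% orr$G
  t(oc$H) %*% lo + t(oc$G) %*% hi
}

# multilevel decomposition: list(LL=, details=list(level1=list(LH,HL,HH),...))
dwt2 <- function(m, f, level) {
  stopifnot(level >= 1)
  details <- vector("list", level)
  cur <- m
  for (l in seq_len(level)) {
    if (nrow(cur) %% 2L != 0L || ncol(cur) %% 2L != 0L ||
        min(dim(cur)) < f$L)
      stop(sprintf("decomposition level %d infeasible for image size %dx%d",
                   l, nrow(m), ncol(m)))
    s <- dwt2_step(cur, f)
    details[[l]] <- s[c("LH", "HL", "HH")]
    cur <- s$LL
  }
  list(LL = cur, details = details)
}

idwt2 <- function(dec, f) {
  cur <- dec$LL
  for (l in rev(seq_along(dec$details))) {
    bands <- dec$details[[l]]
    bands$LL <- cur
    cur <- idwt2_step(bands, f)
  }
  cur
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Wavelet soft-threshold denoising
#'
#' Multilevel orthogonal wavelet decomposition with soft (shrink-toward-zero)
#' thresholding of all detail bands, the standard VisuShrink recipe: the
#' noise scale is estimated as `median(|HH1|) / 0.6745` from the finest
#' diagonal band and the universal threshold `sigma * sqrt(2 log N)` (N the
#' pixel count) is applied, then the image is reconstructed and clipped to
#' \[0, 1\].
#'
#' @param image An [image2d()] or numeric matrix with intensities in \[0, 1\].
#' @param wavelet `"db4"` (default), `"db2"` or `"haar"`.
#' @param level Decomposition depth (>= 1); must be feasible for the image
#'   size (each level halves both dimensions, which must stay even and at
#'   least the filter length).
#' @param threshold `"universal"` (VisuShrink, default) or a fixed numeric
#'   threshold on the detail coefficients.
#' @return A denoised [image2d()] of identical shape, calibration preserved.
#' @examples
#' ph <- generate_phantom(phantom_truth("head", speckle_sigma = 0.3, seed = 3))
#' den <- denoise_wavelet(ph$image)
#' @export
denoise_wavelet <- function(image, wavelet = "db4", level = 3,
                            threshold = "universal") {
  m <- if (inherits(image, "image2d")) as_matrix(image) else image
  stopifnot(is.matrix(m))
  f <- wavelet_filters(wavelet)
  dec <- dwt2(m, f, level)
  if (identical(threshold, "universal")) {
    sigma <- stats::median(abs(dec$details[[1]]$HH)) / 0.6745
    t <- sigma * sqrt(2 * log(length(m)))
  } else {
    stopifnot(is.numeric(threshold), threshold >= 0)
    t <- threshold
  }
  dec$details <- lapply(dec$details, function(lv) lapply(lv, soft_threshold, t = t))
  out <- idwt2(dec, f)
  out[out < 0] <- 0
  out[out > 1] <- 1
  image2d(out, mm_per_pixel = mm_per_pixel(image))
}
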
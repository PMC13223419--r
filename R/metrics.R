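# Full-reference image quality metrics: PSNR, SSIM, NMSE, FSIM.

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in decibels; identical images give `Inf`.
#'
#' @param reference,test numeric matrices of the same shape.
#' @param peak peak intensity value (default 255 for 8-bit images).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, peak = 255) {
  if (!identical(dim(reference), dim(test))) {
    stop("'reference' and 'test' must have identical dimensions")
  }
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Normalized mean square error
#'
#' Error energy divided by reference energy,
#' `sum((ref - test)^2) / sum(ref^2)`.
#'
#' @param reference,test numeric matrices of the same shape; `reference`
#'   must not be identically zero.
#' @return non-negative scalar.
#' @export
nmse <- function(reference, test) {
  if (!identical(dim(reference), dim(test))) {
    stop("'reference' and 'test' must have identical dimensions")
  }
  den <- sum(reference^2)
  if (den == 0) stop("'reference' is identically zero; NMSE undefined")
  sum((reference - test)^2) / den
}

# 1-D valid-convolution operator matrix for a symmetric kernel.
.valid_conv_op <- function(n, kernel) {
  L <- length(kernel)
  m <- n - L + 1L
  W <- matrix(0, m, n)
  for (i in seq_len(m)) W[i, i:(i + L - 1L)] <- kernel
  W
}

# Gaussian window used by SSIM (normalized to sum 1).
.ssim_window <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

#' Structural similarity index
#'
#' Mean of the local SSIM map computed with an 11x11 Gaussian window
#' (std 1.5) over the valid region, with stability constants
#' `C1 = (0.01 peak)^2`, `C2 = (0.03 peak)^2`.
#'
#' @param reference,test numeric matrices of the same shape, both
#'   dimensions at least 11.
#' @param peak dynamic range of the data (default 255).
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(reference, test, peak = 255) {
  if (!identical(dim(reference), dim(test))) {
    stop("'reference' and 'test' must have identical dimensions")
  }
  win <- 11L
  if (min(dim(reference)) < win) {
    stop("images must be at least ", win, "x", win, " for SSIM")
  }
  g <- .ssim_window(win, 1.5)
  Wr <- .valid_conv_op(nrow(reference), g)
  Wc <- .valid_conv_op(ncol(reference), g)
  filt <- function(m) Wr %*% m %*% t(Wc)
  C1 <- (0.01 * peak)^2
  C2 <- (0.03 * peak)^2
  mu1 <- filt(reference); mu2 <- filt(test)
  mu1sq <- mu1 * mu1; mu2sq <- mu2 * mu2; mu12 <- mu1 * mu2
  s1 <- filt(reference * reference) - mu1sq
  s2 <- filt(test * test) - mu2sq
  s12 <- filt(reference * test) - mu12
  map <- ((2 * mu12 + C1) * (2 * s12 + C2)) /
    ((mu1sq + mu2sq + C1) * (s1 + s2 + C2))
  mean(map)
}

#' All four quality metrics for one image pair
#'
#' @param reference,test numeric matrices of the same shape.
#' @param peak peak value; `NULL` picks 255 unless the reference maximum
#'   exceeds it, in which case the reference maximum is used.
#' @return object of class `metrics_report`: list with `psnr`, `ssim`,
#'   `nmse`, `fsim`, `peak`.
#' @export
metrics_report <- function(reference, test, peak = NULL) {
  if (is.null(peak)) peak <- max(255, max(reference))
  structure(
    list(psnr = psnr(reference, test, peak),
         ssim = ssim(reference, test, peak),
         nmse = nmse(reference, test),
         fsim = fsim(reference, test, peak),
         peak = peak),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("PSNR: %.4f dB  SSIM: %.4f  NMSE: %.4f  FSIM: %.4f\n",
              x$psnr, x$ssim, x$nmse, x$fsim))
  invisible(x)
}
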
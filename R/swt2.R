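# 2-D stationary (undecimated, a-trous) wavelet transform.
#
# Boundary handling inside the transform is periodic, which makes the
# transform exactly shift-covariant and the round trip exact; any reflective
# padding is done once, upstream, by pad_to_multiple().
#
# Orientation convention: the "horizontal" detail plane is produced by the
# highpass applied DOWN THE COLUMNS (dimension 1), so it responds to
# horizontal edges and stripes; "vertical" is the transpose arrangement;
# "diagonal" is highpass in both directions.

#' Reflect-pad an image so both dimensions are multiples of a given number
#'
#' Pads by half-sample symmetric reflection (edge row/column repeated),
#' splitting the padding as evenly as possible between the two sides.
#' The returned record inverts the padding exactly via [crop_pad()].
#'
#' @param image numeric matrix.
#' @param multiple positive integer the padded dimensions must divide by.
#' @return list with `image` (padded matrix) and `pad` (a `pad_record`:
#'   original dimensions plus per-edge pad amounts).
#' @examples
#' p <- pad_to_multiple(matrix(0, 100, 100), 32)
#' dim(p$image)  # 128 x 128
#' @export
pad_to_multiple <- function(image, multiple) {
  stopifnot(is.matrix(image), is.numeric(image))
  multiple <- as.integer(multiple)
  if (is.na(multiple) || multiple < 1L) stop("'multiple' must be >= 1")
  h <- nrow(image); w <- ncol(image)
  H <- as.integer(ceiling(h / multiple) * multiple)
  W <- as.integer(ceiling(w / multiple) * multiple)
  pt <- (H - h) %/% 2L; pb <- H - h - pt
  pl <- (W - w) %/% 2L; pr <- W - w - pl
  reflect_idx <- function(n, before, after) {
    # half-sample symmetric: ... 2 1 | 1 2 ... n | n n-1 ...
    if (before > n || after > n) {
      stop("image too small to reflect-pad to a multiple of ", multiple)
    }
    c(if (before > 0) rev(seq_len(before)) else integer(0),
      seq_len(n),
      if (after > 0) n + 1L - seq_len(after) else integer(0))
  }
  ri <- reflect_idx(h, pt, pb)
  ci <- reflect_idx(w, pl, pr)
  out <- image[ri, ci, drop = FALSE]
  pad <- structure(
    list(original_height = h, original_width = w,
         pad_top = pt, pad_bottom = pb, pad_left = pl, pad_right = pr),
    class = "pad_record"
  )
  list(image = out, pad = pad)
}

#' Undo the padding applied by [pad_to_multiple()]
#'
#' @param image padded numeric matrix.
#' @param pad a `pad_record`.
#' @return the original-size matrix.
#' @export
crop_pad <- function(image, pad) {
  stopifnot(inherits(pad, "pad_record"))
  h <- pad$original_height; w <- pad$original_width
  if (nrow(image) != h + pad$pad_top + pad$pad_bottom ||
      ncol(image) != w + pad$pad_left + pad$pad_right) {
    stop("image dimensions do not match the pad record")
  }
  image[pad$pad_top + seq_len(h), pad$pad_left + seq_len(w), drop = FALSE]
}

#' Forward 2-D stationary wavelet transform
#'
#' Undecimated dyadic decomposition: at level j the analysis filters are
#' upsampled a-trous (2^(j-1)-1 zeros between taps) and applied with
#' periodic boundary extension, so every coefficient plane has the size of
#' the input and the transform commutes with circular shifts.
#'
#' @param image numeric matrix with both dimensions divisible by
#'   `2^levels`; use [pad_to_multiple()] first if they are not.
#' @param wavelet wavelet identifier resolved by [get_wavelet_filters()]
#'   (default `"db4"`).
#' @param levels decomposition depth L >= 1 (default 5).
#' @return An object of class `swt_coeffs`: `approx` (level-L approximation
#'   plane), `details` (list of levels 1..L, each with `horizontal`,
#'   `vertical`, `diagonal` planes), `levels`, `wavelet`.
#' @export
swt2_forward <- function(image, wavelet = "db4", levels = 5L) {
  stopifnot(is.matrix(image), is.numeric(image))
  levels <- as.integer(levels)
  if (levels < 1L) stop("'levels' must be >= 1")
  d <- 2L^levels
  if (nrow(image) %% d != 0L || ncol(image) %% d != 0L) {
    stop("image dimensions (", nrow(image), "x", ncol(image),
         ") must be divisible by 2^levels = ", d,
         "; pad first with pad_to_multiple()")
  }
  fb <- get_wavelet_filters(wavelet)
  lo <- fb$analysis_lowpass; hi <- fb$analysis_highpass
  a <- image
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    resp <- .swt_level_responses(lo, hi, nrow(a), ncol(a), 2L^(j - 1L))
    A <- stats::fft(a)
    n <- length(a)
    details[[j]] <- list(
      horizontal = Re(stats::fft(A * resp$hl, inverse = TRUE)) / n,
      vertical   = Re(stats::fft(A * resp$lh, inverse = TRUE)) / n,
      diagonal   = Re(stats::fft(A * resp$hh, inverse = TRUE)) / n
    )
    a <- Re(stats::fft(A * resp$ll, inverse = TRUE)) / n
  }
  structure(
    list(approx = a, details = details, levels = levels, wavelet = wavelet),
    class = "swt_coeffs"
  )
}

#' Inverse 2-D stationary wavelet transform
#'
#' Exact left-inverse of [swt2_forward()], using the adjoint (time-reversed)
#' filters: for an orthonormal pair the per-dimension responses satisfy
#' |Lo|^2 + |Hi|^2 = 2, so synthesis divides by 4 per 2-D level and the
#' round trip is exact to floating-point precision.
#'
#' @param coeffs an `swt_coeffs` object.
#' @return numeric matrix of the same size as the transformed image.
#' @export
swt2_inverse <- function(coeffs) {
  stopifnot(inherits(coeffs, "swt_coeffs"))
  fb <- get_wavelet_filters(coeffs$wavelet)
  lo <- fb$analysis_lowpass; hi <- fb$analysis_highpass
  a <- coeffs$approx
  sh <- dim(a)
  for (j in rev(seq_len(coeffs$levels))) {
    det <- coeffs$details[[j]]
    if (!all(vapply(det, function(p) identical(dim(p), sh), logical(1)))) {
      stop("inconsistent coefficient plane shapes at level ", j)
    }
    resp <- .swt_level_responses(lo, hi, nrow(a), ncol(a), 2L^(j - 1L))
    n <- length(a)
    S <- stats::fft(a) * Conj(resp$ll) +
      stats::fft(det$horizontal) * Conj(resp$hl) +
      stats::fft(det$vertical)   * Conj(resp$lh) +
      stats::fft(det$diagonal)   * Conj(resp$hh)
    a <- Re(stats::fft(S, inverse = TRUE)) / (4 * n)
  }
  a
}
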
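# Real 2-D dual-tree discrete wavelet transform.
#
# Two parallel critically-sampled orthonormal wavelet trees are run on the
# image; their filters are offset by (approximately) half a sample so that
# the pair is far less shift sensitive than either tree alone.  All
# coefficients are scaled by 1/sqrt(2), making the two trees jointly a
# tight frame: total coefficient energy equals image energy, and inversion
# averages the two per-tree reconstructions.
#
# Subband indexing follows the field's Wb{j}{s} notation: tree j in {1,2},
# orientation s in {1,2,3} with s = 1 horizontal (highpass down the
# columns), s = 2 vertical (highpass along the rows), s = 3 diagonal.

# 1-D periodic analysis along the columns of x: circular convolution with
# the filter followed by decimation by two.  Returns list(lo, hi), each
# with nrow(x)/2 rows.
.dwt_cols <- function(x, lo, hi) {
  n <- nrow(x)
  X <- stats::mvfft(x)
  FL <- .freq_response(lo, n)
  FH <- .freq_response(hi, n)
  cl <- Re(stats::mvfft(X * FL, inverse = TRUE)) / n
  ch <- Re(stats::mvfft(X * FH, inverse = TRUE)) / n
  keep <- seq(1L, n, by = 2L)
  list(lo = cl[keep, , drop = FALSE], hi = ch[keep, , drop = FALSE])
}

# Adjoint of .dwt_cols: upsample by two, then circular correlation.
.idwt_cols <- function(clo, chi, lo, hi) {
  n <- 2L * nrow(clo)
  up <- function(c0) {
    u <- matrix(0, n, ncol(c0))
    u[seq(1L, n, by = 2L), ] <- c0
    u
  }
  FL <- Conj(.freq_response(lo, n))
  FH <- Conj(.freq_response(hi, n))
  Re(stats::mvfft(stats::mvfft(up(clo)) * FL +
                  stats::mvfft(up(chi)) * FH, inverse = TRUE)) / n
}

# One separable 2-D analysis level for one tree.
.dwt2_level <- function(x, fb) {
  lo <- fb$analysis_lowpass; hi <- fb$analysis_highpass
  colpass <- .dwt_cols(x, lo, hi)
  ll_lh <- .dwt_cols(t(colpass$lo), lo, hi)   # rows of the col-lowpass
  hl_hh <- .dwt_cols(t(colpass$hi), lo, hi)   # rows of the col-highpass
  list(
    ll         = t(ll_lh$lo),
    vertical   = t(ll_lh$hi),  # lowpass cols, highpass rows
    horizontal = t(hl_hh$lo),  # highpass cols, lowpass rows
    diagonal   = t(hl_hh$hi)
  )
}

.idwt2_level <- function(bands, fb) {
  lo <- fb$analysis_lowpass; hi <- fb$analysis_highpass
  clo <- t(.idwt_cols(t(bands$ll), t(bands$vertical), lo, hi))
  chi <- t(.idwt_cols(t(bands$horizontal), t(bands$diagonal), lo, hi))
  .idwt_cols(clo, chi, lo, hi)
}

.dt_orientations <- c("horizontal", "vertical", "diagonal")

#' Forward real 2-D dual-tree wavelet transform
#'
#' Decomposes an image into the six directional highpass subbands
#' `Wb{j}{s}` (tree j = 1,2; orientation s = 1,2,3) per level, plus one
#' lowpass plane per tree.  With the default single level this is exactly
#' the six-subband decomposition the two-stage denoiser operates on.
#'
#' @param image numeric matrix; both dimensions divisible by `2^levels`.
#' @param levels number of decimation levels J >= 1 (default 1).
#' @param filters a `dualtree_filter_set` from [get_dualtree_filters()].
#' @return An object of class `dualtree_coeffs`: `highpass[[level]][[tree]]`
#'   is a list of `horizontal`, `vertical`, `diagonal` planes of size
#'   `(H/2^level, W/2^level)`; `lowpass[[tree]]` the two `(H/2^J, W/2^J)`
#'   approximation planes; plus `levels` and `source_shape`.
#' @export
dualtree2_forward <- function(image, levels = 1L,
                              filters = get_dualtree_filters()) {
  stopifnot(is.matrix(image), is.numeric(image),
            inherits(filters, "dualtree_filter_set"))
  levels <- as.integer(levels)
  if (levels < 1L) stop("'levels' must be >= 1")
  d <- 2L^levels
  if (nrow(image) %% d != 0L || ncol(image) %% d != 0L) {
    stop("image dimensions (", nrow(image), "x", ncol(image),
         ") must be divisible by 2^levels = ", d)
  }
  highpass <- vector("list", levels)
  lowpass <- vector("list", 2L)
  for (tree in 1:2) {
    a <- image / sqrt(2)  # tight-frame scaling shared by all coefficients
    for (lev in seq_len(levels)) {
      fb <- if (lev == 1L) {
        if (tree == 1L) filters$first_stage_tree1 else filters$first_stage_tree2
      } else {
        if (tree == 1L) filters$qshift_tree1 else filters$qshift_tree2
      }
      bands <- .dwt2_level(a, fb)
      if (is.null(highpass[[lev]])) highpass[[lev]] <- vector("list", 2L)
      highpass[[lev]][[tree]] <- bands[.dt_orientations]
      a <- bands$ll
    }
    lowpass[[tree]] <- a
  }
  structure(
    list(highpass = highpass, lowpass = lowpass, levels = levels,
         source_shape = dim(image)),
    class = "dualtree_coeffs"
  )
}

#' Inverse real 2-D dual-tree wavelet transform
#'
#' Runs the orthonormal synthesis of each tree and averages the two
#' reconstructions; with the 1/sqrt(2) tight-frame scaling of
#' [dualtree2_forward()] this is an exact inverse.
#'
#' @param coeffs a `dualtree_coeffs` object.
#' @param filters the same `dualtree_filter_set` used for analysis.
#' @return numeric matrix of shape `coeffs$source_shape`.
#' @export
dualtree2_inverse <- function(coeffs, filters = get_dualtree_filters()) {
  stopifnot(inherits(coeffs, "dualtree_coeffs"),
            inherits(filters, "dualtree_filter_set"))
  levels <- coeffs$levels
  out <- matrix(0, coeffs$source_shape[1], coeffs$source_shape[2])
  for (tree in 1:2) {
    a <- coeffs$lowpass[[tree]]
    for (lev in rev(seq_len(levels))) {
      bands <- coeffs$highpass[[lev]][[tree]]
      expect <- dim(a)
      for (p in bands) {
        if (!identical(dim(p), expect)) {
          stop("inconsistent subband shapes at level ", lev, ", tree ", tree)
        }
      }
      fb <- if (lev == 1L) {
        if (tree == 1L) filters$first_stage_tree1 else filters$first_stage_tree2
      } else {
        if (tree == 1L) filters$qshift_tree1 else filters$qshift_tree2
      }
      a <- .idwt2_level(c(list(ll = a), bands), fb)
    }
    out <- out + a / sqrt(2)
  }
  out
}

#' Per-subband energy vector of a dual-tree decomposition
#'
#' Sum of squared coefficients for every (level, tree, orientation)
#' highpass subband, in a fixed order; used to quantify shift sensitivity.
#'
#' @param coeffs a `dualtree_coeffs` object.
#' @param include_lowpass also append the two lowpass energies.
#' @return named numeric vector.
#' @export
dualtree2_energy <- function(coeffs, include_lowpass = FALSE) {
  stopifnot(inherits(coeffs, "dualtree_coeffs"))
  out <- c()
  for (lev in seq_len(coeffs$levels)) {
    for (tree in 1:2) {
      for (s in seq_along(.dt_orientations)) {
        nm <- sprintf("L%d.t%d.%s", lev, tree, .dt_orientations[s])
        out[nm] <- sum(coeffs$highpass[[lev]][[tree]][[s]]^2)
      }
    }
  }
  if (include_lowpass) {
    for (tree in 1:2) {
      out[sprintf("low.t%d", tree)] <- sum(coeffs$lowpass[[tree]]^2)
    }
  }
  out
}
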
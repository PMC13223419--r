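# The four denoising methods under comparison.
#
# denoise_swt2d    : soft thresholding of all detail planes of a 5-level
#                    db4 stationary wavelet decomposition (the classical
#                    single-stage scheme).
# denoise_proposed : two-stage composition -- a one-level real dual-tree
#                    DWT splits the image into six directional highpass
#                    subbands Wb{j}{s}; each subband is treated as an image
#                    in its own right and run through denoise_swt2d,
#                    giving Wd{j}{s}; the inverse dual-tree transform of
#                    the denoised subbands is the output.
# denoise_dt_soft  : soft thresholding applied directly to the dual-tree
#                    highpass planes (no inner SWT stage).
# denoise_nlm      : patch-based non-local means averaging.

#' Denoising configuration
#'
#' @param wavelet wavelet for the SWT stage (default `"db4"`).
#' @param swt_levels SWT decomposition depth (default 5).
#' @param dt_levels dual-tree decomposition depth (default 1, i.e. exactly
#'   the six subbands Wb{j}{s}).
#' @param dt_filters dual-tree filter-set identifier.
#' @param threshold a [threshold_rule()]; default universal + MAD with
#'   multiplier 1.
#' @param lowpass_policy `"passthrough"` (default) leaves the dual-tree
#'   lowpass planes untouched; `"denoise"` runs them through the SWT
#'   denoiser as well.
#' @param clip_range optional `c(min, max)` applied to the final output;
#'   `NULL` disables clipping.
#' @return object of class `denoise_config`.
#' @export
denoise_config <- function(wavelet = "db4",
                           swt_levels = 5L,
                           dt_levels = 1L,
                           dt_filters = "farras+qshift10",
                           threshold = threshold_rule(),
                           lowpass_policy = c("passthrough", "denoise"),
                           clip_range = c(0, 255)) {
  lowpass_policy <- match.arg(lowpass_policy)
  swt_levels <- as.integer(swt_levels)
  dt_levels <- as.integer(dt_levels)
  if (swt_levels < 1L || dt_levels < 1L) {
    stop("'swt_levels' and 'dt_levels' must be >= 1")
  }
  stopifnot(inherits(threshold, "threshold_rule"))
  if (!is.null(clip_range)) {
    stopifnot(is.numeric(clip_range), length(clip_range) == 2,
              clip_range[1] < clip_range[2])
  }
  structure(
    list(wavelet = wavelet, swt_levels = swt_levels, dt_levels = dt_levels,
         dt_filters = dt_filters, threshold = threshold,
         lowpass_policy = lowpass_policy, clip_range = clip_range),
    class = "denoise_config"
  )
}

.as_gray_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("input must be a single-channel numeric matrix ",
         "(convert multi-channel images with read_image())")
  }
  storage.mode(x) <- "double"
  x
}

.clip <- function(x, range) {
  if (is.null(range)) x else pmin(pmax(x, range[1]), range[2])
}

# SWT-threshold core without padding/clipping, reused on dual-tree subbands.
.swt_threshold_core <- function(image, config) {
  co <- swt2_forward(image, config$wavelet, config$swt_levels)
  # sigma reference: level-1 diagonal detail of this decomposition
  ref <- co$details[[1]]$diagonal
  for (j in seq_len(co$levels)) {
    for (o in c("horizontal", "vertical", "diagonal")) {
      plane <- co$details[[j]][[o]]
      t <- resolve_threshold(config$threshold, plane, ref)
      co$details[[j]][[o]] <- soft_threshold(plane, t)
    }
  }
  swt2_inverse(co)
}

#' Denoise by soft thresholding in the stationary wavelet domain
#'
#' Pads the image to a multiple of `2^swt_levels`, decomposes with the
#' undecimated db4 transform, soft-thresholds every detail plane at every
#' level (the approximation is untouched), inverts, crops, and optionally
#' clips.
#'
#' @param noisy single-channel numeric matrix.
#' @param config a [denoise_config()].
#' @return denoised matrix with the shape of `noisy`.
#' @export
denoise_swt2d <- function(noisy, config = denoise_config()) {
  noisy <- .as_gray_matrix(noisy)
  stopifnot(inherits(config, "denoise_config"))
  p <- pad_to_multiple(noisy, 2L^config$swt_levels)
  out <- crop_pad(.swt_threshold_core(p$image, config), p$pad)
  .clip(out, config$clip_range)
}

#' Denoise by stationary-wavelet thresholding of dual-tree subbands
#'
#' The two-stage scheme: a `dt_levels`-deep real dual-tree DWT produces the
#' directional subbands Wb{j}{s}; each highpass subband is then denoised as
#' an image by the SWT soft-thresholding scheme (yielding Wd{j}{s}); the
#' lowpass planes follow `lowpass_policy`; the inverse dual-tree transform
#' reconstructs the image.
#'
#' @inheritParams denoise_swt2d
#' @return denoised matrix with the shape of `noisy`.
#' @export
denoise_proposed <- function(noisy, config = denoise_config()) {
  noisy <- .as_gray_matrix(noisy)
  stopifnot(inherits(config, "denoise_config"))
  # after J decimations each subband must still divide by 2^swt_levels
  mult <- 2L^(config$dt_levels + config$swt_levels)
  p <- pad_to_multiple(noisy, mult)
  filters <- get_dualtree_filters(config$dt_filters)
  co <- dualtree2_forward(p$image, config$dt_levels, filters)
  sub_dim <- dim(co$highpass[[config$dt_levels]][[1]][[1]])
  if (any(sub_dim %% 2L^config$swt_levels != 0L)) {
    stop("dual-tree subbands of size ", sub_dim[1], "x", sub_dim[2],
         " are not divisible by 2^swt_levels; reduce swt_levels or pad more")
  }
  for (lev in seq_len(co$levels)) {
    for (tree in 1:2) {
      for (o in c("horizontal", "vertical", "diagonal")) {
        co$highpass[[lev]][[tree]][[o]] <-
          .swt_threshold_core(co$highpass[[lev]][[tree]][[o]], config)
      }
    }
  }
  if (config$lowpass_policy == "denoise") {
    for (tree in 1:2) {
      co$lowpass[[tree]] <- .swt_threshold_core(co$lowpass[[tree]], config)
    }
  }
  out <- crop_pad(dualtree2_inverse(co, filters), p$pad)
  .clip(out, config$clip_range)
}

#' Denoise by soft thresholding directly in the dual-tree domain
#'
#' Each highpass plane of the dual-tree decomposition is soft-thresholded
#' with its own resolved threshold (sigma estimated from the plane itself
#' under the default MAD rule); lowpass planes pass through.
#'
#' @inheritParams denoise_swt2d
#' @return denoised matrix with the shape of `noisy`.
#' @export
denoise_dt_soft <- function(noisy, config = denoise_config()) {
  noisy <- .as_gray_matrix(noisy)
  stopifnot(inherits(config, "denoise_config"))
  p <- pad_to_multiple(noisy, 2L^config$dt_levels)
  filters <- get_dualtree_filters(config$dt_filters)
  co <- dualtree2_forward(p$image, config$dt_levels, filters)
  for (lev in seq_len(co$levels)) {
    for (tree in 1:2) {
      for (o in c("horizontal", "vertical", "diagonal")) {
        plane <- co$highpass[[lev]][[tree]][[o]]
        t <- resolve_threshold(config$threshold, plane)
        co$highpass[[lev]][[tree]][[o]] <- soft_threshold(plane, t)
      }
    }
  }
  out <- crop_pad(dualtree2_inverse(co, filters), p$pad)
  .clip(out, config$clip_range)
}

# circular shift of a matrix by (dr, dc)
.circshift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  dr <- ((dr %% nr) + nr) %% nr
  dc <- ((dc %% nc) + nc) %% nc
  if (dr > 0) m <- m[c((nr - dr + 1):nr, 1:(nr - dr)), , drop = FALSE]
  if (dc > 0) m <- m[, c((nc - dc + 1):nc, 1:(nc - dc)), drop = FALSE]
  m
}

# circular box sum over a k x k window via cumulative sums
.box_mean_circ <- function(m, k) {
  r <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  # pad circularly by r on all sides, then summed-area table
  mi <- m[c((nr - r + 1):nr, 1:nr, 1:r), c((nc - r + 1):nc, 1:nc, 1:r)]
  cs <- apply(apply(mi, 2, cumsum), 1, cumsum)  # transposed SAT
  cs <- t(cs)
  sat <- matrix(0, nrow(mi) + 1, ncol(mi) + 1)
  sat[-1, -1] <- cs
  i0 <- seq_len(nr); j0 <- seq_len(nc)
  (sat[i0 + 2 * r + 1, j0 + 2 * r + 1, drop = FALSE] -
     sat[i0, j0 + 2 * r + 1, drop = FALSE] -
     sat[i0 + 2 * r + 1, j0, drop = FALSE] +
     sat[i0, j0, drop = FALSE]) / (k * k)
}

#' Non-local means denoising
#'
#' Each pixel is replaced by a weighted average of pixels in a square
#' search window, the weight of a candidate being
#' `exp(-d^2 / h^2)` where `d^2` is the mean squared difference between
#' the two pixels' surrounding patches; weights are normalized to sum to
#' one.  Patch comparison uses circular boundary handling.
#'
#' @param noisy single-channel numeric matrix.
#' @param patch_size odd patch side length (default 7).
#' @param search_window odd search-window side length (default 21), must
#'   exceed `patch_size`.
#' @param h filtering bandwidth; `NULL` (default) sets `h = 0.8 * sigma`
#'   with sigma estimated by [mad_sigma()] from the level-1 diagonal plane
#'   of a one-level db4 SWT of the input.
#' @return denoised matrix with the shape of `noisy`.
#' @export
denoise_nlm <- function(noisy, patch_size = 7L, search_window = 21L,
                        h = NULL) {
  noisy <- .as_gray_matrix(noisy)
  patch_size <- as.integer(patch_size)
  search_window <- as.integer(search_window)
  if (patch_size %% 2L == 0L || search_window %% 2L == 0L) {
    stop("'patch_size' and 'search_window' must be odd")
  }
  if (patch_size >= search_window) {
    stop("'patch_size' must be smaller than 'search_window'")
  }
  if (is.null(h)) {
    p <- pad_to_multiple(noisy, 2L)
    ref <- swt2_forward(p$image, "db4", 1L)$details[[1]]$diagonal
    h <- 0.8 * mad_sigma(ref)
    # a zero estimate means a noise-free image: nothing to average away
    if (h == 0) return(noisy)
  }
  if (h <= 0) stop("'h' must be positive")
  r <- (search_window - 1L) %/% 2L
  wsum <- matrix(0, nrow(noisy), ncol(noisy))
  acc <- matrix(0, nrow(noisy), ncol(noisy))
  for (dr in -r:r) {
    for (dc in -r:r) {
      shifted <- .circshift(noisy, dr, dc)
      d2 <- .box_mean_circ((noisy - shifted)^2, patch_size)
      w <- exp(-d2 / h^2)
      wsum <- wsum + w
      acc <- acc + w * shifted
    }
  }
  acc / wsum
}
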
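# Threshold functions and noise-level estimation.
#
# The denoisers shrink wavelet detail coefficients by soft thresholding.
# The threshold itself follows the universal (VisuShrink) rule
# t = sigma * sqrt(2 log n) by default, with sigma either supplied or
# estimated robustly by the median absolute deviation of a level-1
# detail plane.

#' Soft thresholding
#'
#' Elementwise shrinkage `sign(x) * max(|x| - t, 0)`: coefficients inside
#' the dead zone `[-t, t]` are set to zero, the rest are pulled toward
#' zero by `t`.  Continuous in `x`, unlike hard thresholding.
#'
#' @param x numeric vector, matrix or array.
#' @param t non-negative threshold.
#' @return object of the same shape as `x`.
#' @examples
#' soft_threshold(c(-3, -0.5, 0.5, 3), 1)  # -2 0 0 2
#' @export
soft_threshold <- function(x, t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0) {
    stop("threshold 't' must be a single non-negative number")
  }
  sign(x) * pmax(abs(x) - t, 0)
}

#' Robust noise standard deviation from a detail plane
#'
#' The classical median-absolute-deviation estimator
#' `median(|d|) / 0.6745`, consistent for the standard deviation of
#' zero-mean Gaussian noise and insensitive to the sparse signal
#' coefficients that share the plane.
#'
#' @param detail numeric vector or matrix of detail coefficients.
#' @return non-negative scalar estimate of sigma.
#' @export
mad_sigma <- function(detail) {
  if (length(detail) == 0) stop("'detail' must be nonempty")
  stats::median(abs(as.numeric(detail))) / 0.6745
}

#' Universal (VisuShrink) threshold
#'
#' `t = sigma * sqrt(2 log n)`, the asymptotically minimax threshold for
#' n i.i.d. Gaussian coefficients.
#'
#' @param sigma non-negative noise standard deviation.
#' @param n number of coefficients (>= 1).
#' @return non-negative threshold.
#' @export
universal_threshold <- function(sigma, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("'n' must be >= 1")
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    stop("'sigma' must be a single non-negative number")
  }
  sigma * sqrt(2 * log(n))
}

#' Describe a shrinkage policy
#'
#' Bundles the decisions that turn a detail plane into a threshold value:
#' which rule to use, where the noise sigma comes from, and an overall
#' multiplier.
#'
#' @param rule `"universal"` (VisuShrink) or `"fixed"`.
#' @param sigma_mode `"mad"` (estimate sigma by [mad_sigma()] from a
#'   reference detail plane) or `"known"` (use `sigma_value`).
#' @param sigma_value noise standard deviation when `sigma_mode = "known"`.
#' @param multiplier positive scale applied to the resolved threshold.
#' @param fixed_value threshold used when `rule = "fixed"`.
#' @return object of class `threshold_rule`.
#' @export
threshold_rule <- function(rule = c("universal", "fixed"),
                           sigma_mode = c("mad", "known"),
                           sigma_value = NULL,
                           multiplier = 1.0,
                           fixed_value = NULL) {
  rule <- match.arg(rule)
  sigma_mode <- match.arg(sigma_mode)
  if (!is.numeric(multiplier) || multiplier <= 0) {
    stop("'multiplier' must be positive")
  }
  if (!is.null(sigma_value) && sigma_value < 0) {
    stop("'sigma_value' must be non-negative")
  }
  if (!is.null(fixed_value) && fixed_value < 0) {
    stop("'fixed_value' must be non-negative")
  }
  structure(
    list(rule = rule, sigma_mode = sigma_mode, sigma_value = sigma_value,
         multiplier = multiplier, fixed_value = fixed_value),
    class = "threshold_rule"
  )
}

#' Resolve a shrinkage policy to a numeric threshold
#'
#' @param rule a `threshold_rule`.
#' @param subband the plane about to be thresholded (its size is the `n`
#'   of the universal rule).
#' @param reference_detail plane from which sigma is estimated when
#'   `sigma_mode = "mad"`; defaults to `subband` itself.
#' @return non-negative threshold value.
#' @export
resolve_threshold <- function(rule, subband, reference_detail = subband) {
  stopifnot(inherits(rule, "threshold_rule"))
  t <- switch(rule$rule,
    fixed = {
      if (is.null(rule$fixed_value)) stop("fixed rule requires 'fixed_value'")
      rule$fixed_value
    },
    universal = {
      sigma <- switch(rule$sigma_mode,
        known = {
          if (is.null(rule$sigma_value)) {
            stop("sigma_mode 'known' requires 'sigma_value'")
          }
          rule$sigma_value
        },
        mad = mad_sigma(reference_detail)
      )
      universal_threshold(sigma, length(subband))
    }
  )
  t * rule$multiplier
}
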
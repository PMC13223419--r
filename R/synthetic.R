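# MRI-like phantoms and corruption models.
#
# Real MR test images cannot ship with the package, so experiments run on
# deterministic phantoms: a piecewise-constant overlapping-ellipse "brain"
# (sharp boundaries, several tissue-like gray levels) and a textured
# phantom with oriented sinusoids and hard edges that exercises the
# directional subbands.  Corruption models are additive Gaussian white
# noise of a given sigma on the 0-255 scale, salt-and-pepper impulses,
# and Poisson shot noise.

#' Deterministic MRI-like test phantom
#'
#' @param height,width image dimensions, each >= 64.
#' @param kind `"ellipses"` for a piecewise-constant overlapping-ellipse
#'   brain-like phantom; `"texture"` for a smooth background with oriented
#'   sinusoidal texture and sharp edges.
#' @return numeric matrix with values in `[0, 255]`; calling twice with the
#'   same arguments gives bit-identical output.
#' @examples
#' ph <- make_phantom(256, 256, "ellipses")
#' range(ph)
#' @export
make_phantom <- function(height, width, kind = c("ellipses", "texture")) {
  kind <- match.arg(kind)
  height <- as.integer(height); width <- as.integer(width)
  if (height < 64L || width < 64L) {
    stop("phantom dimensions must be at least 64x64")
  }
  # normalized coordinates in [-1, 1]
  y <- (2 * (seq_len(height) - 0.5) / height) - 1
  x <- (2 * (seq_len(width) - 0.5) / width) - 1
  Y <- matrix(y, height, width)
  X <- matrix(x, height, width, byrow = TRUE)
  if (kind == "ellipses") {
    img <- matrix(0, height, width)
    inside <- function(cx, cy, a, b, phi) {
      ct <- cos(phi); st <- sin(phi)
      xr <- (X - cx) * ct + (Y - cy) * st
      yr <- -(X - cx) * st + (Y - cy) * ct
      (xr / a)^2 + (yr / b)^2 <= 1
    }
    # (cx, cy, a, b, angle, gray): later rows overwrite earlier ones,
    # keeping the phantom piecewise constant.
    spec <- rbind(
      c( 0.00,  0.00, 0.86, 0.92, 0.0, 230),  # skull
      c( 0.00,  0.00, 0.78, 0.85, 0.0, 120),  # brain tissue
      c( 0.00, -0.12, 0.16, 0.38, 0.0,  45),  # left-ish ventricle pair
      c(-0.22,  0.00, 0.14, 0.30, 0.3,  60),
      c( 0.22,  0.00, 0.14, 0.30, -0.3, 60),
      c( 0.00,  0.38, 0.20, 0.14, 0.0, 175),  # bright lesion
      c(-0.30, -0.40, 0.10, 0.07, 0.6, 200),
      c( 0.32, -0.38, 0.08, 0.10, -0.5, 90),
      c( 0.00, -0.62, 0.28, 0.10, 0.0, 150)
    )
    for (k in seq_len(nrow(spec))) {
      m <- inside(spec[k, 1], spec[k, 2], spec[k, 3], spec[k, 4], spec[k, 5])
      img[m] <- spec[k, 6]
    }
    img
  } else {
    # smooth radial background + two oriented sinusoids + hard edges
    img <- 110 + 70 * exp(-(X^2 + Y^2) / 0.55)
    band1 <- abs(Y) < 0.55
    img <- img + band1 * 45 * sin(2 * pi * (8 * X + 20 * Y))
    band2 <- X > 0.1
    img <- img + band2 * 30 * sin(2 * pi * 14 * Y)
    img <- img + 50 * (X + Y > 0.9)          # diagonal step
    img[Y < -0.8] <- 25                       # hard horizontal stripe
    pmin(pmax(img, 0), 255)
  }
}

#' Describe a corruption model
#'
#' @param kind `"gaussian"`, `"salt_pepper"`, or `"poisson"`.
#' @param sigma Gaussian noise standard deviation on the 0-255 scale.
#' @param density fraction of pixels hit by salt-and-pepper impulses.
#' @param scale Poisson gain: the image is divided by `scale`, Poisson
#'   sampled, and multiplied back, so smaller `scale` means less noise.
#' @param seed integer seed making the corruption reproducible.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("gaussian", "salt_pepper", "poisson"),
                       sigma = 20, density = 0.05, scale = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "gaussian" && (!is.numeric(sigma) || sigma < 0)) {
    stop("'sigma' must be non-negative")
  }
  if (kind == "salt_pepper" && (density < 0 || density > 1)) {
    stop("'density' must be in [0, 1]")
  }
  if (kind == "poisson" && scale <= 0) stop("'scale' must be positive")
  structure(
    list(kind = kind, sigma = sigma, density = density, scale = scale,
         seed = as.integer(seed)),
    class = "noise_spec"
  )
}

#' Corrupt an image with a specified noise model
#'
#' Gaussian noise is added in floating point without clipping, so the
#' nominal sigma stays exactly interpretable; any clipping is left to the
#' consumer.  Randomness uses R's Mersenne-Twister stream seeded from
#' `spec$seed`, so the same spec always yields the same corruption.
#'
#' @param image numeric matrix.
#' @param spec a `noise_spec`.
#' @return corrupted matrix of the same shape.
#' @export
corrupt <- function(image, spec) {
  stopifnot(is.matrix(image), inherits(spec, "noise_spec"))
  # restore the caller's RNG state afterwards
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(spec$seed)
  out <- switch(spec$kind,
    gaussian = {
      if (spec$sigma == 0) image
      else image + matrix(stats::rnorm(length(image), sd = spec$sigma),
                          nrow(image))
    },
    salt_pepper = {
      n <- length(image)
      hit <- stats::runif(n) < spec$density
      salt <- stats::runif(n) < 0.5
      out <- image
      out[hit & salt] <- 255
      out[hit & !salt] <- 0
      out
    },
    poisson = {
      lam <- pmax(image, 0) / spec$scale
      matrix(stats::rpois(length(lam), lam), nrow(image)) * spec$scale
    }
  )
  out
}
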
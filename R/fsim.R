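# Feature similarity index (FSIM).
#
# FSIM compares two images through two low-level feature maps: phase
# congruency (PC), which marks points where the local Fourier components
# are maximally in phase (edges, lines) regardless of contrast, and the
# gradient magnitude (GM).  The pixelwise similarity
#   S(x) = S_PC(x) * S_G(x)
# is pooled with weights max(PC1, PC2), so agreement matters most where
# either image shows a salient feature.
#
# Constants below are the published defaults for the 0-255 dynamic range:
# log-Gabor bank with 4 scales and 4 orientations, smallest wavelength 6,
# scale multiplier 2, sigma_onf 0.55, angular spread sigma pi/4/1.2;
# Scharr 3x3 gradients; stability constants T1 = 0.85 (PC) and T2 = 160
# (gradient).

.fsim_const <- list(
  nscale = 4L, norient = 4L, min_wavelength = 6, mult = 2,
  sigma_onf = 0.55, d_theta_on_sigma = 1.2, k = 2.0, epsilon = 1e-4,
  cutoff = 0.45, sharpness = 15L,    # lowpass that caps the largest filters
  T1 = 0.85, T2 = 160
)

# Centered frequency coordinates in ifftshift order for an n-point axis.
.freq_axis <- function(n) {
  if (n %% 2L == 0L) {
    r <- (seq_len(n) - 1L - n / 2) / n
  } else {
    r <- (seq_len(n) - 1L - (n - 1L) / 2) / n
  }
  # ifftshift: move DC to the first element
  half <- ceiling(n / 2) + 1L
  c(r[half:n], r[seq_len(half - 1L)])
}

# Log-Gabor x angular-spread filter bank in the frequency domain.
.fsim_filter_bank <- function(nr, nc) {
  cst <- .fsim_const
  u <- .freq_axis(nc)  # along rows (x)
  v <- .freq_axis(nr)  # down columns (y)
  X <- matrix(u, nr, nc, byrow = TRUE)
  Y <- matrix(v, nr, nc)
  radius <- sqrt(X^2 + Y^2)
  radius[1, 1] <- 1
  theta <- atan2(-Y, X)
  lp <- 1 / (1 + (radius / cst$cutoff)^(2 * cst$sharpness))
  log_gabor <- vector("list", cst$nscale)
  for (s in seq_len(cst$nscale)) {
    fo <- 1 / (cst$min_wavelength * cst$mult^(s - 1))
    g <- exp(-(log(radius / fo))^2 / (2 * log(cst$sigma_onf)^2)) * lp
    g[1, 1] <- 0
    log_gabor[[s]] <- g
  }
  theta_sigma <- pi / cst$norient / cst$d_theta_on_sigma
  spread <- vector("list", cst$norient)
  st <- sin(theta); ct <- cos(theta)
  for (o in seq_len(cst$norient)) {
    angl <- (o - 1) * pi / cst$norient
    ds <- st * cos(angl) - ct * sin(angl)
    dc <- ct * cos(angl) + st * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread[[o]] <- exp(-dtheta^2 / (2 * theta_sigma^2))
  }
  list(log_gabor = log_gabor, spread = spread)
}

# Phase congruency map (moment-free variant used for feature similarity):
# for each orientation, energy is the component of the scale responses
# aligned with the locally dominant phase, noise-compensated by a
# Rayleigh-statistics threshold estimated from the smallest-scale
# amplitudes; the map is summed energy over summed amplitude.
.phase_congruency <- function(image, bank = NULL) {
  cst <- .fsim_const
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(bank)) bank <- .fsim_filter_bank(nr, nc)
  IM <- stats::fft(image)
  energy_all <- matrix(0, nr, nc)
  an_all <- matrix(0, nr, nc)
  for (o in seq_len(cst$norient)) {
    sumE <- matrix(0, nr, nc); sumO <- matrix(0, nr, nc)
    sumAn <- matrix(0, nr, nc)
    EOs <- vector("list", cst$nscale)
    tau <- NULL
    for (s in seq_len(cst$nscale)) {
      filt <- bank$log_gabor[[s]] * bank$spread[[o]]
      EO <- stats::fft(IM * filt, inverse = TRUE) / length(image)
      EOs[[s]] <- EO
      An <- Mod(EO)
      sumAn <- sumAn + An
      sumE <- sumE + Re(EO)
      sumO <- sumO + Im(EO)
      if (s == 1L) tau <- stats::median(An) / sqrt(log(4))
    }
    x_energy <- sqrt(sumE^2 + sumO^2) + cst$epsilon
    meanE <- sumE / x_energy
    meanO <- sumO / x_energy
    energy <- matrix(0, nr, nc)
    for (s in seq_len(cst$nscale)) {
      E <- Re(EOs[[s]]); O <- Im(EOs[[s]])
      energy <- energy + E * meanE + O * meanO - abs(E * meanO - O * meanE)
    }
    # noise compensation: expected Rayleigh energy of the filter responses
    total_tau <- tau * (1 - (1 / cst$mult)^cst$nscale) / (1 - 1 / cst$mult)
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sigma <- total_tau * sqrt((4 - pi) / 2)
    Tn <- (noise_mean + cst$k * noise_sigma) / 1.7
    energy <- pmax(energy - Tn, 0)
    energy_all <- energy_all + energy
    an_all <- an_all + sumAn
  }
  energy_all / (an_all + cst$epsilon)
}

# Scharr gradient magnitude, zero-padded 'same' convolution.
.gradient_magnitude <- function(image) {
  kx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16  # d/dx
  pad <- function(m) {
    z <- matrix(0, nrow(m) + 2, ncol(m) + 2)
    z[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    z
  }
  p <- pad(image)
  nr <- nrow(image); nc <- ncol(image)
  conv3 <- function(k) {
    out <- matrix(0, nr, nc)
    for (a in 1:3) for (b in 1:3) {
      out <- out + k[a, b] * p[(4 - a):(4 - a + nr - 1), (4 - b):(4 - b + nc - 1)]
    }
    out
  }
  gx <- conv3(kx)
  gy <- conv3(t(kx))
  sqrt(gx^2 + gy^2)
}

#' Feature similarity index
#'
#' Combines phase-congruency similarity and gradient-magnitude similarity,
#' pooled with `max(PC1, PC2)` weights (the published defaults for
#' grayscale images on the 0-255 range).  Inputs with a different `peak`
#' are rescaled to 0-255 first.  Images larger than about 256 pixels on
#' the short side are pre-smoothed and subsampled by the standard integer
#' factor `max(1, round(min(H, W) / 256))`.
#'
#' @param reference,test numeric matrices of the same shape, both
#'   dimensions at least 32.
#' @param peak dynamic range of the inputs (default 255).
#' @return scalar in `(0, 1]`.
#' @export
fsim <- function(reference, test, peak = 255) {
  if (!identical(dim(reference), dim(test))) {
    stop("'reference' and 'test' must have identical dimensions")
  }
  if (min(dim(reference)) < 32) {
    stop("images must be at least 32x32 for FSIM")
  }
  cst <- .fsim_const
  if (peak != 255) {
    reference <- reference * (255 / peak)
    test <- test * (255 / peak)
  }
  F <- max(1L, as.integer(round(min(dim(reference)) / 256)))
  if (F > 1L) {
    down <- function(m) {
      nr <- (nrow(m) %/% F) * F; nc <- (ncol(m) %/% F) * F
      m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
      # F x F block average, then subsample
      rg <- (rep(seq_len(nr %/% F), each = F))
      cg <- (rep(seq_len(nc %/% F), each = F))
      t(rowsum(t(rowsum(m, rg)), cg)) / (F * F)
    }
    reference <- down(reference)
    test <- down(test)
  }
  bank <- .fsim_filter_bank(nrow(reference), ncol(reference))
  pc1 <- .phase_congruency(reference, bank)
  pc2 <- .phase_congruency(test, bank)
  g1 <- .gradient_magnitude(reference)
  g2 <- .gradient_magnitude(test)
  s_pc <- (2 * pc1 * pc2 + cst$T1) / (pc1^2 + pc2^2 + cst$T1)
  s_g <- (2 * g1 * g2 + cst$T2) / (g1^2 + g2^2 + cst$T2)
  pcm <- pmax(pc1, pc2)
  sum(s_pc * s_g * pcm) / sum(pcm)
}
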
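# Shared fixtures and independent oracles used across the suite.

# deterministic random matrix
rmat <- function(nr, nc = nr, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nr * nc), nr, nc)
}

quick_psnr <- function(ref, test, peak = 255) 10 * log10(peak^2 / mean((ref - test)^2))

circshift2 <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  dr <- ((dr %% nr) + nr) %% nr; dc <- ((dc %% nc) + nc) %% nc
  if (dr > 0) m <- m[c((nr - dr + 1):nr, 1:(nr - dr)), , drop = FALSE]
  if (dc > 0) m <- m[, c((nc - dc + 1):nc, 1:(nc - dc)), drop = FALSE]
  m
}

# Independently transcribed published Daubechies-4 lowpass taps
# (Daubechies, "Ten Lectures on Wavelets", Table 6.1, h/sqrt(2) convention
# rescaled so the taps sum to sqrt(2)).
DB4_PUBLISHED_LO <- c(
  0.2303778133088552, 0.7148465705529154, 0.6308807679298587,
  -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
  0.0328830116668852, -0.0105974017850690
)

# One-level critically sampled single-tree 2-D DWT (independent comparator
# for shift-sensitivity tests): plain matrix implementation, periodic.
single_tree_dwt2 <- function(x, lo, hi, levels = 1) {
  analyze_cols <- function(m, f) {
    n <- nrow(m); L <- length(f)
    out <- matrix(0, n / 2, ncol(m))
    for (i in seq_len(n / 2)) {
      idx <- ((2 * (i - 1) + seq_len(L) - 1) %% n) + 1
      out[i, ] <- colSums(f * m[idx, , drop = FALSE])
    }
    out
  }
  energies <- c()
  a <- x
  for (lev in seq_len(levels)) {
    cl <- analyze_cols(a, lo); ch <- analyze_cols(a, hi)
    ll <- t(analyze_cols(t(cl), lo)); lh <- t(analyze_cols(t(cl), hi))
    hl <- t(analyze_cols(t(ch), lo)); hh <- t(analyze_cols(t(ch), hi))
    energies <- c(energies, sum(hl^2), sum(lh^2), sum(hh^2))
    a <- ll
  }
  energies
}

# Loop-based SSIM oracle: direct evaluation of the windowed formula,
# one window at a time.
ssim_loop <- function(ref, test, peak = 255) {
  w <- 11L; sigma <- 1.5
  g <- outer(
    exp(-((1:w) - 6)^2 / (2 * sigma^2)),
    exp(-((1:w) - 6)^2 / (2 * sigma^2))
  )
  g <- g / sum(g)
  C1 <- (0.01 * peak)^2; C2 <- (0.03 * peak)^2
  nr <- nrow(ref) - w + 1L; nc <- ncol(ref) - w + 1L
  total <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      a <- ref[i:(i + w - 1L), j:(j + w - 1L)]
      b <- test[i:(i + w - 1L), j:(j + w - 1L)]
      mu1 <- sum(g * a); mu2 <- sum(g * b)
      s1 <- sum(g * a * a) - mu1^2
      s2 <- sum(g * b * b) - mu2^2
      s12 <- sum(g * a * b) - mu1 * mu2
      total <- total + ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
        ((mu1^2 + mu2^2 + C1) * (s1 + s2 + C2))
    }
  }
  total / (nr * nc)
}

# Loop-based FSIM oracle: the log-Gabor bank is rebuilt with scalar loops,
# gradients and the similarity pooling are evaluated pixel by pixel.
fsim_loop <- function(ref, test, peak = 255) {
  if (peak != 255) { ref <- ref * 255 / peak; test <- test * 255 / peak }
  nr <- nrow(ref); nc <- ncol(ref)
  freq_axis <- function(n) {
    r <- if (n %% 2 == 0) ((0:(n - 1)) - n / 2) / n else ((0:(n - 1)) - (n - 1) / 2) / n
    half <- ceiling(n / 2) + 1
    c(r[half:n], r[1:(half - 1)])
  }
  u <- freq_axis(nc); v <- freq_axis(nr)
  pc_map <- function(im) {
    IM <- stats::fft(im)
    energy_all <- matrix(0, nr, nc); an_all <- matrix(0, nr, nc)
    for (o in 1:4) {
      angl <- (o - 1) * pi / 4
      sumE <- matrix(0, nr, nc); sumO <- matrix(0, nr, nc)
      sumAn <- matrix(0, nr, nc); EOs <- vector("list", 4)
      tau <- NA
      for (s in 1:4) {
        filt <- matrix(0, nr, nc)
        fo <- 1 / (6 * 2^(s - 1))
        for (i in 1:nr) for (j in 1:nc) {
          rad <- sqrt(u[j]^2 + v[i]^2)
          if (rad == 0) { filt[i, j] <- 0; next }
          lg <- exp(-(log(rad / fo))^2 / (2 * log(0.55)^2)) /
            (1 + (rad / 0.45)^30)
          th <- atan2(-v[i], u[j])
          ds <- sin(th) * cos(angl) - cos(th) * sin(angl)
          dc <- cos(th) * cos(angl) + sin(th) * sin(angl)
          dth <- abs(atan2(ds, dc))
          filt[i, j] <- lg * exp(-dth^2 / (2 * (pi / 4 / 1.2)^2))
        }
        EO <- stats::fft(IM * filt, inverse = TRUE) / (nr * nc)
        EOs[[s]] <- EO
        An <- Mod(EO)
        sumAn <- sumAn + An; sumE <- sumE + Re(EO); sumO <- sumO + Im(EO)
        if (s == 1) tau <- stats::median(An) / sqrt(log(4))
      }
      xe <- sqrt(sumE^2 + sumO^2) + 1e-4
      mE <- sumE / xe; mO <- sumO / xe
      energy <- matrix(0, nr, nc)
      for (s in 1:4) {
        E <- Re(EOs[[s]]); O <- Im(EOs[[s]])
        energy <- energy + E * mE + O * mO - abs(E * mO - O * mE)
      }
      tt <- tau * (1 - (1 / 2)^4) / (1 - 1 / 2)
      Tn <- (tt * sqrt(pi / 2) + 2 * tt * sqrt((4 - pi) / 2)) / 1.7
      energy <- pmax(energy - Tn, 0)
      energy_all <- energy_all + energy
      an_all <- an_all + sumAn
    }
    energy_all / (an_all + 1e-4)
  }
  grad <- function(im) {
    out <- matrix(0, nr, nc)
    at <- function(i, j) if (i < 1 || j < 1 || i > nr || j > nc) 0 else im[i, j]
    for (i in 1:nr) for (j in 1:nc) {
      gx <- (3 * at(i - 1, j - 1) + 10 * at(i, j - 1) + 3 * at(i + 1, j - 1) -
               3 * at(i - 1, j + 1) - 10 * at(i, j + 1) - 3 * at(i + 1, j + 1)) / 16
      gy <- (3 * at(i - 1, j - 1) + 10 * at(i - 1, j) + 3 * at(i - 1, j + 1) -
               3 * at(i + 1, j - 1) - 10 * at(i + 1, j) - 3 * at(i + 1, j + 1)) / 16
      out[i, j] <- sqrt(gx^2 + gy^2)
    }
    out
  }
  pc1 <- pc_map(ref); pc2 <- pc_map(test)
  g1 <- grad(ref); g2 <- grad(test)
  num <- 0; den <- 0
  for (i in 1:nr) for (j in 1:nc) {
    spc <- (2 * pc1[i, j] * pc2[i, j] + 0.85) / (pc1[i, j]^2 + pc2[i, j]^2 + 0.85)
    sg <- (2 * g1[i, j] * g2[i, j] + 160) / (g1[i, j]^2 + g2[i, j]^2 + 160)
    w <- max(pc1[i, j], pc2[i, j])
    num <- num + spc * sg * w
    den <- den + w
  }
  num / den
}
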
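# Internal periodic (circular) filtering primitives.
#
# Both transforms use circular boundary handling, so all filtering is done
# in the frequency domain: a separable filter becomes an outer product of
# two 1-D DFTs.  `dilation` inserts 2^(j-1)-1 zeros between taps (the
# a-trous upsampling of the stationary transform at level j).

# DFT (length n) of `taps` upsampled by `dilation`, taps placed circularly.
.freq_response <- function(taps, n, dilation = 1L) {
  v <- numeric(n)
  pos <- ((seq_along(taps) - 1L) * dilation) %% n
  for (i in seq_along(taps)) v[pos[i] + 1L] <- v[pos[i] + 1L] + taps[i]
  stats::fft(v)
}

# Separable circular convolution of matrix x: `col_taps` applied down the
# columns (dimension 1), `row_taps` along the rows (dimension 2).
# conj = TRUE applies the time-reversed (adjoint) filters instead.
.circ_filter2 <- function(x, col_taps, row_taps, dilation = 1L,
                          conj = FALSE) {
  Fc <- .freq_response(col_taps, nrow(x), dilation)
  Fr <- .freq_response(row_taps, ncol(x), dilation)
  if (conj) { Fc <- Conj(Fc); Fr <- Conj(Fr) }
  X <- stats::fft(x)
  Re(stats::fft(X * outer(Fc, Fr), inverse = TRUE)) / length(x)
}

# Frequency-domain plan for one SWT level: the four separable responses.
.swt_level_responses <- function(lo, hi, nr, nc, dilation) {
  Lc <- .freq_response(lo, nr, dilation)
  Hc <- .freq_response(hi, nr, dilation)
  Lr <- .freq_response(lo, nc, dilation)
  Hr <- .freq_response(hi, nc, dilation)
  list(
    ll = outer(Lc, Lr),  # approximation
    hl = outer(Hc, Lr),  # highpass down columns  -> horizontal features
    lh = outer(Lc, Hr),  # highpass along rows    -> vertical features
    hh = outer(Hc, Hr)   # diagonal
  )
}
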
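---
title: "Two-stage wavelet denoising: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage wavelet denoising: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtswt)
```

## The model

The observation model throughout is additive Gaussian white noise on a
single-channel image,

$$ I_b = I + \varepsilon, \qquad \varepsilon_{ij} \sim
   \mathcal{N}(0, \sigma^2) \ \text{i.i.d.}, $$

with intensities on the 0–255 scale. Wavelet shrinkage exploits the fact
that natural and MR images are sparse in a wavelet basis while white noise
is not: after an orthonormal (or tight-frame) transform the noise is still
Gaussian with known variance in every subband, so coefficients smaller
than a noise-calibrated threshold are discarded and the rest shrunk.

Two transforms cooperate in the two-stage denoiser `denoise_proposed()`:

1. **Real 2-D dual-tree DWT** (`dualtree2_forward()`): two parallel
   critically-sampled orthonormal trees whose filters are offset by half a
   sample. One level yields six directional highpass subbands
   $Wb\{j\}\{s\}$ — tree $j \in \{1,2\}$, orientation $s \in \{1,2,3\}$
   (horizontal / vertical / diagonal) — plus two lowpass planes. All
   coefficients carry a $1/\sqrt{2}$ factor so the pair of trees forms a
   tight frame (coefficient energy equals image energy), and inversion
   averages the two per-tree reconstructions.
2. **2-D stationary wavelet transform** (`swt2_forward()`): the
   undecimated à-trous decomposition with db4, five levels. Having no
   downsampling it is exactly shift-covariant, which removes the
   shift-dependent ringing artifacts that plague thresholding in a
   decimated basis.

The two-stage scheme applies the 5-level db4 SWT soft-thresholding
denoiser *to each highpass subband* $Wb\{j\}\{s\}$ as if it were an image,
producing $Wd\{j\}\{s\}$, and reconstructs with the inverse dual-tree
transform. The single-stage SWT denoiser (`denoise_swt2d()`), direct
shrinkage in the dual-tree domain (`denoise_dt_soft()`), and non-local
means (`denoise_nlm()`) serve as baselines.

## The threshold: a completion the user should know about

Soft thresholding needs a threshold, and the method description this
package implements specifies only the operator, not the value. The
package completes it with the canonical choice:

* rule: **universal (VisuShrink)** $t = \hat\sigma\sqrt{2\ln n}$, $n$ the
  pixel count of the plane being thresholded;
* $\hat\sigma$: **MAD estimator** $\mathrm{median}(|d|)/0.6745$ on the
  level-1 diagonal detail plane of the decomposition being thresholded;
* multiplier: 1.

Everything is configurable through `threshold_rule()` (known sigma, fixed
threshold, any multiplier), and the choice matters: VisuShrink is
deliberately conservative and over-smooths at high resolution, so ranking
experiments between methods should be read as "under the universal
threshold", not as intrinsic properties of the transforms. One observable
consequence, which the benchmark in `scripts/acceptance.R` computes: on
the piecewise-constant ellipse phantom the *direct* dual-tree shrinkage
`denoise_dt_soft()` edges out the two-stage scheme by a few tenths of a
dB at every noise level, because the inner 5-level redundant SWT shrinks
each subband at five scales (more signal attrition) while both methods
pass the same noisy lowpass planes through. The two-stage scheme does beat
the single-stage SWT denoiser at every $\sigma$ by 2–3 dB.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `wavelet` | `"db4"` | mother wavelet of the SWT stage (8 orthonormal taps) |
| `swt_levels` | 5 | SWT depth; input is reflect-padded to a multiple of $2^5$ |
| `dt_levels` | 1 | dual-tree depth; 1 gives exactly the six $Wb\{j\}\{s\}$ |
| `threshold` | universal + MAD | see above |
| `lowpass_policy` | `"passthrough"` | the six highpass subbands are the denoised ones; set `"denoise"` to also run the lowpass planes through the SWT denoiser |
| `clip_range` | `c(0, 255)` | applied once, at the pipeline end; metrics are computed after clipping |
| NLM `patch_size`, `search_window`, `h` | 7, 21, $0.8\hat\sigma$ | standard non-local-means settings; $\hat\sigma$ from a one-level wavelet diagonal |

With `dt_levels = 1` and `swt_levels = 5` the image is padded to a
multiple of $2^6 = 64$ inside `denoise_proposed()` so the decimated
subbands still divide by $2^5$.

## Filter banks

* SWT stage: published Daubechies-4 taps, hard-coded, stored in
  convolution order; synthesis filters are the time-reverse (orthonormal
  convention), and the highpass is the quadrature-mirror alternation of
  the lowpass.
* Dual-tree first stage: the Farras nearly-symmetric 10-tap bank for
  tree 1; tree 2 uses the same bank **delayed by one sample**, the
  standard way to realize the required integer offset at level 1.
* Dual-tree deeper levels: a 10-tap q-shift pair, tree 2 the
  time-reverse of tree 1 (half-sample delay). The commonly printed
  8-decimal q-shift taps are orthonormal only to about $4\times10^{-9}$,
  which would dominate every round-trip error; the package stores a
  Newton refinement of those taps onto the exact orthonormality manifold
  (same structural zeros, within $3\times10^{-9}$ of the printed values).

## Numerical choices

* **Boundaries**: both transforms use periodic (circular) extension,
  which makes the SWT exactly shift-covariant and both round trips exact
  to machine precision. Reflective (half-sample symmetric) padding
  happens once, upstream, in `pad_to_multiple()`, and is undone exactly
  by `crop_pad()`.
* **Implementation**: all filtering is frequency-domain (`stats::fft`);
  the à-trous upsampling becomes a dilation of the filter's DFT, and the
  inverse SWT uses the adjoint filters, exploiting
  $|H_0(\omega)|^2 + |H_1(\omega)|^2 = 2$ for orthonormal pairs.
* **Shift-sensitivity measurements** aggregate subband energy per
  orientation *summed over the two trees* — the real-transform analogue
  of complex-coefficient magnitude. The tree-resolved energies simply
  swap trees under an odd diagonal shift (a direct consequence of the
  one-sample-offset first stage), so they are not the stable quantity.
* **Intensities** are converted to double on entry; clipping to the
  declared range happens once, at the pipeline end.
* **Degenerate inputs**: a constant image has all-zero detail planes and
  passes through every wavelet denoiser unchanged; a noise-free image
  gives a zero MAD estimate, which NLM treats as "nothing to average".

## Quality metrics

* `psnr()`: $10\log_{10}(\mathrm{peak}^2/\mathrm{MSE})$; identical inputs
  give `Inf`.
* `ssim()`: mean of the local SSIM map, 11×11 Gaussian window
  (std 1.5), $C_1 = (0.01\,\mathrm{peak})^2$,
  $C_2 = (0.03\,\mathrm{peak})^2$, valid-region pooling — the standard
  reference constants.
* `nmse()`: error energy over reference energy.
* `fsim()`: phase-congruency / gradient-magnitude similarity pooled with
  $\max(PC_1, PC_2)$ weights. The phase-congruency map uses a log-Gabor
  bank with 4 scales and 4 orientations, smallest wavelength 6, scale
  multiplier 2, $\sigma_{onf} = 0.55$, angular spread $\pi/4/1.2$, a
  Rayleigh-statistics noise threshold ($k = 2$), Scharr 3×3 gradients and
  stability constants $T_1 = 0.85$, $T_2 = 160$ (0–255 range). Inputs
  with a different peak are rescaled; large images are block-averaged
  down by $\max(1, \mathrm{round}(\min(H,W)/256))$.

PSNR and SSIM values computed on the synthetic phantoms are *not*
comparable with absolute numbers reported for external MR test images,
whose intensity-scaling conventions and noise realizations are not
recorded; the meaningful comparisons are within-run, across methods and
noise levels.

## The phantom generator, and what passing tests do not show

`make_phantom()` is deterministic. The `"ellipses"` phantom is a
piecewise-constant overlapping-ellipse "brain" (skull ring, tissue
interior, ventricle-like dark ellipses, bright lesion), which emulates
the sharp tissue boundaries and flat regions of a T1-like MR slice. The
`"texture"` phantom adds oriented sinusoids and hard edges to exercise
the directional subbands. `corrupt()` implements additive Gaussian noise
(no pre-clipping, so $\sigma$ stays exactly interpretable),
salt-and-pepper impulses, and Poisson shot noise, all seeded through R's
Mersenne-Twister stream.

What the phantoms do **not** emulate: Rician magnitude noise of real MR
acquisitions, spatially varying coil sensitivity, partial-volume
gradients at tissue interfaces, and scanner texture. Tests passing on
these phantoms demonstrate the transforms' exactness and the denoisers'
behavior under the stated AWGN model — not clinical performance.

## Problem sizes used by the test suite

Round-trip and shift-covariance checks run on 32²–128×64 matrices;
estimator-recovery and noise-calibration checks on 256² fields; the
denoising benchmark on the 256² ellipse phantom with ten corruption seeds
per noise level (five in the acceptance script). 256² is the canonical
phantom size: it matches typical MR slice resolution, and at this size
the clean-phantom distortion of the two-stage scheme stays above 40 dB
PSNR (the MAD estimate on structured subbands inflates at coarser
resolutions, where edge pixels occupy a third of each plane).

## Known limitations

* The universal threshold is calibrated for Gaussian noise; on
  salt-and-pepper or Poisson corruption the wavelet denoisers run but are
  not optimal (median-type filtering or variance stabilization would be
  the right tools).
* `lowpass_policy = "passthrough"` leaves the noise that lives in the
  dual-tree lowpass planes (about a quarter of the noise energy at one
  level) untouched, which caps the achievable PSNR near
  $10\log_{10}(255^2/(\sigma^2/4))$; this mirrors the method description,
  which denoises only the six highpass subbands.
* FSIM involves a noise-compensation threshold estimated from the image
  itself, so it is the one metric whose value is not a simple closed form
  of the pixel differences; it is deterministic given the inputs.
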
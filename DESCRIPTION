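Package: dtswt
Title: MRI Denoising by Stationary-Wavelet Thresholding of Dual-Tree Subbands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Wavelet-domain denoising of grayscale and magnetic-resonance
    images. Implements a two-stage scheme in which a real 2-D dual-tree
    discrete wavelet transform splits the image into directional subbands
    and each highpass subband is then denoised by soft thresholding in a
    5-level db4 stationary (undecimated) wavelet domain. Also provides the
    single-stage stationary-wavelet denoiser, direct soft thresholding in
    the dual-tree domain, and a non-local means filter as baselines, a
    deterministic MRI-like phantom generator with Gaussian, salt-and-pepper
    and Poisson corruption models, full-reference image quality metrics
    (PSNR, SSIM, NMSE, FSIM), and a benchmark runner that sweeps methods
    over noise levels and seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    png,
    tiff,
    jpeg,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
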
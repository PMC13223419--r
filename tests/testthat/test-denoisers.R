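zero_rule <- denoise_config(threshold = threshold_rule("fixed", fixed_value = 0),
                            clip_range = NULL)

test_that("every wavelet denoiser with threshold 0 reproduces its input", {
  x <- make_phantom(96, 96, "texture")[1:90, 1:90]  # non-dyadic on purpose
  expect_lt(max(abs(denoise_swt2d(x, zero_rule) - x)), 1e-8)
  expect_lt(max(abs(denoise_proposed(x, zero_rule) - x)), 1e-8)
  expect_lt(max(abs(denoise_dt_soft(x, zero_rule) - x)), 1e-8)
})

test_that("denoisers preserve shape and fix the zero image", {
  z <- matrix(0, 70, 80)
  for (f in list(denoise_swt2d, denoise_proposed, denoise_dt_soft)) {
    out <- f(z)
    expect_identical(dim(out), dim(z))
    expect_lt(max(abs(out)), 1e-8)
  }
  out <- denoise_nlm(z)
  expect_identical(dim(out), dim(z))
  expect_lt(max(abs(out)), 1e-8)
})

test_that("a constant image passes through unchanged", {
  x <- matrix(120, 96, 96)
  expect_lt(max(abs(denoise_swt2d(x) - 120)), 1e-8)
  expect_lt(max(abs(denoise_nlm(x, h = 10) - 120)), 1e-8)
})

test_that("multi-channel input is rejected", {
  arr <- array(0, c(8, 8, 3))
  expect_error(denoise_swt2d(arr), "single-channel")
})

test_that("all wavelet denoisers raise PSNR on the noisy phantom", {
  ph <- make_phantom(192, 192, "ellipses")
  gains <- matrix(0, 3, 3)
  for (seed in 1:3) {
    no <- corrupt(ph, noise_spec("gaussian", sigma = 20, seed = seed))
    base <- quick_psnr(ph, no)
    gains[seed, ] <- c(quick_psnr(ph, denoise_proposed(no)) - base,
                       quick_psnr(ph, denoise_swt2d(no)) - base,
                       quick_psnr(ph, denoise_dt_soft(no)) - base)
  }
  expect_true(all(colMeans(gains) > 0))
})

test_that("non-local means denoises and honors its limits", {
  ph <- make_phantom(96, 96, "ellipses")
  no <- corrupt(ph, noise_spec("gaussian", sigma = 20, seed = 1))
  expect_gt(quick_psnr(ph, denoise_nlm(no)), quick_psnr(ph, no))
  expect_error(denoise_nlm(no, patch_size = 6), "odd")
  expect_error(denoise_nlm(no, patch_size = 21, search_window = 21), "smaller")
  # h -> infinity limit: every weight saturates to 1, so the output is the
  # (circular) box mean over the search window
  x <- rmat(48, 48, 2)
  out <- denoise_nlm(x, patch_size = 3, search_window = 9, h = 1e6)
  box <- dtswt:::.box_mean_circ(x, 9)
  expect_lt(max(abs(out - box)), 1e-3)
})

test_that("denoising a clean phantom introduces only slight distortion", {
  for (kind in c("ellipses", "texture")) {
    ph <- make_phantom(256, 256, kind)
    expect_gt(quick_psnr(ph, denoise_proposed(ph)), 40)
  }
})

test_that("the lowpass-denoise policy changes the output", {
  ph <- make_phantom(128, 128, "ellipses")
  no <- corrupt(ph, noise_spec("gaussian", sigma = 30, seed = 1))
  a <- denoise_proposed(no)
  b <- denoise_proposed(no, denoise_config(lowpass_policy = "denoise"))
  expect_gt(max(abs(a - b)), 1)
})
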
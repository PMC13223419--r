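test_that("psnr matches its closed form and degenerate cases", {
  ref <- matrix(100, 16, 16)
  test <- ref
  test[1:8, ] <- 101; test[9:16, ] <- 99   # MSE exactly 1
  expect_equal(psnr(ref, test, peak = 255), 20 * log10(255), tolerance = 1e-12)
  expect_equal(round(psnr(ref, test, peak = 255), 4), 48.1308)
  expect_identical(psnr(ref, ref), Inf)
  # joint scale invariance
  x <- rmat(16, 16, 1); y <- rmat(16, 16, 2)
  expect_equal(psnr(x, y, 255), psnr(10 * x, 10 * y, 2550))
  expect_error(psnr(x, matrix(0, 8, 8)), "dimensions")
})

test_that("nmse identities, full-error case, and scale invariance", {
  expect_equal(nmse(matrix(1, 1, 2), matrix(1, 1, 2)), 0)
  expect_equal(nmse(matrix(1, 1, 2), matrix(0, 1, 2)), 1.0)
  x <- rmat(12, 12, 3); y <- rmat(12, 12, 4)
  expect_equal(nmse(x, y), nmse(5 * x, 5 * y))
  expect_error(nmse(matrix(0, 2, 2), matrix(1, 2, 2)), "zero")
})

test_that("psnr and negated nmse rank noise levels identically", {
  ph <- make_phantom(64, 64, "ellipses")
  set.seed(8)
  sigmas <- runif(20, 1, 60)
  ps <- ns <- numeric(20)
  for (i in 1:20) {
    no <- corrupt(ph, noise_spec("gaussian", sigma = sigmas[i], seed = i))
    ps[i] <- psnr(ph, no); ns[i] <- nmse(ph, no)
  }
  expect_identical(order(ps), order(-ns))
})

test_that("ssim is 1 on identical images, symmetric, and window-checked", {
  ph <- make_phantom(64, 64, "ellipses")
  expect_equal(ssim(ph, ph), 1.0)
  no <- corrupt(ph, noise_spec("gaussian", sigma = 15, seed = 1))
  expect_lt(abs(ssim(ph, no) - ssim(no, ph)), 1e-12)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "11")
})

test_that("ssim matches a loop-based evaluation of the windowed formula", {
  for (seed in 1:10) {
    set.seed(seed)
    a <- matrix(runif(40 * 40, 0, 255), 40)
    b <- a + matrix(rnorm(40 * 40, sd = 25), 40)
    expect_lt(abs(ssim(a, b) - ssim_loop(a, b)), 1e-7)
  }
})

test_that("fsim is 1 on identical images, symmetric, monotone in noise", {
  ph <- make_phantom(96, 96, "ellipses")
  expect_equal(fsim(ph, ph), 1.0)
  n5 <- corrupt(ph, noise_spec("gaussian", sigma = 5, seed = 1))
  n50 <- corrupt(ph, noise_spec("gaussian", sigma = 50, seed = 1))
  expect_lt(abs(fsim(ph, n5) - fsim(n5, ph)), 1e-10)
  expect_gt(fsim(ph, n5), fsim(ph, n50))
  expect_error(fsim(matrix(0, 16, 16), matrix(0, 16, 16)), "32")
})

test_that("fsim matches a loop-based evaluation of its published formula", {
  ph <- make_phantom(64, 64, "texture")
  for (seed in 1:10) {
    a <- corrupt(ph, noise_spec("gaussian", sigma = 5 * seed, seed = seed))
    b <- corrupt(ph, noise_spec("gaussian", sigma = 10, seed = seed + 100))
    expect_lt(abs(fsim(a, b) - fsim_loop(a, b)), 1e-7)
  }
})

test_that("metrics_report returns the invariant values on identical inputs", {
  ph <- make_phantom(64, 64, "ellipses")
  rep <- metrics_report(ph, ph)
  expect_identical(rep$psnr, Inf)
  expect_equal(rep$ssim, 1.0)
  expect_equal(rep$nmse, 0)
  expect_equal(rep$fsim, 1.0)
  expect_output(print(rep), "PSNR")
})
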
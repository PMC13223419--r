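test_that("db4 bank matches published taps and the orthonormal conventions", {
  fb <- get_wavelet_filters("db4")
  expect_length(fb$analysis_lowpass, 8)
  expect_length(fb$analysis_highpass, 8)
  expect_lt(max(abs(fb$analysis_lowpass - DB4_PUBLISHED_LO)), 1e-10)
  expect_lt(abs(sum(fb$analysis_lowpass) - sqrt(2)), 1e-10)
  # quadrature-mirror alternation of the lowpass
  L <- 8
  expect_equal(fb$analysis_highpass,
               rev(fb$analysis_lowpass) * (-1)^(0:(L - 1)))
  expect_equal(fb$synthesis_lowpass, rev(fb$analysis_lowpass))
})

test_that("unsupported identifiers raise descriptive errors", {
  expect_error(get_wavelet_filters("nosuchwavelet"), "supported wavelets")
  expect_error(get_dualtree_filters("unknown"), "supported")
})

test_that("two-channel energy is 2 for every returned bank", {
  banks <- c(
    lapply(c("db4", "haar"), get_wavelet_filters),
    unname(get_dualtree_filters()[c("first_stage_tree1", "first_stage_tree2",
                                    "qshift_tree1", "qshift_tree2")])
  )
  for (fb in banks) {
    expect_lt(abs(sum(fb$analysis_lowpass^2) + sum(fb$analysis_highpass^2) - 2),
              1e-9)
    expect_lt(abs(sum(fb$analysis_lowpass) - sqrt(2)), 1e-9)
  }
})

test_that("dual-tree set has 10-tap first-stage filters and the one-sample shift", {
  fs <- get_dualtree_filters()
  expect_length(fs$first_stage_tree1$analysis_lowpass, 10)
  expect_length(fs$first_stage_tree2$analysis_lowpass, 10)
  # tree 2 first-stage lowpass is exactly tree 1's delayed by one sample
  t1 <- fs$first_stage_tree1$analysis_lowpass
  t2 <- fs$first_stage_tree2$analysis_lowpass
  expect_identical(t2, c(0, t1[-length(t1)]))
})

test_that("one level of analysis + synthesis reconstructs an impulse", {
  fs <- get_dualtree_filters()
  banks <- list(get_wavelet_filters("db4"), fs$first_stage_tree1,
                fs$first_stage_tree2, fs$qshift_tree1, fs$qshift_tree2)
  for (fb in banks) {
    x <- matrix(0, 32, 1); x[7, 1] <- 1
    dec <- dtswt:::.dwt_cols(x, fb$analysis_lowpass, fb$analysis_highpass)
    rec <- dtswt:::.idwt_cols(dec$lo, dec$hi,
                              fb$analysis_lowpass, fb$analysis_highpass)
    expect_lt(max(abs(rec - x)), 1e-10)
  }
})

test_that("perfect reconstruction holds for random even-length signals", {
  fs <- get_dualtree_filters()
  banks <- list(get_wavelet_filters("db4"), fs$first_stage_tree1,
                fs$qshift_tree2)
  set.seed(42)
  for (i in 1:50) {
    fb <- banks[[(i %% 3) + 1]]
    L <- length(fb$analysis_lowpass)
    n <- 2L * sample(L:64, 1)  # even, >= 2x filter length
    x <- matrix(rnorm(n), n, 1)
    dec <- dtswt:::.dwt_cols(x, fb$analysis_lowpass, fb$analysis_highpass)
    rec <- dtswt:::.idwt_cols(dec$lo, dec$hi,
                              fb$analysis_lowpass, fb$analysis_highpass)
    expect_lt(max(abs(rec - x)), 1e-9)
  }
})
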
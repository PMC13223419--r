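test_that("one level of a 64x64 image yields six 32x32 subbands, two lowpass", {
  co <- dualtree2_forward(rmat(64), 1)
  expect_identical(co$levels, 1L)
  for (tree in 1:2) {
    expect_identical(dim(co$lowpass[[tree]]), c(32L, 32L))
    for (o in c("horizontal", "vertical", "diagonal")) {
      expect_identical(dim(co$highpass[[1]][[tree]][[o]]), c(32L, 32L))
    }
  }
  n_coef <- sum(vapply(co$lowpass, length, numeric(1))) +
    sum(unlist(lapply(co$highpass[[1]], function(tr) vapply(tr, length, numeric(1)))))
  expect_identical(n_coef, 2 * 64 * 64)
})

test_that("the two trees form a tight frame (energy preservation)", {
  x <- rmat(64, 64, 11)
  for (J in 1:2) {
    co <- dualtree2_forward(x, J)
    e <- sum(dualtree2_energy(co, include_lowpass = TRUE))
    expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-6)
  }
})

test_that("inverse(forward(x)) == x across levels and shapes", {
  shapes <- list(c(32, 32), c(64, 64), c(128, 64))
  for (sh in shapes) {
    for (J in 1:2) {
      for (seed in 1:20) {
        x <- rmat(sh[1], sh[2], seed)
        expect_lt(max(abs(dualtree2_inverse(dualtree2_forward(x, J)) - x)),
                  1e-9)
      }
    }
  }
})

test_that("all-zero coefficients invert to the zero image", {
  co <- dualtree2_forward(matrix(0, 32, 32), 1)
  expect_identical(max(abs(dualtree2_inverse(co))), 0)
})

test_that("the forward transform is linear", {
  x <- rmat(32, 32, 1); y <- rmat(32, 32, 2)
  ca <- dualtree2_forward(2 * x - 3 * y, 1)
  cx <- dualtree2_forward(x, 1); cy <- dualtree2_forward(y, 1)
  for (tree in 1:2) {
    for (o in c("horizontal", "vertical", "diagonal")) {
      expect_lt(max(abs(ca$highpass[[1]][[tree]][[o]] -
                          (2 * cx$highpass[[1]][[tree]][[o]] -
                             3 * cy$highpass[[1]][[tree]][[o]]))), 1e-9)
    }
    expect_lt(max(abs(ca$lowpass[[tree]] -
                        (2 * cx$lowpass[[tree]] - 3 * cy$lowpass[[tree]]))),
              1e-9)
  }
})

test_that("a horizontal-edge image drives the horizontal-sensitive subbands", {
  img <- matrix(0, 64, 64)
  img[rep(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 8), ] <- 100
  e <- dualtree2_energy(dualtree2_forward(img, 1))
  horiz <- sum(e[grepl("horizontal", names(e))])
  expect_gt(horiz / sum(e), 0.80)
})

test_that("per-orientation energy is steadier under shift than a single tree", {
  n <- 64
  ph <- make_phantom(n, n, "texture")
  shifted <- circshift2(ph, 1, 1)
  orient_energy <- function(co) {
    out <- c()
    for (lev in seq_len(co$levels)) {
      for (s in 1:3) {
        out <- c(out, sum(co$highpass[[lev]][[1]][[s]]^2) +
                   sum(co$highpass[[lev]][[2]][[s]]^2))
      }
    }
    out
  }
  fb <- get_wavelet_filters("db4")
  for (J in 1:2) {
    e0 <- orient_energy(dualtree2_forward(ph, J))
    e1 <- orient_energy(dualtree2_forward(shifted, J))
    dt_rel <- sqrt(sum((e1 - e0)^2)) / sqrt(sum(e0^2))
    s0 <- single_tree_dwt2(ph, fb$analysis_lowpass, fb$analysis_highpass, J)
    s1 <- single_tree_dwt2(shifted, fb$analysis_lowpass, fb$analysis_highpass, J)
    st_rel <- sqrt(sum((s1 - s0)^2)) / sqrt(sum(s0^2))
    expect_lt(dt_rel, st_rel)
  }
})

test_that("indivisible dimensions are rejected", {
  expect_error(dualtree2_forward(matrix(0, 30, 30), 2), "divisible")
})
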
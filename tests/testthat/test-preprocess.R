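test_that("denoising preserves constants and is the identity at sigma 0", {
  cst <- matrix(77, 48, 48)
  expect_equal(denoiseImage(cst, noise_sigma = 10), cst)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  expect_identical(denoiseImage(img, noise_sigma = 0), img)
  expect_error(denoiseImage(img, noise_sigma = -1), ">= 0")
  expect_error(denoiseImage(img, block_size = 20L, search_window = 16L),
               "search_window")
})

test_that("denoising reduces MSE on a noisy piecewise-constant image", {
  clean <- matrix(30, 128, 128)
  clean[40:90, 30:100] <- 180
  clean[10:25, ] <- 90
  noisy <- withr::with_seed(42, {
    pmin(pmax(clean + matrix(rnorm(128^2, 0, 25), 128, 128), 0), 255)
  })
  den <- denoiseImage(noisy, noise_sigma = 25)
  expect_identical(dim(den), dim(clean))
  expect_true(all(den >= 0 & den <= 255))
  mseNoisy <- mean((noisy - clean)^2)
  mseDen <- mean((den - clean)^2)
  expect_lt(mseDen, mseNoisy)
  expect_lt(mseDen, mseNoisy / 3)  # substantial, not marginal, reduction
})

test_that("unsharp masking follows g = I + k (I - lowpass(I))", {
  img <- matrix(runif(40 * 40, 0, 200), 40, 40)
  expect_equal(unsharpMask(img, k = 0, kernel_size = 3L), img)
  cst <- matrix(123, 32, 32)
  expect_equal(unsharpMask(cst, k = 2.5, kernel_size = 5L), cst)
  expect_error(unsharpMask(img, kernel_size = 4L), "odd")

  # hand evaluation on a 1-row step, 3-tap mean, replicate borders, k = 1
  row <- matrix(c(0, 0, 0, 100, 100, 100), nrow = 1)
  lp <- c(0, 0, 100 / 3, 200 / 3, 100, 100)
  gmask <- as.vector(row) - lp
  expected <- as.vector(row) + 1 * gmask
  raw <- coroseg:::.umRaw(row, k = 1, ks = 3L)
  expect_equal(as.vector(raw), expected, tolerance = 1e-12)
  # clipping maps the undershoot to 0
  expect_equal(as.vector(unsharpMask(row, k = 1, kernel_size = 3L)),
               pmin(pmax(expected, 0), 255), tolerance = 1e-12)
})

test_that("unsharp masking is linear before clipping", {
  img <- matrix(runif(30 * 30, 0, 60), 30, 30)
  a <- 2.7
  expect_equal(coroseg:::.umRaw(a * img, 1.5, 9L),
               a * coroseg:::.umRaw(img, 1.5, 9L), tolerance = 1e-10)
})

test_that("histogram clipping redistributes and conserves mass", {
  expect_equal(clipHistogram(c(10, 10, 10, 10), 20), c(10, 10, 10, 10))
  expect_error(clipHistogram(c(1, 2), 0), "> 0")

  # iterate the redistribution rule by hand for [100,0,0,0], limit 40
  h <- c(100, 0, 0, 0)
  ref <- h
  for (i in 1:16) {
    excess <- sum(pmax(ref - 40, 0))
    if (excess < 1) break
    ref <- pmin(ref, 40) + excess / 4
  }
  out <- clipHistogram(h, 40)
  expect_equal(out, ref)
  expect_equal(sum(out), 100)
  expect_lte(max(out), 40 + 1)  # residual below one count

  withr::with_seed(7, {
    for (i in 1:20) {
      hh <- rpois(64, lambda = runif(1, 1, 50))
      lim <- runif(1, 1, 30)
      expect_equal(sum(clipHistogram(hh, lim)), sum(hh))
    }
  })
})

test_that("CLAHE maps constants to constants and validates tiling", {
  cst <- matrix(42, 64, 64)
  out <- clahe(cst)
  expect_equal(max(out) - min(out), 0)
  expect_error(clahe(matrix(1, 4, 4), tile_rows = 8L, tile_cols = 8L),
               "larger than image")
})

test_that("unclipped CLAHE equals a direct per-tile AHE oracle", {
  img <- withr::with_seed(11, matrix(runif(32 * 32, 0, 255), 32, 32))
  nb <- 32L; tr <- 2L; tc <- 2L
  got <- clahe(img, clip_limit = 1e9, tile_rows = tr, tile_cols = tc,
               n_bins = nb)

  # oracle: per-tile CDF mapping, bilinear interpolation between the four
  # nearest tile centers, clamped at the borders
  bin <- pmin(pmax(floor(img / 256 * nb), 0), nb - 1)
  rb <- round(seq(0, 32, length.out = tr + 1))
  cb <- round(seq(0, 32, length.out = tc + 1))
  ctrR <- (rb[-1] + rb[-(tr + 1)] - 1) / 2
  ctrC <- (cb[-1] + cb[-(tc + 1)] - 1) / 2
  maps <- array(0, c(nb, tr, tc))
  for (i in 1:tr) for (j in 1:tc) {
    b <- bin[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]]
    h <- tabulate(as.vector(b) + 1L, nbins = nb)
    maps[, i, j] <- 255 * cumsum(h) / length(b)
  }
  oracle <- matrix(0, 32, 32)
  for (r in 1:32) for (cc in 1:32) {
    y <- r - 1; x <- cc - 1
    iT <- max(which(ctrR <= y), 1L); if (length(which(ctrR <= y)) == 0) iT <- 1L
    iB <- min(iT + 1L, tr)
    if (y <= ctrR[1]) { iT <- 1L; iB <- 1L }
    if (y >= ctrR[tr]) { iT <- tr; iB <- tr }
    jL <- max(which(ctrC <= x), 1L); if (length(which(ctrC <= x)) == 0) jL <- 1L
    jR <- min(jL + 1L, tc)
    if (x <= ctrC[1]) { jL <- 1L; jR <- 1L }
    if (x >= ctrC[tc]) { jL <- tc; jR <- tc }
    wy <- if (iT == iB) 0 else (y - ctrR[iT]) / (ctrR[iB] - ctrR[iT])
    wx <- if (jL == jR) 0 else (x - ctrC[jL]) / (ctrC[jR] - ctrC[jL])
    b <- bin[r, cc] + 1L
    oracle[r, cc] <- (1 - wy) * ((1 - wx) * maps[b, iT, jL] +
                                 wx * maps[b, iT, jR]) +
      wy * ((1 - wx) * maps[b, iB, jL] + wx * maps[b, iB, jR])
  }
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("CLAHE widens the support of a low-contrast ramp", {
  ramp <- matrix(rep(seq(100, 140, length.out = 64), each = 64), 64, 64)
  out <- clahe(ramp, clip_limit = 4)
  expect_gt(max(out) - min(out), max(ramp) - min(ramp))
})

test_that("preprocessing operators preserve shape and the [0,255] range", {
  img <- withr::with_seed(3, matrix(runif(48 * 56, 0, 255), 48, 56))
  for (out in list(denoiseImage(img, 15), unsharpMask(img, 1.5, 9L),
                   clahe(img))) {
    expect_identical(dim(out), dim(img))
    expect_gte(min(out), 0)
    expect_lte(max(out), 255)
  }
})
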
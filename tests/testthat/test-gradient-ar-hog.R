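test_that("gradient features on constant, ramp and random ROIs", {
  msk <- matrix(TRUE, 16, 16)
  f <- gradientFeatures(matrix(5, 16, 16), msk)
  expect_equal(f[["grad_mean"]], 0)
  expect_equal(f[["grad_nonzero_frac"]], 0)

  # unit ramp: constant gradient of magnitude 1, zero variance
  ramp <- matrix(rep(1:16, each = 16), 16, byrow = TRUE)
  f2 <- gradientFeatures(ramp, msk)
  expect_equal(f2[["grad_mean"]], 1, tolerance = 1e-12)
  expect_equal(f2[["grad_variance"]], 0, tolerance = 1e-12)

  # random ROI vs direct convolution oracle
  for (seed in 1:10) {
    roi <- randomROI(seed)
    em <- oracleErode(roi$mask)
    if (!any(em)) next
    g <- c()
    for (r in seq_len(nrow(roi$img))) for (c in seq_len(ncol(roi$img))) {
      if (em[r, c]) {
        gg <- oracleSobelXY(roi$img, r, c)
        g <- c(g, sqrt(sum(gg^2)))
      }
    }
    ref <- oracleMoments(g)
    got <- gradientFeatures(roi$img, roi$mask)
    expect_equal(got[["grad_mean"]], ref[["mean"]], tolerance = 1e-9)
    expect_equal(got[["grad_variance"]], ref[["variance"]], tolerance = 1e-9)
    expect_equal(got[["grad_skewness"]], ref[["skewness"]], tolerance = 1e-9)
    expect_equal(got[["grad_kurtosis"]], ref[["kurtosis"]], tolerance = 1e-9)
  }
})

test_that("AR estimates match the direct normal-equation oracle", {
  set.seed(8)
  img <- matrix(100 + rnorm(32 * 32), 32, 32)
  msk <- matrix(TRUE, 32, 32)
  got <- arFeatures(img, msk)
  # direct OLS on the explicitly assembled design
  y <- c(); X <- NULL
  mu <- mean(img)
  for (r in 2:32) for (c in 2:31) {
    y <- c(y, img[r, c] - mu)
    X <- rbind(X, c(img[r, c - 1], img[r - 1, c - 1], img[r - 1, c],
                    img[r - 1, c + 1]) - mu)
  }
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(got[1:4]), as.vector(beta), tolerance = 1e-9)
  res <- y - X %*% beta
  expect_equal(got[["ar_sigma"]], sqrt(mean(res^2)), tolerance = 1e-9)
})

test_that("AR weights are recovered from simulated AR textures", {
  theta <- c(0.4, 0.1, 0.3, 0.1)
  for (seed in 1:3) {
    img <- simulateARTexture(theta, 64, sigma = 1, seed = seed)
    got <- arFeatures(img, matrix(TRUE, 64, 64))
    expect_lt(max(abs(got[1:4] - theta)), 0.05)
  }
})

test_that("AR on white noise finds no spatial dependence", {
  for (seed in 1:3) {
    set.seed(seed)
    img <- matrix(rnorm(64 * 64), 64, 64)
    got <- arFeatures(img, matrix(TRUE, 64, 64))
    expect_lt(max(abs(got[1:4])), 3 / sqrt(63 * 62))  # ~3 standard errors
  }
  expect_error(arFeatures(matrix(1, 64, 64), matrix(TRUE, 64, 64)),
               "singular")
  expect_error(arFeatures(matrix(rnorm(64), 8, 8), matrix(TRUE, 8, 8)),
               "100")
})

test_that("HOG binning, normalization and the ramp case", {
  msk <- matrix(TRUE, 16, 16)
  ramp <- matrix(rep(1:16, each = 16), 16)  # intensity grows along columns
  h <- hogFeatures(ramp, msk)
  expect_equal(h[["hog_bin1"]], 1)          # all mass at 0 degrees
  expect_equal(sum(h), 1, tolerance = 1e-9)

  expect_warning(h0 <- hogFeatures(matrix(3, 16, 16), msk), "uniform")
  expect_equal(unname(h0), rep(1 / 8, 8))

  for (seed in 1:10) {
    roi <- randomROI(seed)
    em <- oracleErode(roi$mask)
    if (!any(em)) next
    bins <- rep(0, 8)
    for (r in seq_len(nrow(roi$img))) for (c in seq_len(ncol(roi$img))) {
      if (em[r, c]) {
        g <- oracleSobelXY(roi$img, r, c)
        ang <- (atan2(g[["gy"]], g[["gx"]]) * 180 / pi) %% 360
        b <- min(8, floor(ang / 45) + 1)
        bins[b] <- bins[b] + sqrt(sum(g^2))
      }
    }
    got <- hogFeatures(roi$img, roi$mask)
    expect_equal(unname(got), bins / sum(bins), tolerance = 1e-9)
  }
})
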
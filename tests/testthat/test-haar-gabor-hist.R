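test_that("Haar energies vanish in detail bands for constant ROIs", {
  f <- haarFeatures(matrix(9, 32, 32), matrix(TRUE, 32, 32))
  det <- grep("_(lh|hl|hh)_", names(f))
  expect_true(all(abs(f[det]) < 1e-20))
  expect_true(all(f[grep("_ll_", names(f))] > 0))
  expect_error(haarFeatures(matrix(1, 8, 8), matrix(TRUE, 8, 8)), "16")
})

test_that("period-2 vertical stripes load the horizontally-detailed sub-band", {
  img <- matrix(rep(c(0, 1), times = 16), 32, 32, byrow = TRUE)
  # columns alternate 0/1: variation along x only
  f <- haarFeatures(img, matrix(TRUE, 32, 32))
  expect_gt(f[["haar_en_hl_s1"]], 10 * f[["haar_en_lh_s1"]] + 1e-12)
  expect_gt(f[["haar_en_hl_s1"]], 10 * f[["haar_en_hh_s1"]] + 1e-12)
})

test_that("Haar energies match the recursive block-loop oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(c(16, 20, 24), 1)
    img <- matrix(rnorm(n * n), n, n)
    msk <- matrix(TRUE, n, n)
    got <- haarFeatures(img, msk)
    x <- img
    for (sc in 1:4) {
      st <- oracleHaarStep(x)
      for (bd in c("ll", "lh", "hl", "hh")) {
        expect_equal(got[[paste0("haar_en_", bd, "_s", sc)]],
                     mean(st[[bd]]^2), tolerance = 1e-9)
      }
      x <- st$ll
    }
  }
})

test_that("histogram features: constants, ranks and the sort oracle", {
  f <- histogramFeatures(matrix(7, 10, 10), matrix(TRUE, 10, 10))
  expect_equal(f[["hist_mean"]], 7)
  expect_equal(f[["hist_variance"]], 0)
  expect_true(all(f[paste0("hist_p", c("01", "10", "50", "90", "99"))] == 7))

  img <- matrix(1:100, 10, 10)
  f2 <- histogramFeatures(img, matrix(TRUE, 10, 10))
  expect_equal(f2[["hist_p50"]], 50)
  expect_equal(f2[["hist_p90"]], 90)
  expect_equal(f2[["hist_p01"]], 1)
  expect_equal(f2[["hist_p99"]], 99)

  for (seed in 1:10) {
    roi <- randomROI(seed)
    v <- roi$img[roi$mask]
    got <- histogramFeatures(roi$img, roi$mask)
    ref <- oracleMoments(v)
    expect_equal(got[["hist_mean"]], ref[["mean"]], tolerance = 1e-12)
    expect_equal(got[["hist_variance"]], ref[["variance"]], tolerance = 1e-12)
    expect_equal(got[["hist_skewness"]], ref[["skewness"]], tolerance = 1e-9)
    expect_equal(got[["hist_kurtosis"]], ref[["kurtosis"]], tolerance = 1e-9)
    expect_equal(got[["hist_p01"]], oraclePercentile(v, 0.01))
    expect_equal(got[["hist_p10"]], oraclePercentile(v, 0.1))
    expect_equal(got[["hist_p50"]], oraclePercentile(v, 0.5))
    expect_equal(got[["hist_p99"]], oraclePercentile(v, 0.99))
  }
})

test_that("Gabor bank: constants, grating selectivity and rotation symmetry", {
  msk <- matrix(TRUE, 48, 48)
  f0 <- gaborFeatures(matrix(5, 48, 48), msk)
  expect_true(all(f0 < 1e-8))

  # vertical grating of wavelength 8 px (varies along x): the strongest of
  # the 24 responses is orientation 0 at envelope 8
  img <- matrix(sin(2 * pi * rep(1:48, each = 48) / 8), 48, 48)
  f <- gaborFeatures(img, msk)
  expect_equal(names(which.max(f)), "gabor_mag_0_s8")

  # rotating the image by 90 degrees permutes the orientation labels
  set.seed(4)
  img2 <- matrix(rnorm(48 * 48), 48, 48)
  rot <- t(img2)[, 48:1]   # 90-degree rotation
  fa <- gaborFeatures(img2, msk)
  fb <- gaborFeatures(rot, msk)
  for (s in c(4, 6, 8, 12, 16, 24)) {
    expect_equal(fa[[paste0("gabor_mag_0_s", s)]],
                 fb[[paste0("gabor_mag_90_s", s)]], tolerance = 1e-9)
    expect_equal(fa[[paste0("gabor_mag_45_s", s)]],
                 fb[[paste0("gabor_mag_135_s", s)]], tolerance = 1e-9)
  }

  expect_error(gaborFeatures(matrix(0, 16, 16), matrix(TRUE, 16, 16)),
               "envelope")
})
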
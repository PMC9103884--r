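test_that("scaleROI scales areas by the squared matrix ratio", {
  m <- matrix(FALSE, 256, 256)
  m[101:110, 101:110] <- TRUE
  expect_identical(scaleROI(m, 256, 256), m)
  up <- scaleROI(m, 256, 512)
  expect_equal(sum(up) / sum(m), 4, tolerance = 0.15)
  rr <- range(which(rowSums(up) > 0))
  expect_lte(abs(diff(rr) + 1 - 20), 2)  # ~20 px wide, +/-1 per side
  expect_error(scaleROI(matrix(FALSE, 8, 8), 8, 16), "empty")
})

test_that("scaleROI matches the study's bone ROI growth to order of magnitude", {
  # reference bone ROI ~1165 px at 256: synthetic masks scale by exactly
  # (512/256)^2 = 4; anatomical ROIs grew by 3.59 (4185/1165), same order
  m <- matrix(FALSE, 256, 256)
  m[100:133, 101:135] <- TRUE  # 34 x 35 = 1190 px
  scaled <- sum(scaleROI(m, 256, 512))
  expect_lt(abs(scaled - 4 * sum(m)) / (4 * sum(m)), 0.15)
  expect_lt(abs(scaled - 4185) / 4185, 0.2)
})

test_that("scale down then up keeps the mask (Jaccard >= 0.8)", {
  set.seed(1)
  m <- matrix(FALSE, 320, 320)
  m[60:140, 90:200] <- TRUE
  m[150:260, 40:120] <- TRUE
  back <- scaleROI(scaleROI(m, 320, 256), 256, 320)
  jac <- sum(m & back) / sum(m | back)
  expect_gte(jac, 0.8)
})

test_that("roiStats computes population statistics over in-mask pixels", {
  img <- matrix(7, 5, 5)
  st <- roiStats(img, matrix(TRUE, 5, 5))
  expect_equal(st$mean, 7); expect_equal(st$sd, 0)

  img2 <- matrix(c(0, 10), 4, 4)
  st2 <- roiStats(img2, matrix(TRUE, 4, 4))
  expect_equal(st2$mean, 5); expect_equal(st2$sd, 5)

  roi <- randomROI(77)
  st3 <- roiStats(roi$img, roi$mask)
  v <- roi$img[roi$mask]
  expect_equal(st3$mean, sum(v) / length(v), tolerance = 1e-12)
  expect_equal(st3$sd, sqrt(sum((v - mean(v))^2) / length(v)),
               tolerance = 1e-12)
  expect_error(roiStats(matrix(0, 3, 3), matrix(TRUE, 4, 4)), "dimensions")
})

test_that("+/-3 sigma normalization maps the band endpoints and clips", {
  # integer-valued ROI constructed so that mu = 128 and sigma = 32 exactly
  # (all arithmetic dyadic): probes sit at mu - 3s, mu + 3s, mu, mu +/- 4s
  v <- c(32, 224, 128, 256, 0,
         rep(c(96, 160), 27), rep(c(112, 144), 2), rep(128, 42))
  img <- matrix(v, 15, 7)
  msk <- matrix(TRUE, 15, 7)
  st <- roiStats(img, msk)
  expect_equal(st$mean, 128)
  expect_equal(st$sd, 32)
  nrm <- normalizeROI(img, msk)
  expect_equal(nrm[1, 1], 0L)     # pixel at mu - 3 sigma
  expect_equal(nrm[2, 1], 255L)   # pixel at mu + 3 sigma
  expect_equal(nrm[3, 1], 128L)   # pixel at mu: round-half-up of 127.5
  expect_equal(nrm[4, 1], 255L)   # mu + 4 sigma, clipped
  expect_equal(nrm[5, 1], 0L)     # mu - 4 sigma, clipped
  expect_true(all(nrm[msk] >= 0 & nrm[msk] <= 255))
  expect_error(normalizeROI(matrix(1, 4, 4), matrix(TRUE, 4, 4)),
               "degenerate")
})

test_that("normalization is invariant to affine intensity changes", {
  for (seed in 1:5) {
    roi <- randomROI(seed)
    n1 <- normalizeROI(roi$img, roi$mask)
    n2 <- normalizeROI(2.5 * roi$img + 17, roi$mask)
    expect_lte(max(abs(n1 - n2), na.rm = TRUE), 1)
  }
})

test_that("quantization follows the documented per-pixel formula", {
  # full-range on 8-bit with 64 levels is floor(value / 4)
  img <- matrix(0:255, 16, 16)
  q <- quantizeROI(img, matrix(TRUE, 16, 16), 64, "full_range")
  expect_identical(as.vector(q@levels), as.integer(floor(0:255 / 4)))

  two <- matrix(c(3, 9), 4, 4)
  q2 <- quantizeROI(two, matrix(TRUE, 4, 4), 2, "minmax")
  expect_setequal(unique(as.vector(q2@levels)), c(0L, 1L))

  roi <- randomROI(5, ng = 16)
  q3 <- quantizeROI(roi$img, roi$mask, 16, "minmax")
  expect_identical(q3@levels, oracleQuantize(roi$img, roi$mask, 16))

  # min-max mode attains both extreme levels on non-constant ROIs
  for (seed in 6:10) {
    r <- randomROI(seed)
    q4 <- quantizeROI(r$img, r$mask, 32, "minmax")
    lv <- q4@levels[!is.na(q4@levels)]
    expect_equal(min(lv), 0L)
    expect_equal(max(lv), 31L)
  }

  expect_warning(quantizeROI(matrix(5, 4, 4), matrix(TRUE, 4, 4), 8,
                             "minmax"), "constant")
})
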
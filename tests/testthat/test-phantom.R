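test_that("tissue textures are deterministic and respect contrast", {
  cfg <- TissuePhantomConfig("bone", seed = 11)
  a <- generateTissueTexture(cfg, 64)
  b <- generateTissueTexture(cfg, 64)
  expect_identical(a, b)

  for (cls in c("bone", "fat", "muscle")) {
    flat <- TissuePhantomConfig(cls, contrast = 0, baseIntensity = 42,
                                seed = 1)
    img <- generateTissueTexture(flat, 32)
    expect_equal(img, matrix(42, 32, 32))
  }

  cf <- TissuePhantomConfig("bone", seed = 1)
  cf@tissueClass <- "liver"
  expect_error(generateTissueTexture(cf, 64), "liver")
})

test_that("tissue classes are texturally distinguishable (GLCM contrast)", {
  contrastOf <- function(cls) {
    cfg <- TissuePhantomConfig(cls, seed = 0)
    img <- generateTissueTexture(cfg, 128)
    q <- quantizeROI(img, matrix(TRUE, 128, 128))
    glcmFeatures(glcm(q, "0", 1))[["contrast"]]
  }
  cb <- contrastOf("bone"); cf <- contrastOf("fat"); cm <- contrastOf("muscle")
  expect_gt(cb, cm)
  expect_gt(cb, cf)
})

test_that("k-space crop at the reference size is the identity", {
  cfg <- TissuePhantomConfig("fat", seed = 3)
  ref <- generateTissueTexture(cfg, 64)
  sp <- AcquisitionSpec(64, noiseScale = 0, referenceMatrix = 64)
  out <- simulateAcquisition(ref, sp)
  expect_lt(max(abs(out - ref)) / max(abs(ref)), 1e-9)
})

test_that("unitary cropping preserves the retained k-space energy (Parseval)", {
  set.seed(42)
  R <- 64L; m <- 32L
  ref <- matrix(rnorm(R * R), R, R)
  sp <- AcquisitionSpec(m, noiseScale = 0, referenceMatrix = R)
  out <- simulateAcquisition(ref, sp, scaling = "unitary")
  # retained coefficients under the unitary forward convention fft/R, with
  # the unpaired Nyquist row/column zeroed as the simulator does
  FF <- TexConcord:::.fftshift2(fft(ref)) / R
  ctr <- R %/% 2L + 1L
  keep <- (ctr - m %/% 2L):(ctr + m %/% 2L - 1L)
  G <- FF[keep, keep]
  G[1, ] <- 0; G[, 1] <- 0
  expect_equal(sum(out^2), sum(Mod(G)^2), tolerance = 1e-10)
})

test_that("low-pass cropping reduces the variance of a pure-noise image", {
  lower <- vapply(1:20, function(s) {
    set.seed(s)
    ref <- matrix(rnorm(128 * 128), 128, 128)
    sp <- AcquisitionSpec(64, noiseScale = 0, referenceMatrix = 128)
    out <- simulateAcquisition(ref, sp)
    var(as.vector(out)) < var(as.vector(ref))
  }, logical(1))
  expect_true(all(lower))
})

test_that("upsampling and odd sizes are rejected", {
  ref <- matrix(0, 64, 64)
  expect_error(simulateAcquisition(
    ref, AcquisitionSpec(128, referenceMatrix = 64)), "upsampling")
  expect_error(AcquisitionSpec(63), "even")
})

test_that("noiseless sharpness is non-decreasing in matrix size", {
  # blur monotonicity: per-mm mean gradient amplitude of the simulated
  # composite image grows as more of the k-space periphery is retained
  sizes <- c(64L, 96L, 128L)
  R <- 128L
  for (seed in 1:10) {
    ps <- buildPhantomSeries(2, sizes, masterSeed = seed, nSlices = 1,
                             noiseScale = 0, referenceMatrix = R)
    sh <- vapply(sizes, function(m) {
      img <- phantomImage(ps, 1, m, 1)
      roiSharpness(img, matrix(TRUE, m, m), pixelSpacingMM = 200 / m)
    }, numeric(1))
    expect_true(all(diff(sh) >= 0))
  }
})

test_that("noise grows with matrix size on a flat reference", {
  R <- 128L
  flat <- matrix(100, R, R)
  sds <- vapply(c(64L, 96L, 128L), function(m) {
    sp <- AcquisitionSpec(m, noiseScale = 5, referenceMatrix = R)
    out <- simulateAcquisition(flat, sp, seed = 99)
    sd(as.vector(out))
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("phantom series structure, determinism and ROI scaling", {
  sizes <- c(64L, 128L)
  ps <- buildPhantomSeries(3, sizes, masterSeed = 5, nSlices = 2,
                           noiseScale = 2, referenceMatrix = 128)
  expect_equal(nSubjects(ps), 3)
  expect_equal(matrixSizes(ps), sizes)
  # image count: subjects x matrices x slices
  nImages <- sum(vapply(seq_len(3), function(s)
    sum(vapply(as.character(sizes), function(m)
      dim(ps@images[[s]][[m]])[3], numeric(1))), numeric(1)))
  expect_equal(nImages, 3 * 2 * 2)
  # ROI records: subjects x matrices x slices x tissues
  expect_equal(nImages * length(tissueLabels(ps)), 3 * 2 * 2 * 3)

  ps2 <- buildPhantomSeries(3, sizes, masterSeed = 5, nSlices = 2,
                            noiseScale = 2, referenceMatrix = 128)
  expect_identical(ps@images, ps2@images)

  # mask areas scale with the squared matrix ratio (up to boundary rounding)
  for (tis in tissueLabels(ps)) {
    ratio <- sum(phantomMask(ps, 128, tis)) / sum(phantomMask(ps, 64, tis))
    expect_lt(abs(ratio - 4), 0.6)
  }
})

test_that("all matrix sizes of a slice derive from one reference (pairing)", {
  ps <- buildPhantomSeries(2, c(64L, 128L), masterSeed = 9, nSlices = 1,
                           noiseScale = 0, referenceMatrix = 128)
  # with the largest size equal to the reference, the smaller matrix must be
  # exactly the k-space crop of the larger image
  big <- phantomImage(ps, 1, 128, 1)
  small <- phantomImage(ps, 1, 64, 1)
  sp <- AcquisitionSpec(64, noiseScale = 0, referenceMatrix = 128)
  expect_equal(small, simulateAcquisition(big, sp), tolerance = 1e-12)
})
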
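test_that("2D extraction emits the full 307-feature registry", {
  reg <- featureRegistry("2D")
  expect_equal(nrow(reg), 307)
  expect_false(any(duplicated(reg$name)))

  img <- generateTissueTexture(TissuePhantomConfig("fat", seed = 2), 64)
  fv <- extractAll(img, matrix(TRUE, 64, 64))
  expect_equal(length(fv), 307)
  expect_identical(names(fv), reg$name)
  counts <- table(attr(fv, "families"))
  expect_equal(unname(counts[c("GLCM", "GRLM", "GRA", "ARM", "DWT", "HIST",
                               "GAB", "HOG")]),
               c(220, 20, 5, 5, 16, 9, 24, 8), ignore_attr = TRUE)

  fv2 <- extractAll(img, matrix(TRUE, 64, 64))
  expect_identical(fv, fv2)
})

test_that("extraction is a pure function of the in-mask content", {
  img <- generateTissueTexture(TissuePhantomConfig("bone", seed = 6), 96)
  msk <- matrix(FALSE, 96, 96); msk[20:75, 25:80] <- TRUE
  a <- extractAll(img, msk)
  # embed the same ROI elsewhere in a larger, different image
  img2 <- matrix(rnorm(128 * 128), 128, 128)
  msk2 <- matrix(FALSE, 128, 128)
  img2[41:96, 31:86] <- img[20:75, 25:80]
  msk2[41:96, 31:86] <- TRUE
  b <- extractAll(img2, msk2)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("3D extraction: registry, constant volumes and in-plane consistency", {
  reg <- featureRegistry("3D")
  expect_equal(nrow(reg), 794)
  expect_equal(unname(table(reg$family)[c("GLCM", "GRLM", "GRA", "HIST")]),
               c(715, 65, 5, 9), ignore_attr = TRUE)

  vol <- array(5, c(24, 24, 5))
  msk <- array(TRUE, c(24, 24, 5))
  fv <- suppressWarnings(extractAll(vol, msk, mode = "3D"))
  ctr <- fv[grep("glcm3d_contrast", names(fv))]
  expect_true(all(ctr[!is.na(ctr)] == 0))

  # a volume of identical slices: in-plane 3D GLCM equals the 2D GLCM
  img <- generateTissueTexture(TissuePhantomConfig("fat", seed = 9), 48)
  vol2 <- array(rep(img, 5), c(48, 48, 5))
  msk2 <- array(TRUE, c(48, 48, 5))
  f3 <- extractAll(vol2, msk2, mode = "3D")
  f2 <- extractAll(img, matrix(TRUE, 48, 48))
  # 2D "0" (0,1) <-> 3D "0.1.0"; "90" (1,0) <-> "1.0.0";
  # "135" (1,1) <-> "1.1.0"; "45" (-1,1) <-> "1.-1.0"
  map <- c("0" = "0.1.0", "90" = "1.0.0", "135" = "1.1.0", "45" = "1.-1.0")
  for (st in c("contrast", "entropy", "correlation", "asm")) {
    for (d2 in names(map)) {
      for (k in 1:3) {
        expect_equal(
          f3[[paste0("glcm3d_", st, "_", map[[d2]], "_d", k)]],
          f2[[paste0("glcm_", st, "_", d2, "_d", k)]],
          tolerance = 1e-12)
      }
    }
  }
  expect_error(extractAll(img, matrix(TRUE, 48, 48), mode = "3D"),
               "multi-slice")
})

test_that("slice averaging is an element-wise mean with name checks", {
  v <- stats::setNames(c(1, 2, 3), c("a", "b", "c"))
  expect_equal(averageOverSlices(list(v)), v)
  expect_equal(averageOverSlices(list(v, 3 * v)), 2 * v)

  set.seed(3)
  nm <- featureRegistry("2D")$name[1:20]
  vecs <- lapply(1:5, function(i) stats::setNames(rnorm(20), nm))
  avg <- averageOverSlices(vecs)
  expect_equal(unname(avg), unname(colMeans(do.call(rbind, vecs))),
               tolerance = 1e-12)

  w <- stats::setNames(1:3, c("a", "b", "x"))
  expect_error(averageOverSlices(list(v, w)), "names differ")
})
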
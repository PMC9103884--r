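# Canonical feature registry and the full per-ROI extraction.

.dirs2D <- c("0", "45", "90", "135")
.glcmDistances <- 1:5
.gaborEnvelopes <- c(4, 6, 8, 12, 16, 24)

# Canonical ordering: families in the conventional listing order, then
# statistic, then direction, then distance/scale. Frozen here; extractAll()
# and the CSV writers all derive their column order from these functions.
.featureNames2D <- function() {
  glcm <- as.vector(vapply(.glcmStatNames, function(st)
    vapply(.dirs2D, function(d)
      paste0("glcm_", st, "_", d, "_d", .glcmDistances), character(5)),
    character(20)))
  rlm <- as.vector(vapply(.rlmStatNames, function(st)
    paste0("rlm_", st, "_", .dirs2D), character(4)))
  haar <- paste0("haar_en_", rep(.haarBands, each = 4), "_s", 1:4)
  gab <- paste0("gabor_mag_", rep(c(0, 45, 90, 135), each = 6), "_s",
                rep(.gaborEnvelopes, 4))
  hog <- paste0("hog_bin", 1:8)
  list(names = c(glcm, rlm, .gradStatNames, .arStatNames, haar,
                 .histStatNames, gab, hog),
       families = c(rep("GLCM", 220), rep("GRLM", 20), rep("GRA", 5),
                    rep("ARM", 5), rep("DWT", 16), rep("HIST", 9),
                    rep("GAB", 24), rep("HOG", 8)))
}

.featureNames3D <- function() {
  dirs <- names(.offsets3D())
  glcm <- as.vector(vapply(.glcmStatNames, function(st)
    vapply(dirs, function(d)
      paste0("glcm3d_", st, "_", d, "_d", .glcmDistances), character(5)),
    character(65)))
  rlm <- as.vector(vapply(.rlmStatNames, function(st)
    paste0("rlm3d_", st, "_", dirs), character(13)))
  list(names = c(glcm, rlm, .gradStatNames, .histStatNames),
       families = c(rep("GLCM", 715), rep("GRLM", 65), rep("GRA", 5),
                    rep("HIST", 9)))
}

#' Canonical texture-feature registry
#'
#' The frozen name/family registry defining the order of every feature
#' vector produced by [extractAll()]. The 2D set has 307 entries (GLCM 220,
#' GRLM 20, GRA 5, ARM 5, DWT 16, HIST 9, GAB 24, HOG 8); the 3D subset has
#' 794 (GLCM over the 13 unique offsets of the 26-neighbourhood, GRLM over
#' 13 directions, 3D gradient and histogram).
#'
#' @param mode `"2D"` or `"3D"`.
#' @return data.frame with columns `name` and `family`.
#' @examples
#' table(featureRegistry("2D")$family)
#' @export
featureRegistry <- function(mode = c("2D", "3D")) {
  mode <- match.arg(mode)
  fn <- if (mode == "2D") .featureNames2D() else .featureNames3D()
  data.frame(name = fn$names, family = fn$families)
}

# reorder a (stat x direction [x distance]) block computed direction-major
# into the canonical stat-major order
.blockByStat <- function(values, statNames, dirNames, distances = NULL) {
  # values: list indexed [[dir]][[dist]] -> named stat vector (or
  # [[dir]] -> named stat vector when distances is NULL)
  out <- numeric(0)
  for (st in statNames) {
    for (d in dirNames) {
      if (is.null(distances)) {
        out <- c(out, values[[d]][[st]])
      } else {
        for (k in seq_along(distances)) out <- c(out, values[[d]][[k]][[st]])
      }
    }
  }
  out
}

#' Extract the full texture-feature vector of one ROI
#'
#' Computes every feature family on a single 2D ROI (307 features) or on a
#' multi-slice ROI volume (3D subset: co-occurrence and run-length over the
#' 13 unique 3D offsets, 3D gradient, histogram; 794 features). Gray-level
#' quantization for the co-occurrence/run-length families uses in-ROI
#' min-max bounds with `nLevels` levels; all other families operate on the
#' supplied intensities.
#'
#' @param roiImage numeric matrix (2D mode) or 3D array (3D mode).
#' @param mask logical mask of identical dimensions.
#' @param mode `"2D"` or `"3D"`.
#' @param nLevels gray levels for quantization (default 64).
#' @return named numeric vector in registry order, with attributes
#'   `families` and `mode`.
#' @examples
#' img <- generateTissueTexture(TissuePhantomConfig("bone", seed = 1), 64)
#' fv <- extractAll(img, matrix(TRUE, 64, 64))
#' length(fv)  # 307
#' @export
extractAll <- function(roiImage, mask, mode = c("2D", "3D"), nLevels = 64L) {
  mode <- match.arg(mode)
  mask <- .checkImageMask(roiImage, mask)
  # crop to the mask bounding box: every family is a pure function of the
  # in-mask content, and the cost then scales with the ROI, not the image
  if (length(dim(roiImage)) == 2L) {
    bb <- .maskBBox(mask)
    roiImage <- roiImage[bb$rows, bb$cols, drop = FALSE]
    mask <- mask[bb$rows, bb$cols, drop = FALSE]
  } else {
    bb <- .maskBBox(rowSums(mask, dims = 2) > 0)
    roiImage <- roiImage[bb$rows, bb$cols, , drop = FALSE]
    mask <- mask[bb$rows, bb$cols, , drop = FALSE]
  }
  if (mode == "3D") {
    if (length(dim(roiImage)) != 3L || dim(roiImage)[3] < 2L)
      stop("3D mode requires a multi-slice volume")
    q <- quantizeROI(roiImage, mask, nLevels, "minmax")
    dirs <- names(.offsets3D())
    o3 <- .offsets3D()
    vals <- lapply(dirs, function(d)
      lapply(.glcmDistances, function(k) {
        tryCatch(.glcmFeaturesInternal(q@levels, o3[[d]] * k, q@nLevels),
                 error = function(e) stats::setNames(
                   rep(NA_real_, 11), .glcmStatNames))
      }))
    names(vals) <- dirs
    glcmv <- .blockByStat(vals, .glcmStatNames, dirs, .glcmDistances)
    rvals <- lapply(dirs, function(d) rlmFeatures(q, d))
    names(rvals) <- dirs
    rlmv <- .blockByStat(rvals, .rlmStatNames, dirs)
    out <- c(glcmv, rlmv, gradientFeatures(roiImage, mask),
             histogramFeatures(roiImage, mask))
    reg <- .featureNames3D()
    names(out)[seq_len(715 + 65)] <- reg$names[seq_len(715 + 65)]
  } else {
    if (length(dim(roiImage)) == 3L) {
      roiImage <- roiImage[, , 1]; mask <- mask[, , 1]
    }
    q <- quantizeROI(roiImage, mask, nLevels, "minmax")
    vals <- lapply(.dirs2D, function(d)
      lapply(.glcmDistances, function(k)
        .glcmFeaturesInternal(q@levels, .dirOffset2D(d) * k, q@nLevels)))
    names(vals) <- .dirs2D
    glcmv <- .blockByStat(vals, .glcmStatNames, .dirs2D, .glcmDistances)
    rvals <- lapply(.dirs2D, function(d) rlmFeatures(q, d))
    names(rvals) <- .dirs2D
    rlmv <- .blockByStat(rvals, .rlmStatNames, .dirs2D)
    out <- c(glcmv, rlmv, gradientFeatures(roiImage, mask),
             arFeatures(roiImage, mask), haarFeatures(roiImage, mask),
             histogramFeatures(roiImage, mask),
             gaborFeatures(roiImage, mask), hogFeatures(roiImage, mask))
    reg <- .featureNames2D()
    names(out)[seq_len(220 + 20)] <- reg$names[seq_len(220 + 20)]
  }
  # reorder named components (e.g. Haar energies are computed scale-major
  # but registered band-major) into the frozen registry order
  if (anyNA(match(reg$names, names(out))))
    stop("internal error: extracted features do not match the registry")
  out <- out[reg$names]
  attr(out, "families") <- reg$families
  attr(out, "mode") <- mode
  out
}

#' Element-wise mean of per-slice feature vectors
#'
#' Averages the feature vectors obtained for the same ROI on several slices
#' (texture parameters are summarized per subject as the mean over the
#' analyzed layers, before any between-matrix comparison).
#'
#' @param vectors list of feature vectors from [extractAll()] with identical
#'   names.
#' @return a feature vector of the same length and names.
#' @examples
#' v <- stats::setNames(1:3, c("a", "b", "c"))
#' averageOverSlices(list(v, 3 * v))  # 2 * v
#' @export
averageOverSlices <- function(vectors) {
  stopifnot(length(vectors) >= 1L)
  nm <- names(vectors[[1]])
  for (v in vectors) {
    if (!identical(names(v), nm))
      stop("feature names differ between slices")
  }
  out <- rowMeans(do.call(cbind, vectors))
  names(out) <- nm
  attributes(out) <- attributes(vectors[[1]])
  out
}
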
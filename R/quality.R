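# ROI signal-to-noise and sharpness comparator metrics.

#' ROI signal-to-noise ratio
#'
#' Two estimators: the default within-ROI estimator `mean(ROI) / sd(ROI)`
#' (no background region required), and a background estimator
#' `mean(ROI) / sd(noiseMask)` when a disjoint noise region is supplied.
#' Both are invariant under global intensity scaling. A zero noise estimate
#' yields `Inf` (callers exclude infinite values from means).
#'
#' @param image numeric matrix.
#' @param roiMask logical mask.
#' @param noiseMask optional logical mask, disjoint from `roiMask`.
#' @return single numeric (possibly `Inf`).
#' @examples
#' img <- matrix(rnorm(400, 100, 10), 20)
#' roiSNR(img, matrix(TRUE, 20, 20))
#' @export
roiSNR <- function(image, roiMask, noiseMask = NULL) {
  roiMask <- .checkImageMask(image, roiMask)
  st <- roiStats(image, roiMask)
  if (is.null(noiseMask)) {
    if (st$sd == 0) return(Inf)
    return(st$mean / st$sd)
  }
  noiseMask <- .checkImageMask(image, noiseMask)
  if (any(roiMask & noiseMask)) stop("noiseMask must be disjoint from roiMask")
  ns <- roiStats(image, noiseMask)
  if (ns$sd == 0) return(Inf)
  st$mean / ns$sd
}

#' ROI sharpness (mean gradient amplitude)
#'
#' Mean gradient magnitude over the eroded mask, using the same 3x3
#' Sobel-type operator as [gradientFeatures()]. With `pixelSpacingMM` set,
#' the gradient is expressed per millimetre instead of per pixel, so the
#' measure quantifies physical blur independently of how densely the fixed
#' field of view is sampled.
#'
#' @param image numeric matrix.
#' @param roiMask logical mask.
#' @param pixelSpacingMM pixel spacing in mm (default 1: per-pixel units).
#' @return single nonnegative numeric.
#' @examples
#' ramp <- matrix(rep(1:32, each = 32), 32)
#' roiSharpness(ramp, matrix(TRUE, 32, 32))  # 1 (unit ramp)
#' @export
roiSharpness <- function(image, roiMask, pixelSpacingMM = 1) {
  roiMask <- .checkImageMask(image, roiMask)
  gm <- .gradientMagnitude(image, roiMask)
  mean(gm$g) / pixelSpacingMM
}

#' SNR and sharpness report for a phantom series
#'
#' Computes the mean ROI SNR and mean per-mm sharpness across subjects and
#' slices, for every (matrix size, tissue) combination of the series. These
#' are the two opposing image-quality trends against which the
#' texture-concordance curves are interpreted: with a fixed field of view,
#' noise grows with matrix size (smaller voxels, less signal) while
#' sharpness grows with matrix size (more of the k-space periphery is
#' sampled).
#'
#' @param series a [PhantomSeries-class].
#' @param fovMM field of view in mm used to convert sharpness to per-mm
#'   units; defaults to the series provenance.
#' @return a [QualityReport-class].
#' @export
qualityReport <- function(series, fovMM = NULL) {
  stopifnot(is(series, "PhantomSeries"))
  if (is.null(fovMM)) fovMM <- series@provenance$fovMM %||% 200
  rows <- list()
  for (m in series@matrixSizes) {
    spacing <- fovMM / m
    for (tis in series@tissues) {
      msk <- phantomMask(series, m, tis)
      snrs <- c(); shps <- c()
      for (s in seq_len(nSubjects(series))) {
        for (sl in seq_len(series@nSlices)) {
          img <- phantomImage(series, s, m, sl)
          snrs <- c(snrs, roiSNR(img, msk))
          shps <- c(shps, roiSharpness(img, msk, pixelSpacingMM = spacing))
        }
      }
      snrs <- snrs[is.finite(snrs)]
      rows[[paste(m, tis)]] <- data.frame(
        matrix_size = m, tissue = tis,
        snr_mean = mean(snrs), sharpness_mean = mean(shps),
        estimator = "within_roi", n = length(shps))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("QualityReport", table = tab)
}
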
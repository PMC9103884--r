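# ROI handling: proportional mask scaling, intensity statistics, +/-3 sigma
# normalization and gray-level quantization.

#' Scale an ROI mask between acquisition matrices
#'
#' Rescales a binary mask from one matrix size to another with
#' nearest-neighbor sampling, so the mask area scales (up to boundary
#' rounding) with `(toMatrix / fromMatrix)^2`, mirroring ROIs drawn in
#' proportion to the fixed field of view.
#'
#' @param mask logical (or 0/1) matrix.
#' @param fromMatrix,toMatrix positive integers; the mask dimensions must
#'   match `fromMatrix`.
#' @return logical `toMatrix x toMatrix` matrix.
#' @examples
#' m <- matrix(FALSE, 256, 256); m[101:110, 101:110] <- TRUE
#' sum(scaleROI(m, 256, 512)) / sum(m)  # ~4
#' @export
scaleROI <- function(mask, fromMatrix, toMatrix) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!any(mask)) stop("mask is empty")
  fromMatrix <- as.integer(fromMatrix); toMatrix <- as.integer(toMatrix)
  stopifnot(fromMatrix > 0L, toMatrix > 0L)
  if (nrow(mask) != fromMatrix || ncol(mask) != fromMatrix)
    stop("mask dimensions must equal fromMatrix")
  if (fromMatrix == toMatrix) return(mask)
  # output pixel centre (i - 0.5) maps to input index floor((i-0.5)*f/t) + 1
  idx <- pmin(fromMatrix,
              pmax(1L, floor((seq_len(toMatrix) - 0.5) *
                               fromMatrix / toMatrix) + 1L))
  mask[idx, idx, drop = FALSE]
}

#' ROI intensity statistics
#'
#' Population statistics (divisor `n`) over in-mask pixels, plus the
#' `mu +/- 3 sigma` normalization bounds.
#'
#' @param image numeric matrix (or 3D array).
#' @param mask logical mask of identical dimensions.
#' @return list with `mean`, `sd`, `min`, `max`, `n`, `minNorm`
#'   (`mean - 3*sd`) and `maxNorm` (`mean + 3*sd`).
#' @examples
#' img <- matrix(c(0, 10), 2, 2)
#' roiStats(img, matrix(TRUE, 2, 2))$sd  # 5
#' @export
roiStats <- function(image, mask) {
  mask <- .checkImageMask(image, mask)
  v <- image[mask]
  mu <- mean(v)
  sdp <- sqrt(sum((v - mu)^2) / length(v))
  list(mean = mu, sd = sdp, min = min(v), max = max(v), n = length(v),
       minNorm = mu - 3 * sdp, maxNorm = mu + 3 * sdp)
}

#' +/- 3 sigma ROI intensity normalization
#'
#' Remaps in-mask intensities linearly so that `mu - 3*sigma` maps to 0 and
#' `mu + 3*sigma` maps to 255, with round-half-up to integers and clipping
#' to `[0, 255]`:
#' `N(x, y) = round(255 * (I(x, y) - (mu - 3*sigma)) / (6*sigma))`.
#' Out-of-mask pixels are `NA` (invalid).
#'
#' @param image numeric matrix or 3D array.
#' @param mask logical mask of identical dimensions.
#' @return integer matrix/array of normalized 8-bit intensities, `NA`
#'   outside the mask.
#' @examples
#' img <- matrix(rnorm(64, 100, 10), 8)
#' rng <- range(normalizeROI(img, matrix(TRUE, 8, 8)), na.rm = TRUE)
#' stopifnot(rng[1] >= 0, rng[2] <= 255)
#' @export
normalizeROI <- function(image, mask) {
  mask <- .checkImageMask(image, mask)
  st <- roiStats(image, mask)
  if (st$sd == 0) stop("degenerate ROI: zero intensity variance")
  out <- array(NA_real_, dim = dim(image))
  out[mask] <- pmin(255, pmax(0, .roundHalfUp(
    255 * (image[mask] - st$minNorm) / (st$maxNorm - st$minNorm))))
  storage.mode(out) <- "integer"
  out
}

#' Quantize ROI intensities to Ng gray levels
#'
#' Maps in-mask intensities to integer levels `0 .. Ng - 1`, as required by
#' co-occurrence and run-length analysis. In `"minmax"` mode the bounds are
#' the in-mask minimum/maximum (`level = floor(Ng * (I - min) / (max - min +
#' eps))`, so the maximum attains `Ng - 1`); in `"full_range"` mode the
#' bounds are the bit-depth range `[0, 2^bitDepth - 1]`.
#'
#' @param roiImage numeric matrix or 3D array.
#' @param mask logical mask of identical dimensions.
#' @param nLevels integer >= 2 (default 64).
#' @param mode `"minmax"` (default) or `"full_range"`.
#' @param bitDepth bit depth used by `"full_range"` (default 8).
#' @return a [QuantizedROI-class].
#' @examples
#' q <- quantizeROI(matrix(0:255, 16), matrix(TRUE, 16, 16), 64, "full_range")
#' range(q@levels)  # 0 63
#' @export
quantizeROI <- function(roiImage, mask, nLevels = 64L,
                        mode = c("minmax", "full_range"), bitDepth = 8L) {
  mode <- match.arg(mode)
  mask <- .checkImageMask(roiImage, mask)
  nLevels <- as.integer(nLevels)
  if (nLevels < 2L) stop("nLevels must be >= 2")
  v <- as.numeric(roiImage[mask])
  if (mode == "minmax") {
    lo <- min(v); hi <- max(v)
    if (hi == lo) {
      warning("constant ROI in minmax mode; all levels set to 0")
      lev <- rep(0L, length(v))
    } else {
      lev <- as.integer(floor(nLevels * (v - lo) /
                                ((hi - lo) * (1 + 1e-9))))
    }
  } else {
    lo <- 0; hi <- 2^bitDepth - 1
    lev <- as.integer(floor(nLevels * (v - lo) / ((hi - lo) * (1 + 1e-9))))
    lev <- pmin(nLevels - 1L, pmax(0L, lev))
  }
  levels <- array(NA_integer_, dim = dim(roiImage))
  levels[mask] <- lev
  new("QuantizedROI", levels = levels, mask = array(mask, dim = dim(mask)),
      nLevels = nLevels, bounds = c(lo, hi))
}
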
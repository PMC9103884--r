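# First-order, gradient, autoregressive and HOG features.

# 3D Sobel-type gradient (derivative [-1 0 1]/2 along one axis, [1 2 1]/4
# smoothing along the two others), normalized so a unit ramp gives 1.
.sobelGradient3D <- function(vol) {
  d <- dim(vol)
  sm <- function(dr, dc, ds) {
    out <- array(0, d)
    rs <- max(1L, 1L + dr):min(d[1], d[1] + dr)
    cs <- max(1L, 1L + dc):min(d[2], d[2] + dc)
    ss <- max(1L, 1L + ds):min(d[3], d[3] + ds)
    out[rs, cs, ss] <- vol[rs - dr, cs - dc, ss - ds]
    out
  }
  w <- c(1, 2, 1) / 4
  dv <- c(-1, 0, 1) / 2
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  for (a in -1:1) for (b in -1:1) for (cc in -1:1) {
    # sm(dr,dc,ds) holds vol[r - dr, ...]: use negative shifts for +offsets
    v <- sm(-a, -b, -cc)
    gy <- gy + dv[a + 2] * w[b + 2] * w[cc + 2] * v
    gx <- gx + w[a + 2] * dv[b + 2] * w[cc + 2] * v
    gz <- gz + w[a + 2] * w[b + 2] * dv[cc + 2] * v
  }
  sqrt(gx^2 + gy^2 + gz^2)
}

.gradientMagnitude <- function(roiImage, mask) {
  if (length(dim(roiImage)) == 3L && dim(roiImage)[3] > 1L) {
    em <- .erodeMask3d(mask)
    if (!any(em)) stop("eroded mask is empty")
    roiImage[is.na(roiImage)] <- 0
    g <- .sobelGradient3D(roiImage)
    list(g = g[em], em = em)
  } else {
    if (length(dim(roiImage)) == 3L) {
      roiImage <- roiImage[, , 1]; mask <- mask[, , 1]
    }
    # the operator only ever contributes inside the mask bounding box;
    # cropping keeps the cost proportional to the ROI, not the image
    bb <- .maskBBox(mask)
    roiImage <- roiImage[bb$rows, bb$cols, drop = FALSE]
    mask <- mask[bb$rows, bb$cols, drop = FALSE]
    em <- .erodeMask3(mask)
    if (!any(em)) stop("eroded mask is empty")
    roiImage[is.na(roiImage)] <- 0
    gr <- .sobelGradient(roiImage)
    list(g = sqrt(gr$gx^2 + gr$gy^2)[em], em = em)
  }
}

.gradStatNames <- c("grad_mean", "grad_variance", "grad_skewness",
                    "grad_kurtosis", "grad_nonzero_frac")

#' Gradient-matrix features
#'
#' Gradient magnitudes from a 3x3 Sobel-type operator (3D Sobel on volumes),
#' evaluated on the mask eroded by one pixel so the operator support stays
#' in-mask. Features: mean, variance, skewness and excess kurtosis of the
#' magnitude, and the fraction of pixels with a nonzero gradient.
#'
#' @param roiImage numeric matrix or 3D array.
#' @param mask logical mask of identical dimensions.
#' @return named numeric vector of length 5.
#' @examples
#' gradientFeatures(matrix(rnorm(256), 16), matrix(TRUE, 16, 16))
#' @export
gradientFeatures <- function(roiImage, mask) {
  mask <- .checkImageMask(roiImage, mask)
  gm <- .gradientMagnitude(roiImage, mask)
  ms <- .momentStats(gm$g)
  tol <- 1e-10 * max(1, max(abs(gm$g)))
  out <- c(ms[["mean"]], ms[["variance"]], ms[["skewness"]],
           ms[["kurtosis"]], mean(gm$g > tol))
  names(out) <- .gradStatNames
  out
}

.arStatNames <- c("ar_theta1", "ar_theta2", "ar_theta3", "ar_theta4",
                  "ar_sigma")

#' Causal autoregressive texture model
#'
#' Least-squares fit of the first-order causal AR model
#' `I(x, y) = t1*I(x-1, y) + t2*I(x-1, y-1) + t3*I(x, y-1) + t4*I(x+1, y-1)`
#' on mean-subtracted in-mask intensities (x runs along columns, y along
#' rows; the four neighbors are the previously scanned ones in raster
#' order). Returns the four weights and the residual standard deviation.
#'
#' @param roiImage numeric matrix.
#' @param mask logical mask; at least 100 pixels must have all four causal
#'   neighbors in-mask.
#' @return named numeric vector of length 5.
#' @examples
#' arFeatures(matrix(rnorm(1024), 32), matrix(TRUE, 32, 32))
#' @export
arFeatures <- function(roiImage, mask) {
  mask <- .checkImageMask(roiImage, mask)
  if (length(dim(roiImage)) == 3L) {
    roiImage <- roiImage[, , 1]; mask <- mask[, , 1]
  }
  # neighbor (x-1, y) is (r, c-1); (x-1, y-1) is (r-1, c-1); etc.
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  ok <- mask
  nb <- vector("list", 4L)
  for (k in 1:4) {
    ok <- ok & .shiftMat(mask, offs[[k]][1], offs[[k]][2], fill = FALSE)
    nb[[k]] <- .shiftMat(roiImage, offs[[k]][1], offs[[k]][2], fill = 0)
  }
  nOK <- sum(ok)
  if (nOK < 100L)
    stop("AR model needs >= 100 pixels with causal neighbors in-mask (got ",
         nOK, ")")
  mu <- mean(roiImage[mask])
  y <- roiImage[ok] - mu
  X <- cbind(nb[[1]][ok], nb[[2]][ok], nb[[3]][ok], nb[[4]][ok]) - mu
  theta <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                    error = function(e) stop("singular AR normal equations ",
                                             "(constant ROI?)"))
  res <- y - X %*% theta
  out <- c(as.vector(theta), sqrt(sum(res^2) / nOK))
  names(out) <- .arStatNames
  out
}

.histStatNames <- c("hist_mean", "hist_variance", "hist_skewness",
                    "hist_kurtosis", "hist_p01", "hist_p10", "hist_p50",
                    "hist_p90", "hist_p99")

#' First-order histogram features
#'
#' Mean, variance (population), skewness and excess kurtosis of in-mask
#' intensities, plus the 1st, 10th, 50th, 90th and 99th percentiles
#' (nearest-rank definition: the `ceil(q * n)`-th order statistic).
#'
#' @param roiImage numeric matrix or 3D array.
#' @param mask logical mask of identical dimensions.
#' @return named numeric vector of length 9.
#' @examples
#' histogramFeatures(matrix(1:100, 10), matrix(TRUE, 10, 10))[["hist_p90"]]
#' @export
histogramFeatures <- function(roiImage, mask) {
  mask <- .checkImageMask(roiImage, mask)
  v <- sort(as.numeric(roiImage[mask]))
  n <- length(v)
  ms <- .momentStats(v)
  pct <- v[pmax(1L, ceiling(c(0.01, 0.10, 0.50, 0.90, 0.99) * n))]
  out <- c(ms[["mean"]], ms[["variance"]], ms[["skewness"]],
           ms[["kurtosis"]], pct)
  names(out) <- .histStatNames
  out
}

#' Histogram of oriented gradients
#'
#' Signed gradient orientations (`atan2`, mapped to `[0, 360)` degrees) on
#' the eroded mask, binned into `nBins` equal bins weighted by gradient
#' magnitude and normalized to sum to 1. An all-zero gradient field yields a
#' uniform histogram with a warning.
#'
#' @param roiImage numeric matrix.
#' @param mask logical mask.
#' @param nBins number of orientation bins (default 8).
#' @return named numeric vector (`hog_bin1` .. `hog_bin8` containing bins
#'   starting at 0, 45, ... degrees).
#' @examples
#' ramp <- matrix(rep(1:16, each = 16), 16)   # intensity grows along columns
#' hogFeatures(ramp, matrix(TRUE, 16, 16))    # mass in the 0-degree bin
#' @export
hogFeatures <- function(roiImage, mask, nBins = 8L) {
  mask <- .checkImageMask(roiImage, mask)
  if (length(dim(roiImage)) == 3L) {
    roiImage <- roiImage[, , 1]; mask <- mask[, , 1]
  }
  bb <- .maskBBox(mask)
  roiImage <- roiImage[bb$rows, bb$cols, drop = FALSE]
  mask <- mask[bb$rows, bb$cols, drop = FALSE]
  em <- .erodeMask3(mask)
  if (!any(em)) stop("eroded mask is empty")
  roiImage[is.na(roiImage)] <- 0
  gr <- .sobelGradient(roiImage)
  gx <- gr$gx[em]; gy <- gr$gy[em]
  mag <- sqrt(gx^2 + gy^2)
  nBins <- as.integer(nBins)
  nm <- paste0("hog_bin", seq_len(nBins))
  if (all(mag <= 1e-12 * max(1, max(abs(roiImage[mask]))))) {
    warning("all gradients are zero; returning a uniform HOG")
    out <- rep(1 / nBins, nBins)
    names(out) <- nm
    return(out)
  }
  ang <- (atan2(gy, gx) * 180 / pi) %% 360
  bin <- pmin(nBins, floor(ang / (360 / nBins)) + 1L)
  h <- vapply(seq_len(nBins), function(b) sum(mag[bin == b]), numeric(1))
  out <- h / sum(h)
  names(out) <- nm
  out
}
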
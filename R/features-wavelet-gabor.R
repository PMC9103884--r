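# Haar wavelet sub-band energies and Gabor filter-bank magnitudes.

.haarBands <- c("ll", "lh", "hl", "hh")

# one orthonormal 2D Haar analysis step on even-cropped x; returns the four
# sub-band coefficient matrices and the down-sampled validity mask
.haarStep <- function(x, msk) {
  nr <- (nrow(x) %/% 2L) * 2L
  nc <- (ncol(x) %/% 2L) * 2L
  x <- x[seq_len(nr), seq_len(nc), drop = FALSE]
  msk <- msk[seq_len(nr), seq_len(nc), drop = FALSE]
  ro <- seq(1L, nr, 2L); re <- seq(2L, nr, 2L)
  co <- seq(1L, nc, 2L); ce <- seq(2L, nc, 2L)
  a <- x[ro, co, drop = FALSE]; b <- x[ro, ce, drop = FALSE]
  cm <- x[re, co, drop = FALSE]; d <- x[re, ce, drop = FALSE]
  bm <- msk[ro, co, drop = FALSE] & msk[ro, ce, drop = FALSE] &
    msk[re, co, drop = FALSE] & msk[re, ce, drop = FALSE]
  list(
    ll = (a + b + cm + d) / 2,
    lh = (cm + d - a - b) / 2,   # low-pass along x, high-pass along y
    hl = (b - a + d - cm) / 2,   # high-pass along x (column differences)
    hh = (a - b - cm + d) / 2,
    mask = bm
  )
}

#' Haar wavelet sub-band energies
#'
#' Computes a 4-scale orthonormal Haar decomposition of the mask bounding
#' box (out-of-mask pixels filled with the in-mask mean) and returns the
#' energy (mean squared coefficient over coefficients whose 2x2 support is
#' in-mask) of the LL, LH, HL and HH sub-bands at each scale: 16 features.
#'
#' @param roiImage numeric matrix.
#' @param mask logical mask; its bounding box must be at least 16 x 16.
#' @param nScales number of dyadic scales (default 4).
#' @return named numeric vector (`haar_en_<band>_s<scale>`).
#' @examples
#' haarFeatures(matrix(rnorm(1024), 32), matrix(TRUE, 32, 32))
#' @export
haarFeatures <- function(roiImage, mask, nScales = 4L) {
  mask <- .checkImageMask(roiImage, mask)
  if (length(dim(roiImage)) == 3L) {
    roiImage <- roiImage[, , 1]; mask <- mask[, , 1]
  }
  bb <- .maskBBox(mask)
  minSide <- 2L^nScales
  if (length(bb$rows) < minSide || length(bb$cols) < minSide)
    stop("mask bounding box must be at least ", minSide, " x ", minSide,
         " for ", nScales, " scales")
  x <- roiImage[bb$rows, bb$cols, drop = FALSE]
  msk <- mask[bb$rows, bb$cols, drop = FALSE]
  x[!msk] <- mean(roiImage[mask])
  out <- numeric(0)
  for (sc in seq_len(nScales)) {
    st <- .haarStep(x, msk)
    bm <- if (any(st$mask)) st$mask else !logical(length(st$mask))
    en <- vapply(.haarBands, function(bd) mean(st[[bd]][bm]^2), numeric(1))
    names(en) <- paste0("haar_en_", .haarBands, "_s", sc)
    out <- c(out, en)
    x <- st$ll
    msk <- st$mask
  }
  out
}

# cache of Gabor transfer functions keyed by pad size and filter parameters
.gaborCache <- new.env(parent = emptyenv())

# complex Gabor kernel FFT on a P1 x P2 grid with wrap-around coordinates;
# envelope sd = s/2, wavelength = s, zero-DC (the Gaussian-weighted carrier
# mean is subtracted)
.gaborTransfer <- function(P1, P2, thetaDeg, s) {
  key <- paste(P1, P2, thetaDeg, s, sep = "_")
  if (!is.null(.gaborCache[[key]])) return(.gaborCache[[key]])
  wrap <- function(P) {
    i <- 0:(P - 1)
    ifelse(i <= P / 2, i, i - P)
  }
  X <- matrix(wrap(P2), P1, P2, byrow = TRUE)   # column offsets
  Y <- matrix(wrap(P1), P1, P2)                 # row offsets
  sig <- s / 2
  g <- exp(-(X^2 + Y^2) / (2 * sig^2))
  th <- thetaDeg * pi / 180
  carrier <- exp(2i * pi * (X * cos(th) + Y * sin(th)) / s)
  beta <- sum(g * carrier) / sum(g)
  k <- g * (carrier - beta)
  tf <- fft(k)
  .gaborCache[[key]] <- tf
  tf
}

#' Gabor filter-bank magnitude features
#'
#' Mean magnitude over in-mask pixels of the complex Gabor response for four
#' wave-vector orientations (0, 45, 90, 135 degrees) and six Gaussian
#' envelope sizes (4, 6, 8, 12, 16, 24 px). The envelope sd is `s/2` and the
#' sinusoid wavelength equals the envelope size `s` (one cycle per
#' envelope). Filters are zero-DC, so a constant ROI gives (numerically)
#' zero responses. Orientation 0 means the sinusoid varies along x
#' (responding to vertical stripes).
#'
#' @param roiImage numeric matrix.
#' @param mask logical mask; the bounding box must be at least as large as
#'   the largest envelope.
#' @param envelopes integer envelope sizes (default `c(4, 6, 8, 12, 16, 24)`).
#' @param orientations in degrees (default `c(0, 45, 90, 135)`).
#' @return named numeric vector (`gabor_mag_<dir>_s<envelope>`, orientation
#'   varying slowest).
#' @examples
#' img <- matrix(sin(2 * pi * col(matrix(0, 32, 32)) / 8), 32)
#' gaborFeatures(img, matrix(TRUE, 32, 32))
#' @export
gaborFeatures <- function(roiImage, mask,
                          envelopes = c(4, 6, 8, 12, 16, 24),
                          orientations = c(0, 45, 90, 135)) {
  mask <- .checkImageMask(roiImage, mask)
  if (length(dim(roiImage)) == 3L) {
    roiImage <- roiImage[, , 1]; mask <- mask[, , 1]
  }
  bb <- .maskBBox(mask)
  nr <- length(bb$rows); nc <- length(bb$cols)
  if (min(nr, nc) < max(envelopes))
    stop("mask bounding box (", nr, " x ", nc,
         ") is smaller than the largest Gabor envelope (", max(envelopes),
         ")")
  sub <- roiImage[bb$rows, bb$cols, drop = FALSE]
  mskbb <- mask[bb$rows, bb$cols, drop = FALSE]
  mu <- mean(roiImage[mask])
  sub[!mskbb] <- mu
  sub <- sub - mu
  pad <- ceiling(1.25 * max(envelopes))
  P1 <- .nextGoodSize(nr + 2L * pad)
  P2 <- .nextGoodSize(nc + 2L * pad)
  padded <- matrix(0, P1, P2)
  padded[seq_len(nr), seq_len(nc)] <- sub
  FI <- fft(padded)
  out <- numeric(0)
  for (th in orientations) {
    for (s in envelopes) {
      tf <- .gaborTransfer(P1, P2, th, s)
      resp <- fft(FI * tf, inverse = TRUE) / (P1 * P2)
      mag <- Mod(resp[seq_len(nr), seq_len(nc)])[mskbb]
      out <- c(out, stats::setNames(mean(mag),
                                    paste0("gabor_mag_", th, "_s", s)))
    }
  }
  out
}
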
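# Gray-level co-occurrence matrices and the 11 classical Haralick statistics.

# 2D direction label -> unit offset (drow, dcol). "0" is horizontal, "90"
# vertical; the GLCM is symmetrized so the offset sign is immaterial.
.dirOffset2D <- function(direction) {
  switch(as.character(direction),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(1L, 0L),
         "135" = c(1L, 1L),
         stop("unknown 2D direction '", direction,
              "' (use 0, 45, 90 or 135)"))
}

# the 13 unique direction classes of the 3D 26-neighbourhood
.offsets3D <- function() {
  o <- list(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0), c(1,0,1),
            c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1), c(1,1,-1), c(1,-1,1),
            c(1,-1,-1))
  names(o) <- vapply(o, paste, character(1), collapse = ".")
  o
}

# shift a 3D array by (dr, dc, ds) filling with NA
.shiftArr3 <- function(a, dr, dc, ds) {
  d <- dim(a)
  out <- array(NA_integer_, d)
  rs <- max(1L, 1L + dr):min(d[1], d[1] + dr)
  cs <- max(1L, 1L + dc):min(d[2], d[2] + dc)
  ss <- max(1L, 1L + ds):min(d[3], d[3] + ds)
  out[rs, cs, ss] <- a[rs - dr, cs - dc, ss - ds]
  out
}

# symmetric normalized co-occurrence counts for one offset; pairs (p, p +
# offset) are gathered by range subsetting (no full-array shift copies)
.glcmCounts <- function(levels, offset, ng) {
  d <- dim(levels)
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(offset) == 2L) offset <- c(offset, 0L)
  lo <- pmax(1L, 1L - offset)
  hi <- pmin(d, d - offset)
  if (any(lo > hi)) return(NULL)
  r1 <- lo[1]:hi[1]; c1 <- lo[2]:hi[2]; s1 <- lo[3]:hi[3]
  if (length(dim(levels)) == 2L) {
    av <- levels[r1, c1]
    bv <- levels[r1 + offset[1], c1 + offset[2]]
  } else {
    av <- levels[r1, c1, s1]
    bv <- levels[r1 + offset[1], c1 + offset[2], s1 + offset[3]]
  }
  ok <- !is.na(av) & !is.na(bv)
  if (!all(ok)) {
    av <- av[ok]; bv <- bv[ok]
  }
  n <- length(av)
  if (n == 0L) return(NULL)
  counts <- tabulate(av * ng + bv + 1L, nbins = ng * ng) +
    tabulate(bv * ng + av + 1L, nbins = ng * ng)
  list(probs = matrix(counts / (2 * n), ng, ng), nPairs = 2L * n)
}

#' Gray-level co-occurrence matrix of a quantized ROI
#'
#' Counts pairs of in-mask gray levels separated by `distance` pixels along
#' `direction`; both pixels of a pair must be in-mask. The matrix is
#' symmetrized (each ordered pair counted both ways) and normalized to
#' probabilities.
#'
#' @param q a [QuantizedROI-class] (2D or 3D).
#' @param direction for 2D, one of `"0"`, `"45"`, `"90"`, `"135"` (degrees);
#'   for 3D, one of the 13 offset labels of the 26-neighbourhood, e.g.
#'   `"1.0.0"` (see [extractAll()]).
#' @param distance integer pixel distance, 1-5 by convention.
#' @return a [CooccurrenceMatrix-class].
#' @examples
#' q <- quantizeROI(matrix(rep(0:1, 8), 4), matrix(TRUE, 4, 4), 2)
#' glcm(q, "0", 1)
#' @export
glcm <- function(q, direction, distance = 1L) {
  stopifnot(is(q, "QuantizedROI"))
  distance <- as.integer(distance)
  if (distance < 1L) stop("distance must be >= 1")
  dl <- as.character(direction)
  if (length(dim(q@levels)) == 2L || dim(q@levels)[3] == 1L) {
    off <- .dirOffset2D(dl) * distance
  } else {
    o3 <- .offsets3D()
    if (!dl %in% names(o3)) stop("unknown 3D direction '", dl, "'")
    off <- o3[[dl]] * distance
  }
  res <- .glcmCounts(q@levels, off, q@nLevels)
  if (is.null(res))
    stop("no valid pixel pairs for direction ", dl, ", distance ", distance)
  new("CooccurrenceMatrix", probs = res$probs, direction = dl,
      distance = distance, nPairs = res$nPairs)
}

# fast internal path used by extractAll(): skips S4 construction/validity
.glcmFeaturesInternal <- function(levels, offset, ng) {
  res <- .glcmCounts(levels, offset, ng)
  if (is.null(res))
    stop("no valid pixel pairs for offset ", paste(offset, collapse = ","))
  .haralick11(res$probs)
}

.glcmStatNames <- c("asm", "contrast", "correlation", "sum_of_squares",
                    "idm", "sum_average", "sum_variance", "sum_entropy",
                    "entropy", "diff_variance", "diff_entropy")

.xlogx <- function(z) {
  z <- z[z > 0]
  sum(z * log(z))
}

# per-Ng constants for the Haralick statistics, cached (the statistics are
# evaluated thousands of times per run on identically sized matrices)
.haralickCache <- new.env(parent = emptyenv())

.haralickConsts <- function(ng) {
  key <- as.character(ng)
  cc <- .haralickCache[[key]]
  if (!is.null(cc)) return(cc)
  i <- as.vector(row(matrix(0, ng, ng)))
  j <- as.vector(col(matrix(0, ng, ng)))
  cc <- list(
    lev = seq_len(ng),
    ij = i * j,
    dsq = (i - j)^2,
    idmw = 1 / (1 + (i - j)^2),
    kp = i + j,                 # 2 .. 2*ng
    km = abs(i - j),            # 0 .. ng - 1
    kv = 2:(2 * ng),
    dv = 0:(ng - 1)
  )
  .haralickCache[[key]] <- cc
  cc
}

# the 11 Haralick statistics of a normalized symmetric GLCM; entropies use
# natural log with 0*log0 = 0; gray levels indexed 1..Ng
.haralick11 <- function(p) {
  ng <- nrow(p)
  cc <- .haralickConsts(ng)
  pv <- as.vector(p)
  px <- .rowSums(p, ng, ng)            # = colSums by symmetry
  mux <- sum(cc$lev * px)
  varx <- sum((cc$lev - mux)^2 * px)
  asm <- sum(pv * pv)
  contrast <- sum(cc$dsq * pv)
  correlation <- if (varx > 0) (sum(cc$ij * pv) - mux^2) / varx else 0
  idm <- sum(cc$idmw * pv)
  pplus <- as.vector(rowsum(pv, cc$kp))            # k = 2 .. 2*ng
  sum_average <- sum(cc$kv * pplus)
  sum_variance <- sum((cc$kv - sum_average)^2 * pplus)
  sum_entropy <- -.xlogx(pplus)
  pminus <- as.vector(rowsum(pv, cc$km))           # k = 0 .. ng - 1
  dmu <- sum(cc$dv * pminus)
  diff_variance <- sum((cc$dv - dmu)^2 * pminus)
  diff_entropy <- -.xlogx(pminus)
  out <- c(asm, contrast, correlation, varx, idm, sum_average, sum_variance,
           sum_entropy, -.xlogx(pv), diff_variance, diff_entropy)
  names(out) <- .glcmStatNames
  out
}

#' Haralick statistics of a co-occurrence matrix
#'
#' Computes the 11 classical second-order statistics: angular second moment,
#' contrast, correlation, sum of squares (variance), inverse difference
#' moment, sum average, sum variance, sum entropy, entropy, difference
#' variance and difference entropy. Entropies use the natural logarithm with
#' `0 * log 0 = 0`; the sum variance is taken around the sum average and the
#' difference variance is the variance of the difference histogram.
#'
#' @param m a [CooccurrenceMatrix-class] (normalized probabilities).
#' @return named numeric vector of length 11.
#' @examples
#' q <- quantizeROI(matrix(rep(0:1, 8), 4), matrix(TRUE, 4, 4), 2)
#' glcmFeatures(glcm(q, "0", 1))["contrast"]
#' @export
glcmFeatures <- function(m) {
  stopifnot(is(m, "CooccurrenceMatrix"))
  if (abs(sum(m@probs) - 1) > 1e-9)
    stop("co-occurrence matrix is not normalized")
  .haralick11(m@probs)
}
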
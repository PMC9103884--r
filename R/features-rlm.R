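# Gray-level run-length analysis. A run is a maximal sequence of equal
# levels along a direction; runs end at the mask boundary.

# Enumerate all maximal in-mask runs along a unit offset through a 2D or 3D
# level array (NA outside the mask). Returns list(gray =, len =).
# Works by sorting voxels by (line identifier, position along line): all
# lattice points of a line are present, so positions are consecutive and a
# single pass over the sorted values finds the run boundaries.
.runLengths <- function(levels, offset) {
  if (length(dim(levels)) == 2L)
    levels <- array(levels, c(dim(levels), 1L))
  if (length(offset) == 2L) offset <- c(offset, 0L)
  d <- dim(levels)
  n <- prod(d)
  r <- rep(seq_len(d[1]), times = d[2] * d[3])
  cc <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  s <- rep(seq_len(d[3]), each = d[1] * d[2])
  # position along the line: the first nonzero offset component has |.| = 1,
  # so coordinate * sign advances by exactly 1 per step along the offset
  t <- if (offset[1] != 0L) r * offset[1] else if (offset[2] != 0L)
    cc * offset[2] else s * offset[3]
  B <- 2 * (sum(d) + 2)
  key <- (r - t * offset[1] + B) +
    (cc - t * offset[2] + B) * (2 * B) +
    (s - t * offset[3] + B) * (2 * B)^2
  ord <- order(key, t)
  v <- as.vector(levels)[ord]
  k <- key[ord]
  vna <- ifelse(is.na(v), -1L, v)
  newRun <- c(TRUE, diff(k) != 0 | diff(vna) != 0)
  runId <- cumsum(newRun)
  lens <- tabulate(runId)
  vals <- vna[newRun]
  keep <- vals >= 0L
  list(gray = vals[keep], len = lens[keep])
}

.rlmStatNames <- c("sre", "lre", "gln", "rln", "rp")

#' Run-length features of a quantized ROI
#'
#' Builds the gray-level run-length matrix for one direction (in-mask runs
#' only; a run ends at the mask boundary) and returns five statistics:
#' short-run emphasis, long-run emphasis, gray-level nonuniformity,
#' run-length nonuniformity and the fraction of the ROI in runs (number of
#' runs divided by in-mask pixels).
#'
#' @param q a [QuantizedROI-class] (2D or 3D).
#' @param direction as in [glcm()].
#' @return named numeric vector of length 5.
#' @examples
#' q <- quantizeROI(matrix(rep(0:1, each = 8), 4), matrix(TRUE, 4, 4), 2)
#' rlmFeatures(q, "0")
#' @export
rlmFeatures <- function(q, direction) {
  stopifnot(is(q, "QuantizedROI"))
  if (!any(q@mask)) stop("empty ROI")
  dl <- as.character(direction)
  if (length(dim(q@levels)) == 2L || dim(q@levels)[3] == 1L) {
    off <- .dirOffset2D(dl)
  } else {
    o3 <- .offsets3D()
    if (!dl %in% names(o3)) stop("unknown 3D direction '", dl, "'")
    off <- o3[[dl]]
  }
  runs <- .runLengths(q@levels, off)
  nr <- length(runs$len)
  np <- sum(!is.na(q@levels))
  out <- c(
    sre = sum(1 / runs$len^2) / nr,
    lre = sum(runs$len^2) / nr,
    gln = sum(tabulate(runs$gray + 1L, q@nLevels)^2) / nr,
    rln = sum(tabulate(runs$len)^2) / nr,
    rp  = nr / np
  )
  out
}
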
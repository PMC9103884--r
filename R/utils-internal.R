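# Internal helpers shared across modules. None of these are exported.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded helpers stay pure functions of their arguments.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# round-half-up (base round() is round-half-even)
.roundHalfUp <- function(x) floor(x + 0.5)

# centred FFT quadrant swap for even-sized square matrices
.fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  h1 <- n1 %/% 2L; h2 <- n2 %/% 2L
  m[c((h1 + 1L):n1, 1L:h1), c((h2 + 1L):n2, 1L:h2)]
}

.ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  h1 <- n1 %/% 2L; h2 <- n2 %/% 2L
  m[c((n1 - h1 + 1L):n1, 1L:(n1 - h1)), c((n2 - h2 + 1L):n2, 1L:(n2 - h2))]
}

# smallest integer >= n whose prime factors are all in {2,3,5}; keeps
# mixed-radix FFTs fast for padded convolution sizes
.nextGoodSize <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# shift a matrix by (dr, dc), filling vacated cells with `fill`
.shiftMat <- function(m, dr, dc, fill = NA) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(fill, n1, n2)
  rs <- max(1L, 1L + dr):min(n1, n1 + dr)
  cs <- max(1L, 1L + dc):min(n2, n2 + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# population central moments -> c(mean, variance, skewness, excess kurtosis)
.momentStats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  d <- x - mu
  m2 <- sum(d^2) / n
  if (m2 <= 0) return(c(mean = mu, variance = 0, skewness = 0, kurtosis = 0))
  m3 <- sum(d^3) / n
  m4 <- sum(d^4) / n
  c(mean = mu, variance = m2, skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# erode a logical mask so a 3x3 neighbourhood around every retained pixel is
# fully in-mask and inside image bounds
.erodeMask3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out & .shiftMat(mask, dr, dc, fill = FALSE)
  }
  out[c(1L, nrow(out)), ] <- FALSE
  out[, c(1L, ncol(out))] <- FALSE
  out
}

# 3D analogue over the 26-neighbourhood
.erodeMask3d <- function(mask) {
  d <- dim(mask)
  out <- mask
  idx <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
  for (k in seq_len(nrow(idx))) {
    dr <- idx$dr[k]; dc <- idx$dc[k]; ds <- idx$ds[k]
    if (dr == 0L && dc == 0L && ds == 0L) next
    sh <- array(FALSE, d)
    rs <- max(1L, 1L + dr):min(d[1], d[1] + dr)
    cs <- max(1L, 1L + dc):min(d[2], d[2] + dc)
    ss <- max(1L, 1L + ds):min(d[3], d[3] + ds)
    sh[rs, cs, ss] <- mask[rs - dr, cs - dc, ss - ds]
    out <- out & sh
  }
  out[c(1L, d[1]), , ] <- FALSE
  out[, c(1L, d[2]), ] <- FALSE
  out[, , c(1L, d[3])] <- FALSE
  out
}

# bounding box of a logical mask as list(rows =, cols =)
.maskBBox <- function(mask) {
  stopifnot(any(mask))
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  list(rows = rr[1]:rr[2], cols = cc[1]:cc[2])
}

# Sobel gradient (normalized so a unit ramp gives magnitude 1) on a matrix;
# returns list(gx, gy) with gy along rows (increasing row index) and gx along
# columns. Border values are meaningless; callers mask them via erosion.
.sobelGradient <- function(img) {
  sm <- function(m, dr, dc) .shiftMat(m, dr, dc, fill = 0)
  # derivative [-1 0 1]/2 (x) smoothing [1 2 1]/4; note sm(dr, dc) holds
  # img[r - dr, c - dc], so sm(., -1) carries the c + 1 column
  gx <- (sm(img, -1, -1) + 2 * sm(img, 0, -1) + sm(img, 1, -1) -
         sm(img, -1,  1) - 2 * sm(img, 0,  1) - sm(img, 1,  1)) / 8
  gy <- (sm(img, -1, -1) + 2 * sm(img, -1, 0) + sm(img, -1, 1) -
         sm(img,  1, -1) - 2 * sm(img,  1, 0) - sm(img,  1, 1)) / 8
  list(gx = gx, gy = gy)
}

.checkImageMask <- function(image, mask) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!identical(dim(image), dim(mask)))
    stop("image and mask dimensions differ: ",
         paste(dim(image), collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"))
  if (!any(mask)) stop("mask is empty")
  mask
}
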
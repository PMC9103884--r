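# Independent brute-force oracles. These deliberately use naive loops and
# direct definitions, not the package's vectorized implementations.

# random small ROI: image, random blob-ish mask, quantized levels
randomROI <- function(seed, minSide = 8, maxSide = 16, ng = 8) {
  set.seed(seed)
  n1 <- sample(minSide:maxSide, 1)
  n2 <- sample(minSide:maxSide, 1)
  img <- matrix(rnorm(n1 * n2, 100, 20), n1, n2)
  mask <- matrix(runif(n1 * n2) < 0.85, n1, n2)
  # guarantee enough pixels
  if (sum(mask) < 10) mask[] <- TRUE
  list(img = img, mask = mask, ng = ng)
}

# gray levels by the package's documented minmax formula, via a per-pixel loop
oracleQuantize <- function(img, mask, ng) {
  v <- img[mask]
  lo <- min(v); hi <- max(v)
  lev <- matrix(NA_integer_, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    if (mask[r, c])
      lev[r, c] <- as.integer(floor(ng * (img[r, c] - lo) /
                                      ((hi - lo) * (1 + 1e-9))))
  }
  lev
}

# symmetric normalized GLCM by enumerating every in-mask ordered pixel pair
oracleGLCM <- function(lev, dr, dc, ng) {
  counts <- matrix(0, ng, ng)
  n1 <- nrow(lev); n2 <- ncol(lev)
  for (r in seq_len(n1)) for (c in seq_len(n2)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= n1 && c2 >= 1 && c2 <= n2 &&
        !is.na(lev[r, c]) && !is.na(lev[r2, c2])) {
      a <- lev[r, c] + 1L; b <- lev[r2, c2] + 1L
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

# all maximal in-mask runs along (dr, dc) by walking each line
oracleRuns <- function(lev, dr, dc) {
  n1 <- nrow(lev); n2 <- ncol(lev)
  gray <- integer(0); len <- integer(0)
  inb <- function(r, c) r >= 1 && r <= n1 && c >= 1 && c <= n2
  for (r in seq_len(n1)) for (c in seq_len(n2)) {
    if (is.na(lev[r, c])) next
    # start of a run iff the predecessor is absent or different
    pr <- r - dr; pc <- c - dc
    if (inb(pr, pc) && !is.na(lev[pr, pc]) && lev[pr, pc] == lev[r, c]) next
    l <- 1L
    nr <- r + dr; nc <- c + dc
    while (inb(nr, nc) && !is.na(lev[nr, nc]) && lev[nr, nc] == lev[r, c]) {
      l <- l + 1L
      nr <- nr + dr; nc <- nc + dc
    }
    gray <- c(gray, lev[r, c]); len <- c(len, l)
  }
  list(gray = gray, len = len)
}

oracleRLMFeatures <- function(lev, dr, dc, ng) {
  runs <- oracleRuns(lev, dr, dc)
  nr <- length(runs$len)
  np <- sum(!is.na(lev))
  c(sre = sum(1 / runs$len^2) / nr,
    lre = sum(runs$len^2) / nr,
    gln = sum(tabulate(runs$gray + 1L, ng)^2) / nr,
    rln = sum(tabulate(runs$len)^2) / nr,
    rp = nr / np)
}

# direct 3x3 Sobel response at one pixel (normalized: unit ramp -> 1)
oracleSobelXY <- function(img, r, c) {
  gx <- (img[r - 1, c + 1] + 2 * img[r, c + 1] + img[r + 1, c + 1] -
         img[r - 1, c - 1] - 2 * img[r, c - 1] - img[r + 1, c - 1]) / 8
  gy <- (img[r + 1, c - 1] + 2 * img[r + 1, c] + img[r + 1, c + 1] -
         img[r - 1, c - 1] - 2 * img[r - 1, c] - img[r - 1, c + 1]) / 8
  c(gx = gx, gy = gy)
}

# pixels whose full 3x3 neighbourhood is in-mask and off the image border
oracleErode <- function(mask) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in 2:(nrow(mask) - 1)) for (c in 2:(ncol(mask) - 1)) {
    out[r, c] <- all(mask[(r - 1):(r + 1), (c - 1):(c + 1)])
  }
  out
}

# population moments by direct summation
oracleMoments <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  c(mean = mu, variance = m2,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0)
}

# nearest-rank percentile
oraclePercentile <- function(v, q) sort(v)[max(1, ceiling(q * length(v)))]

# one orthonormal Haar analysis level by looping over 2x2 blocks
oracleHaarStep <- function(x) {
  nr <- (nrow(x) %/% 2) * 2; nc <- (ncol(x) %/% 2) * 2
  ll <- lh <- hl <- hh <- matrix(0, nr / 2, nc / 2)
  for (i in seq_len(nr / 2)) for (j in seq_len(nc / 2)) {
    a <- x[2 * i - 1, 2 * j - 1]; b <- x[2 * i - 1, 2 * j]
    cm <- x[2 * i, 2 * j - 1]; d <- x[2 * i, 2 * j]
    ll[i, j] <- (a + b + cm + d) / 2
    lh[i, j] <- (cm + d - a - b) / 2
    hl[i, j] <- (b - a + d - cm) / 2
    hh[i, j] <- (a - b - cm + d) / 2
  }
  list(ll = ll, lh = lh, hl = hl, hh = hh)
}

# Lin's concordance by direct population-moment summation
oracleCCC <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  2 * cxy / (vx + vy + (mx - my)^2)
}

# simulate a causal AR texture with known weights on a margin-padded grid
simulateARTexture <- function(theta, n, sigma, seed) {
  set.seed(seed)
  pad <- 4L
  N <- n + 2 * pad
  img <- matrix(rnorm(N * N, 0, sigma), N, N)
  for (r in 2:N) {
    for (c in 2:(N - 1)) {
      img[r, c] <- theta[1] * img[r, c - 1] + theta[2] * img[r - 1, c - 1] +
        theta[3] * img[r - 1, c] + theta[4] * img[r - 1, c + 1] +
        rnorm(1, 0, sigma)
    }
  }
  img[(pad + 1):(pad + n), (pad + 1):(pad + n)]
}

relErr <- function(a, b) {
  d <- abs(a - b)
  s <- pmax(abs(a), abs(b))
  ifelse(s > 0, d / pmax(s, 1), d)
}
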
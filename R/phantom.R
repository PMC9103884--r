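# Synthetic tissue phantom and k-space truncation acquisition simulator.

.tissueClassDefaults <- function(tissueClass) {
  # Granule scales are set by the anatomy at the 512-matrix pixel spacing of
  # 0.39 mm/px: trabeculae ~0.5-1 mm (fine, partly beyond the 256-matrix
  # Nyquist), fat lobules ~3 mm, muscle fascicle striping ~6 mm period with
  # low T2 contrast.
  switch(tissueClass,
    bone   = list(granuleScalePx = 1.5, directionality = 0,
                  contrast = 60, baseIntensity = 160),
    fat    = list(granuleScalePx = 4,   directionality = 0,
                  contrast = 45, baseIntensity = 200),
    muscle = list(granuleScalePx = 8,   directionality = 0.8,
                  contrast = 12, baseIntensity = 110),
    stop("unknown tissue class: '", tissueClass, "'")
  )
}

#' Default tissue texture configurations
#'
#' Returns the three default tissue configurations (bone, fat, muscle) used
#' by [buildPhantomSeries()]. Bone is a fine binarized trabecular pattern,
#' fat a blobby lobular pattern with saturated edges, and muscle a smooth
#' low-contrast directional stripe pattern, so the three classes span the
#' texture-complexity range from highly structured to smooth.
#'
#' @param seed integer seed stored in each configuration.
#' @return named list of [TissuePhantomConfig-class] objects.
#' @examples
#' names(tissueDefaults())
#' @export
tissueDefaults <- function(seed = 0L) {
  classes <- c("bone", "fat", "muscle")
  out <- lapply(classes, TissuePhantomConfig, seed = seed)
  names(out) <- classes
  out
}

# frequency magnitude grid (cycles/pixel) for an n x n FFT
.freqGrid <- function(n) {
  f <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1)) / n
  list(fx = matrix(f, n, n, byrow = TRUE), fy = matrix(f, n, n))
}

# filter white noise in the Fourier domain with transfer H (n x n)
.filteredNoise <- function(n, H) {
  w <- matrix(rnorm(n * n), n, n)
  Re(fft(fft(w) * H, inverse = TRUE)) / (n * n)
}

#' Generate one synthetic tissue texture
#'
#' Renders a `size x size` real-valued texture for the configured tissue
#' class, deterministically from `config@seed`. Bone is band-pass noise
#' binarized at its median (trabecular micro-texture of amplitude
#' `contrast`); fat is low-pass blob noise passed through a saturating
#' `tanh` nonlinearity (lobules with edges); muscle blends an isotropic
#' low-pass field with a directional band (stripes), at low contrast.
#'
#' @param config a [TissuePhantomConfig-class].
#' @param size integer image side, >= 32.
#' @return a `size x size` numeric matrix of intensities
#'   (`baseIntensity + contrast * pattern`).
#' @examples
#' img <- generateTissueTexture(TissuePhantomConfig("bone", seed = 1), 64)
#' dim(img)
#' @export
generateTissueTexture <- function(config, size) {
  stopifnot(is(config, "TissuePhantomConfig"))
  validObject(config)
  size <- as.integer(size)
  if (size < 32L) stop("size must be >= 32")
  cls <- config@tissueClass
  .tissueClassDefaults(cls)  # errors on unknown class
  g <- config@granuleScalePx
  f0 <- 1 / (2 * g)  # characteristic frequency, cycles/px
  .withSeed(config@seed, {
    fr <- .freqGrid(size)
    fmag <- sqrt(fr$fx^2 + fr$fy^2)
    pattern <- switch(cls,
      bone = {
        H <- exp(-((fmag - f0)^2) / (2 * (f0 / 2)^2))
        field <- .filteredNoise(size, H)
        ifelse(field > median(field), 1, -1)
      },
      fat = {
        H <- exp(-(fmag / f0)^2 / 2)
        field <- .filteredNoise(size, H)
        s <- sd(field)
        if (s == 0) field else tanh(2 * field / s) / 0.9
      },
      muscle = {
        d <- config@directionality
        Hiso <- exp(-(fmag / f0)^2 / 2)
        # horizontal stripes: band along fy, narrow in fx
        Hdir <- exp(-((abs(fr$fy) - f0)^2) / (2 * (f0 / 2)^2)) *
          exp(-(fr$fx^2) / (2 * (f0 / 4)^2))
        field <- .filteredNoise(size, (1 - d) * Hiso + d * Hdir)
        s <- sd(field)
        if (s == 0) field else field / s
      })
    config@baseIntensity + config@contrast * pattern
  })
}

#' Simulate acquisition at a smaller matrix by k-space truncation
#'
#' Emulates acquiring the same field of view with a smaller acquisition
#' matrix: the 2D Fourier transform of the reference image is cropped to the
#' central `matrixSize x matrixSize` block (the k-space periphery carrying
#' fine spatial detail is discarded), inverse transformed, and Gaussian
#' noise with standard deviation `noiseScale * (matrixSize /
#' referenceMatrix)^2` is added (noise relative to signal grows with matrix
#' size because smaller voxels collect less signal). When the matrix is
#' strictly smaller than the reference, the unpaired Nyquist row/column of
#' the cropped spectrum is zeroed so the retained spectrum stays Hermitian
#' and the output is exactly real. No zero-filling
#' interpolation is performed: the output grid is `matrixSize` pixels.
#'
#' Two inverse-transform scalings are available. `"intensity"` (default)
#' preserves the image mean, so tissue intensities are comparable across
#' matrix sizes; `"unitary"` uses the orthonormal FFT convention, under
#' which the sum of squared output intensities equals the sum of squared
#' retained Fourier coefficients (Parseval).
#'
#' @param referenceImage square numeric matrix of side
#'   `referenceMatrix(spec)`.
#' @param spec an [AcquisitionSpec-class]; `matrixSize(spec)` must not
#'   exceed the reference matrix.
#' @param seed integer seed for the additive noise.
#' @param scaling `"intensity"` or `"unitary"`.
#' @return `matrixSize x matrixSize` numeric matrix.
#' @examples
#' ref <- generateTissueTexture(TissuePhantomConfig("fat", seed = 1), 64)
#' low <- simulateAcquisition(ref, AcquisitionSpec(32, referenceMatrix = 64))
#' dim(low)
#' @export
simulateAcquisition <- function(referenceImage, spec, seed = 0L,
                                scaling = c("intensity", "unitary")) {
  scaling <- match.arg(scaling)
  stopifnot(is(spec, "AcquisitionSpec"))
  validObject(spec)
  R <- spec@referenceMatrix
  m <- spec@matrixSize
  if (!is.matrix(referenceImage) || nrow(referenceImage) != R ||
      ncol(referenceImage) != R)
    stop("referenceImage must be ", R, " x ", R)
  if (m > R) stop("matrixSize ", m, " exceeds reference matrix ", R,
                  " (upsampling unsupported)")
  if (m %% 2L != 0L) stop("odd matrix sizes are not supported")
  FF <- .fftshift2(fft(referenceImage))
  ctr <- R %/% 2L + 1L
  keep <- (ctr - m %/% 2L):(ctr + m %/% 2L - 1L)
  Gs <- FF[keep, keep]
  if (m < R) {
    # the -m/2 Nyquist row/column has no +m/2 conjugate partner inside the
    # crop; zeroing it keeps the retained spectrum Hermitian, so the output
    # is exactly real and the retained energy is exactly preserved
    Gs[1, ] <- 0
    Gs[, 1] <- 0
  }
  G <- .ifftshift2(Gs)
  out <- Re(fft(G, inverse = TRUE)) /
    switch(scaling, intensity = as.numeric(R)^2, unitary = as.numeric(R) * m)
  if (spec@noiseScale > 0) {
    sdn <- spec@noiseScale * (m / R)^2
    out <- out + .withSeed(seed, matrix(rnorm(m * m, 0, sdn), m, m))
  }
  out
}

# region layout: non-overlapping axis-aligned rectangles in reference
# coordinates, as fractions of the reference side (up to 3 tissues)
.regionLayout <- function(R, nTissues) {
  if (nTissues > 3L) stop("the built-in layout supports at most 3 tissues")
  rects <- list(
    list(rows = c(1 / 16, 3 / 8), cols = c(1 / 16, 3 / 8)),
    list(rows = c(1 / 16, 3 / 8), cols = c(5 / 8, 15 / 16)),
    list(rows = c(5 / 8, 15 / 16), cols = c(1 / 16, 3 / 8))
  )[seq_len(nTissues)]
  lapply(rects, function(r) {
    list(rows = (round(r$rows[1] * R) + 1L):round(r$rows[2] * R),
         cols = (round(r$cols[1] * R) + 1L):round(r$cols[2] * R))
  })
}

.checkRegionsDisjoint <- function(regions, R) {
  occ <- matrix(FALSE, R, R)
  for (rg in regions) {
    if (any(occ[rg$rows, rg$cols])) stop("overlapping tissue regions")
    occ[rg$rows, rg$cols] <- TRUE
  }
  invisible(TRUE)
}

#' Build a paired multi-subject phantom series
#'
#' Generates `nSubjects` synthetic subjects. Each subject gets
#' subject-specific texture parameters (uniform `+/- jitter` on granule
#' scale, contrast and base intensity, so between-subject feature variance
#' exists), `nSlices` reference slices at the reference matrix with the
#' tissue textures composited into non-overlapping rectangular regions, and
#' a simulated acquisition of every requested matrix size from each
#' reference slice (paired within-subject design). ROI masks are rectangles
#' inset from the tissue-region borders (`insetPx` pixels at the reference,
#' scaled per matrix), keeping Gibbs ringing from region edges out of the
#' ROI.
#'
#' @param nSubjects integer >= 2 (default 20).
#' @param matrixSizes integer vector (default `c(256, 320, 384, 448, 512)`).
#' @param tissueConfigs list of [TissuePhantomConfig-class] (default
#'   [tissueDefaults()]).
#' @param masterSeed integer; the whole series is reproducible from it.
#' @param nSlices slices per subject (default 5).
#' @param noiseScale Gaussian noise sd at the reference matrix (default 8).
#' @param fovMM field of view in mm (default 200).
#' @param referenceMatrix reference matrix size (default 512).
#' @param jitter relative subject-to-subject parameter jitter (default 0.1).
#' @param insetPx ROI inset from region borders at the reference (default 8).
#' @param backgroundIntensity intensity outside tissue regions (default 40).
#' @return a [PhantomSeries-class].
#' @examples
#' ps <- buildPhantomSeries(2, c(64, 128), masterSeed = 1, nSlices = 1,
#'                          referenceMatrix = 128)
#' ps
#' @export
buildPhantomSeries <- function(nSubjects = 20L,
                               matrixSizes = c(256L, 320L, 384L, 448L, 512L),
                               tissueConfigs = tissueDefaults(),
                               masterSeed = 1L, nSlices = 5L, noiseScale = 8,
                               fovMM = 200, referenceMatrix = 512L,
                               jitter = 0.1, insetPx = 8L,
                               backgroundIntensity = 40) {
  nSubjects <- as.integer(nSubjects)
  if (nSubjects < 2L) stop("nSubjects must be >= 2")
  matrixSizes <- sort(as.integer(matrixSizes))
  if (!length(matrixSizes)) stop("matrixSizes must be non-empty")
  if (!length(tissueConfigs)) stop("tissueConfigs must be non-empty")
  R <- as.integer(referenceMatrix)
  if (max(matrixSizes) > R) stop("matrix sizes must not exceed the reference")
  tissues <- vapply(tissueConfigs, function(cf) cf@tissueClass, character(1))
  names(tissueConfigs) <- tissues
  regions <- .regionLayout(R, length(tissues))
  names(regions) <- tissues
  .checkRegionsDisjoint(regions, R)

  # all sub-seeds and jitters are drawn up-front from the master seed
  draws <- .withSeed(masterSeed, {
    list(
      jit = array(runif(nSubjects * length(tissues) * 3, 1 - jitter, 1 + jitter),
                  dim = c(nSubjects, length(tissues), 3)),
      texSeed = array(sample.int(.Machine$integer.max - 1L,
                                 nSubjects * nSlices * length(tissues)),
                      dim = c(nSubjects, nSlices, length(tissues))),
      noiseSeed = array(sample.int(.Machine$integer.max - 1L,
                                   nSubjects * nSlices * length(matrixSizes)),
                        dim = c(nSubjects, nSlices, length(matrixSizes)))
    )
  })

  subjectIds <- sprintf("S%02d", seq_len(nSubjects))
  specs <- lapply(matrixSizes, function(m)
    AcquisitionSpec(m, fovMM = fovMM, noiseScale = noiseScale,
                    referenceMatrix = R))
  names(specs) <- as.character(matrixSizes)

  images <- vector("list", nSubjects)
  for (s in seq_len(nSubjects)) {
    stacks <- lapply(matrixSizes, function(m)
      array(0, dim = c(m, m, nSlices)))
    names(stacks) <- as.character(matrixSizes)
    for (sl in seq_len(nSlices)) {
      ref <- matrix(backgroundIntensity, R, R)
      for (t in seq_along(tissues)) {
        cf <- tissueConfigs[[t]]
        jcf <- new("TissuePhantomConfig", tissueClass = cf@tissueClass,
                   granuleScalePx = cf@granuleScalePx * draws$jit[s, t, 1],
                   directionality = cf@directionality,
                   contrast = cf@contrast * draws$jit[s, t, 2],
                   baseIntensity = cf@baseIntensity * draws$jit[s, t, 3],
                   seed = draws$texSeed[s, sl, t])
        rg <- regions[[t]]
        tex <- generateTissueTexture(jcf, length(rg$rows))
        ref[rg$rows, rg$cols] <- tex[, seq_along(rg$cols)]
      }
      for (mi in seq_along(matrixSizes)) {
        m <- matrixSizes[mi]
        stacks[[as.character(m)]][, , sl] <-
          simulateAcquisition(ref, specs[[as.character(m)]],
                              seed = draws$noiseSeed[s, sl, mi])
      }
    }
    images[[s]] <- stacks
  }

  masks <- lapply(matrixSizes, function(m) {
    out <- lapply(seq_along(tissues), function(t) {
      rg <- regions[[t]]
      r0 <- range(rg$rows) + c(insetPx, -insetPx)
      c0 <- range(rg$cols) + c(insetPx, -insetPx)
      rows <- max(1L, round(r0[1] * m / R)):min(m, round(r0[2] * m / R))
      cols <- max(1L, round(c0[1] * m / R)):min(m, round(c0[2] * m / R))
      mk <- matrix(FALSE, m, m)
      mk[rows, cols] <- TRUE
      mk
    })
    names(out) <- tissues
    out
  })
  names(masks) <- as.character(matrixSizes)

  new("PhantomSeries", images = images, masks = masks,
      matrixSizes = matrixSizes, nSlices = as.integer(nSlices),
      tissues = tissues, subjectIds = subjectIds,
      provenance = list(masterSeed = masterSeed, jitter = jitter,
                        noiseScale = noiseScale, fovMM = fovMM,
                        referenceMatrix = R, insetPx = insetPx,
                        tissueConfigs = tissueConfigs, draws = draws))
}
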
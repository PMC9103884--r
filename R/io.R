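# Image/mask I/O (16-bit grayscale TIFF images, 8-bit PNG masks) and series
# round-tripping via a JSON manifest.

#' Read / write 16-bit grayscale images
#'
#' `writeImage16()` stores integer intensities in `[0, 2^bitDepth - 1]`
#' losslessly as single-channel TIFF; `readImage16()` returns them on the
#' same integer scale.
#'
#' @param image numeric matrix of integers in `[0, 2^bitDepth - 1]`.
#' @param path file path.
#' @param bitDepth 8 or 16 (default 16).
#' @return `readImage16()` returns a numeric matrix of stored intensities.
#' @export
writeImage16 <- function(image, path, bitDepth = 16L) {
  mx <- 2^bitDepth - 1
  if (min(image) < 0 || max(image) > mx)
    stop("intensities must lie in [0, ", mx, "] for ", bitDepth,
         "-bit storage")
  tiff::writeTIFF(image / mx, path, bits.per.sample = as.integer(bitDepth))
  invisible(path)
}

#' @rdname writeImage16
#' @export
readImage16 <- function(path, bitDepth = 16L) {
  if (!file.exists(path)) stop("missing image file: ", path)
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  round(x * (2^bitDepth - 1))
}

#' Write a phantom series as PNG images plus a JSON manifest
#'
#' Persists every image as 16-bit grayscale TIFF (intensities affinely
#' mapped to the 16-bit range; the mapping is recorded in the manifest),
#' masks as
#' 0/255 8-bit PNG, and a JSON manifest mapping subject/matrix/slice/tissue
#' to file paths. [readImageStack()] reconstructs the series from the
#' manifest.
#'
#' @param series a [PhantomSeries-class].
#' @param dir output directory.
#' @return path of the manifest, invisibly.
#' @export
writePhantomSeries <- function(series, dir) {
  stopifnot(is(series, "PhantomSeries"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng <- range(unlist(lapply(series@images, function(st)
    lapply(st, range))))
  offset <- rng[1]
  scale <- max((rng[2] - rng[1]) / 65535, .Machine$double.eps)
  subjects <- list()
  for (s in seq_len(nSubjects(series))) {
    sid <- series@subjectIds[s]
    stacks <- list()
    for (m in as.character(series@matrixSizes)) {
      files <- character(series@nSlices)
      for (sl in seq_len(series@nSlices)) {
        f <- sprintf("%s_m%s_sl%02d.tif", sid, m, sl)
        writeImage16(round((series@images[[s]][[m]][, , sl] - offset) / scale),
                      file.path(dir, f))
        files[sl] <- f
      }
      stacks[[m]] <- files
    }
    subjects[[s]] <- list(id = sid, stacks = stacks)
  }
  masks <- list()
  for (m in as.character(series@matrixSizes)) {
    masks[[m]] <- list()
    for (tis in series@tissues) {
      f <- sprintf("mask_m%s_%s.png", m, tis)
      png::writePNG(phantomMask(series, m, tis) * 1.0, file.path(dir, f))
      masks[[m]][[tis]] <- f
    }
  }
  manifest <- list(
    fovMM = series@provenance$fovMM %||% 200,
    nSlices = series@nSlices,
    matrixSizes = series@matrixSizes,
    tissues = as.list(series@tissues),
    bitDepth = 16L,
    intensityOffset = offset,
    intensityScale = scale,
    subjects = subjects,
    masks = masks)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read an image series from a JSON manifest
#'
#' Loads per-subject image stacks at several matrix sizes plus per-tissue ROI
#' masks, as written by [writePhantomSeries()] (real acquisitions exported
#' to the same layout are read identically). Intensities are mapped back
#' through the manifest's affine intensity scaling; masks are binarized at
#' > 0. Subjects missing any matrix size are dropped with a warning (the
#' paired design requires complete coverage).
#'
#' @param manifest path to `manifest.json`.
#' @return a [PhantomSeries-class].
#' @export
readImageStack <- function(manifest) {
  if (!file.exists(manifest)) stop("missing manifest: ", manifest)
  mf <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  dir <- dirname(manifest)
  sizes <- sort(as.integer(unlist(mf$matrixSizes)))
  key <- as.character(sizes)
  tissues <- as.character(unlist(mf$tissues))
  offset <- as.numeric(mf$intensityOffset %||% 0)
  scale <- as.numeric(mf$intensityScale %||% 1)
  bitDepth <- as.integer(mf$bitDepth %||% 16)
  nSlices <- as.integer(mf$nSlices)
  images <- list(); ids <- character(0)
  for (sub in mf$subjects) {
    have <- names(sub$stacks)
    if (!all(key %in% have)) {
      warning("subject ", sub$id, " lacks matrix sizes ",
              paste(setdiff(key, have), collapse = ", "), "; dropped")
      next
    }
    stacks <- list()
    for (m in key) {
      mm <- as.integer(m)
      files <- unlist(sub$stacks[[m]])
      stk <- array(0, c(mm, mm, nSlices))
      for (sl in seq_len(nSlices)) {
        img <- readImage16(file.path(dir, files[sl]), bitDepth)
        stk[, , sl] <- img * scale + offset
      }
      stacks[[m]] <- stk
    }
    images[[length(images) + 1L]] <- stacks
    ids <- c(ids, as.character(sub$id))
  }
  if (length(images) < 2L)
    stop("fewer than 2 complete subjects in the manifest")
  masks <- list()
  for (m in key) {
    masks[[m]] <- list()
    for (tis in tissues) {
      f <- file.path(dir, mf$masks[[m]][[tis]])
      if (!file.exists(f)) stop("missing mask file: ", f)
      x <- png::readPNG(f)
      if (length(dim(x)) == 3L) x <- x[, , 1]
      masks[[m]][[tis]] <- x > 0
    }
  }
  new("PhantomSeries", images = images, masks = masks, matrixSizes = sizes,
      nSlices = nSlices, tissues = tissues, subjectIds = ids,
      provenance = list(manifest = manifest, fovMM = as.numeric(mf$fovMM)))
}
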
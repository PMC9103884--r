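# End-to-end orchestration: phantom -> feature tables -> concordance and
# quality reports, plus CSV/JSON export and PNG round-trip I/O.

#' Construct a TextureFeatureSet
#'
#' @param values subjects-by-features numeric matrix with dimnames.
#' @param matrixSize integer acquisition matrix.
#' @param tissue tissue label.
#' @param mode `"2D"` or `"3D"`.
#' @param normalization `"raw"` or `"pm3sigma"`.
#' @param families feature family per column; defaults to the registry for
#'   `mode`.
#' @return a [TextureFeatureSet] object.
#' @rdname TextureFeatureSet
#' @export
TextureFeatureSet <- function(values, matrixSize, tissue, mode = "2D",
                              normalization = "raw", families = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(families)) {
    reg <- featureRegistry(mode)
    stopifnot(identical(colnames(values), reg$name))
    families <- reg$family
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(values)),
    rowData = S4Vectors::DataFrame(family = families),
    metadata = list(matrixSize = as.integer(matrixSize), tissue = tissue,
                    mode = mode, normalization = normalization))
  new("TextureFeatureSet", se)
}

#' Pipeline run configuration
#'
#' Validated configuration for [runPipeline()]. The defaults reproduce the
#' package's reference study conditions: 20 subjects, matrix sizes 256-512
#' at a 200 mm field of view, three tissues, five slices, 2D analysis, both
#' raw and normalized ROIs, 64 gray levels.
#'
#' @param inputMode `"synthetic"` or `"real"`.
#' @param nSubjects number of synthetic subjects.
#' @param matrixSizes integer vector.
#' @param modes subset of `c("2D", "3D")`.
#' @param normalizations subset of `c("raw", "pm3sigma")`.
#' @param nLevels gray levels for quantization.
#' @param masterSeed integer master seed.
#' @param nSlices slices per subject.
#' @param noiseScale phantom noise sd at the reference matrix.
#' @param fovMM field of view (mm).
#' @param referenceMatrix phantom reference matrix.
#' @param manifest for `"real"` mode, path to a JSON manifest (see
#'   [readImageStack()]).
#' @param outDir optional output directory for CSV/JSON artifacts.
#' @return a validated list of class `RunConfig`.
#' @export
runConfig <- function(inputMode = c("synthetic", "real"), nSubjects = 20L,
                      matrixSizes = c(256L, 320L, 384L, 448L, 512L),
                      modes = "2D", normalizations = c("raw", "pm3sigma"),
                      nLevels = 64L, masterSeed = 1L, nSlices = 5L,
                      noiseScale = 8, fovMM = 200, referenceMatrix = 512L,
                      manifest = NULL, outDir = NULL) {
  inputMode <- match.arg(inputMode)
  stopifnot(all(modes %in% c("2D", "3D")),
            all(normalizations %in% c("raw", "pm3sigma")),
            length(matrixSizes) >= 2L, nLevels >= 2L)
  if (inputMode == "real" && is.null(manifest))
    stop("real input mode requires a manifest")
  cfg <- list(inputMode = inputMode, nSubjects = as.integer(nSubjects),
              matrixSizes = sort(as.integer(matrixSizes)), modes = modes,
              normalizations = normalizations, nLevels = as.integer(nLevels),
              masterSeed = as.integer(masterSeed), nSlices = as.integer(nSlices),
              noiseScale = noiseScale, fovMM = fovMM,
              referenceMatrix = as.integer(referenceMatrix),
              manifest = manifest, outDir = outDir)
  class(cfg) <- "RunConfig"
  cfg
}

# per-subject feature vector for one (tissue, matrix, mode, normalization):
# slice features averaged in 2D mode, one volume extraction in 3D mode
.subjectFeatures <- function(stack, mask, mode, normalization, nLevels) {
  nSlices <- dim(stack)[3]
  if (mode == "3D") {
    vol <- stack
    mask3 <- array(mask, dim = dim(vol))
    if (normalization == "pm3sigma") vol <- normalizeROI(vol, mask3)
    extractAll(vol, mask3, mode = "3D", nLevels = nLevels)
  } else {
    vecs <- lapply(seq_len(nSlices), function(sl) {
      img <- stack[, , sl]
      if (normalization == "pm3sigma") img <- normalizeROI(img, mask)
      extractAll(img, mask, mode = "2D", nLevels = nLevels)
    })
    averageOverSlices(vecs)
  }
}

#' Extract per-stratum feature tables from a phantom series
#'
#' For every combination of tissue, matrix size, analysis mode and
#' normalization, extracts the feature vector of each subject (slice
#' features averaged in 2D mode) and assembles a [TextureFeatureSet].
#'
#' @param series a [PhantomSeries-class].
#' @param modes subset of `c("2D", "3D")`.
#' @param normalizations subset of `c("raw", "pm3sigma")`.
#' @param nLevels gray levels for quantization (default 64).
#' @param verbose print progress.
#' @return nested list `tables[[mode]][[normalization]][[tissue]][[matrix]]`.
#' @export
extractFeatureTables <- function(series, modes = "2D",
                                 normalizations = c("raw", "pm3sigma"),
                                 nLevels = 64L, verbose = FALSE) {
  stopifnot(is(series, "PhantomSeries"))
  out <- list()
  for (mode in modes) {
    reg <- featureRegistry(mode)
    for (nrm in normalizations) {
      for (tis in series@tissues) {
        for (m in series@matrixSizes) {
          if (verbose)
            message("features: ", mode, "/", nrm, "/", tis, "/", m)
          msk <- phantomMask(series, m, tis)
          vals <- t(vapply(seq_len(nSubjects(series)), function(s)
            .subjectFeatures(series@images[[s]][[as.character(m)]], msk,
                             mode, nrm, nLevels),
            numeric(nrow(reg))))
          dimnames(vals) <- list(series@subjectIds, reg$name)
          out[[mode]][[nrm]][[tis]][[as.character(m)]] <-
            TextureFeatureSet(vals, m, tis, mode, nrm)
        }
      }
    }
  }
  out
}

#' Run the full concordance pipeline
#'
#' Builds (or loads) the image series, extracts all feature tables, computes
#' Lin's concordance for every matrix pair within each stratum, aggregates
#' neighboring and all-pairs transition reports, and computes the quality
#' report. With `outDir` set, writes tidy CSVs (feature tables, per-feature
#' CCC, transition reports, quality report), the feature registry (JSON) and
#' the resolved configuration (JSON). The run is deterministic given the
#' configuration.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @param verbose print progress.
#' @return list with `series`, `featureTables`, `ccc` (per-stratum lists of
#'   [CCCResult-class]), `transitions` (per-stratum
#'   [TransitionReport-class]s under `$neighboring` / `$all_pairs`) and
#'   `quality`.
#' @export
runPipeline <- function(config = runConfig(), verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  series <- if (config$inputMode == "synthetic") {
    buildPhantomSeries(nSubjects = config$nSubjects,
                       matrixSizes = config$matrixSizes,
                       masterSeed = config$masterSeed,
                       nSlices = config$nSlices,
                       noiseScale = config$noiseScale, fovMM = config$fovMM,
                       referenceMatrix = config$referenceMatrix)
  } else {
    readImageStack(config$manifest)
  }
  tables <- extractFeatureTables(series, config$modes,
                                 config$normalizations, config$nLevels,
                                 verbose = verbose)
  sizes <- series@matrixSizes
  pairs <- utils::combn(as.character(sizes), 2)
  ccc <- list(); transitions <- list()
  for (mode in config$modes) {
    for (nrm in config$normalizations) {
      for (tis in series@tissues) {
        tabs <- tables[[mode]][[nrm]][[tis]]
        res <- lapply(seq_len(ncol(pairs)), function(i)
          cccBetweenMatrices(tabs[[pairs[1, i]]], tabs[[pairs[2, i]]]))
        key <- paste(mode, nrm, tis, sep = ".")
        ccc[[key]] <- res
        transitions[[key]] <- list(
          neighboring = aggregateTransitions(res, "neighboring", sizes),
          all_pairs = aggregateTransitions(res, "all_pairs", sizes))
      }
    }
  }
  quality <- qualityReport(series, fovMM = config$fovMM)
  out <- list(series = series, featureTables = tables, ccc = ccc,
              transitions = transitions, quality = quality, config = config)
  if (!is.null(config$outDir)) writeRunArtifacts(out, config$outDir)
  out
}

#' Write pipeline artifacts to disk
#'
#' @param run result of [runPipeline()].
#' @param outDir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeRunArtifacts <- function(run, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  # tidy feature tables
  featRows <- list()
  for (mode in names(run$featureTables))
    for (nrm in names(run$featureTables[[mode]]))
      for (tis in names(run$featureTables[[mode]][[nrm]]))
        for (m in names(run$featureTables[[mode]][[nrm]][[tis]])) {
          fs <- run$featureTables[[mode]][[nrm]][[tis]][[m]]
          v <- featureValues(fs)
          featRows[[paste(mode, nrm, tis, m)]] <- data.frame(
            subject = rep(rownames(v), ncol(v)),
            matrix_size = as.integer(m), tissue = tis, mode = mode,
            normalization = nrm,
            feature = rep(colnames(v), each = nrow(v)),
            value = as.vector(v))
        }
  p <- file.path(outDir, "feature_tables.csv")
  utils::write.csv(do.call(rbind, featRows), p, row.names = FALSE)
  paths <- c(paths, p)
  # transition reports
  trRows <- list(); mcRows <- list()
  for (key in names(run$transitions)) {
    for (scope in c("neighboring", "all_pairs")) {
      tr <- run$transitions[[key]][[scope]]
      tt <- transitionTable(tr)
      tt$scope <- scope
      trRows[[paste(key, scope)]] <- tt
    }
    mcRows[[key]] <- meanChange(run$transitions[[key]]$neighboring)
  }
  p <- file.path(outDir, "transition_report.csv")
  utils::write.csv(do.call(rbind, trRows), p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(outDir, "mean_change.csv")
  utils::write.csv(do.call(rbind, mcRows), p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(outDir, "quality_report.csv")
  utils::write.csv(qualityTable(run$quality), p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(outDir, "feature_registry.json")
  jsonlite::write_json(lapply(run$config$modes, featureRegistry), p)
  paths <- c(paths, p)
  cfg <- run$config
  cfg$outDir <- NULL
  p <- file.path(outDir, "run_config.json")
  jsonlite::write_json(unclass(cfg), p, auto_unbox = TRUE, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}
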
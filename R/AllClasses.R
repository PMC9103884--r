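#' @import methods
#' @importFrom stats fft rnorm runif var sd median quantile
NULL

#' Acquisition geometry and noise model of one simulated scan
#'
#' Describes how one image is (re-)acquired: the acquisition matrix (pixels
#' per side), the fixed physical field of view, slice thickness, and the
#' Gaussian noise level. `noiseScale` is the noise standard deviation at the
#' reference matrix; smaller matrices receive proportionally less noise
#' because larger voxels collect more signal (noise sd scales with
#' `(matrixSize / referenceMatrix)^2`, i.e. SNR scales with voxel area).
#'
#' @slot matrixSize integer, pixels per image side.
#' @slot fovMM numeric, field of view in mm (fixed across matrix sizes).
#' @slot sliceThicknessMM numeric, slice thickness in mm.
#' @slot noiseScale numeric >= 0, noise sd at the reference matrix.
#' @slot referenceMatrix integer, matrix size of the reference image that
#'   acquisitions are simulated from (default 512).
#'
#' @examples
#' sp <- AcquisitionSpec(256)
#' pixelSpacing(sp)   # 200 / 256 mm
#' @export
setClass("AcquisitionSpec",
  representation(matrixSize = "integer", fovMM = "numeric",
                 sliceThicknessMM = "numeric", noiseScale = "numeric",
                 referenceMatrix = "integer"),
  validity = function(object) {
    msg <- character()
    m <- object@matrixSize
    if (length(m) != 1L || is.na(m) || m < 32L)
      msg <- c(msg, "matrixSize must be a single integer >= 32")
    else if (m %% 2L != 0L)
      msg <- c(msg, "matrixSize must be even")
    if (object@fovMM <= 0) msg <- c(msg, "fovMM must be positive")
    if (object@sliceThicknessMM <= 0)
      msg <- c(msg, "sliceThicknessMM must be positive")
    if (object@noiseScale < 0) msg <- c(msg, "noiseScale must be >= 0")
    if (object@referenceMatrix < 32L || object@referenceMatrix %% 2L != 0L)
      msg <- c(msg, "referenceMatrix must be an even integer >= 32")
    if (length(msg)) msg else TRUE
  })

#' @rdname AcquisitionSpec-class
#' @param matrixSize,fovMM,sliceThicknessMM,noiseScale,referenceMatrix see
#'   the corresponding slots.
#' @return an [AcquisitionSpec-class] object.
#' @export
AcquisitionSpec <- function(matrixSize, fovMM = 200, sliceThicknessMM = 3,
                            noiseScale = 0, referenceMatrix = 512L) {
  new("AcquisitionSpec", matrixSize = as.integer(matrixSize),
      fovMM = as.numeric(fovMM), sliceThicknessMM = as.numeric(sliceThicknessMM),
      noiseScale = as.numeric(noiseScale),
      referenceMatrix = as.integer(referenceMatrix))
}

#' Configuration of one synthetic tissue texture
#'
#' Parameters of the texture generator for one tissue class. The three
#' built-in classes emulate the qualitative structure of shoulder MRI
#' tissues: `bone` is a binarized trabecular pattern (band-pass noise,
#' fine granules), `fat` consists of blobby lobules with saturated edges
#' (low-pass noise through a tanh nonlinearity) and `muscle` is a smooth,
#' low-contrast, directional striped pattern.
#'
#' @slot tissueClass one of `"bone"`, `"fat"`, `"muscle"`.
#' @slot granuleScalePx characteristic texture element size in pixels at the
#'   reference matrix (>= 1 not required; bone trabeculae are ~1.5 px at a
#'   0.39 mm spacing).
#' @slot directionality in `[0, 1]`; 0 = isotropic, 1 = fully striped.
#' @slot contrast texture amplitude (intensity units); 0 gives a constant.
#' @slot baseIntensity mean tissue intensity.
#' @slot seed integer RNG seed for the noise field.
#' @export
setClass("TissuePhantomConfig",
  representation(tissueClass = "character", granuleScalePx = "numeric",
                 directionality = "numeric", contrast = "numeric",
                 baseIntensity = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@tissueClass) != 1L)
      msg <- c(msg, "tissueClass must be a single string")
    if (object@granuleScalePx <= 0) msg <- c(msg, "granuleScalePx must be > 0")
    if (object@directionality < 0 || object@directionality > 1)
      msg <- c(msg, "directionality must be in [0, 1]")
    if (object@contrast < 0) msg <- c(msg, "contrast must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname TissuePhantomConfig-class
#' @param tissueClass,granuleScalePx,directionality,contrast,baseIntensity,seed
#'   see the corresponding slots; unset texture parameters take the
#'   class-specific defaults of [tissueDefaults()].
#' @return a [TissuePhantomConfig-class] object.
#' @export
TissuePhantomConfig <- function(tissueClass, granuleScalePx = NULL,
                                directionality = NULL, contrast = NULL,
                                baseIntensity = NULL, seed = 0L) {
  def <- .tissueClassDefaults(tissueClass)
  new("TissuePhantomConfig", tissueClass = tissueClass,
      granuleScalePx = as.numeric(granuleScalePx %||% def$granuleScalePx),
      directionality = as.numeric(directionality %||% def$directionality),
      contrast = as.numeric(contrast %||% def$contrast),
      baseIntensity = as.numeric(baseIntensity %||% def$baseIntensity),
      seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-subject, multi-matrix phantom series
#'
#' Container for a paired synthetic study: every subject is rendered once at
#' the reference matrix (per slice) and then re-acquired at every requested
#' matrix size from the same reference, so all matrix sizes of a slice are
#' paired. ROI masks are stored per matrix size and tissue.
#'
#' @slot images nested list: `images[[subject]][[as.character(matrix)]]` is a
#'   `size x size x nSlices` array.
#' @slot masks nested list: `masks[[as.character(matrix)]][[tissue]]` is a
#'   logical matrix (shared by all subjects; the phantom geometry is fixed).
#' @slot matrixSizes integer vector of simulated matrix sizes.
#' @slot nSlices integer, slices per subject.
#' @slot tissues character vector of tissue labels.
#' @slot subjectIds character vector.
#' @slot provenance list of seeds and configurations used.
#' @export
setClass("PhantomSeries",
  representation(images = "list", masks = "list", matrixSizes = "integer",
                 nSlices = "integer", tissues = "character",
                 subjectIds = "character", provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@images) != length(object@subjectIds))
      msg <- c(msg, "one image set per subject required")
    key <- as.character(object@matrixSizes)
    for (s in seq_along(object@images)) {
      if (!identical(sort(names(object@images[[s]])), sort(key))) {
        msg <- c(msg, "every subject must cover the identical matrix-size set")
        break
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Gray-level quantized ROI
#'
#' In-mask intensities mapped to integer levels `0 .. nLevels - 1`;
#' out-of-mask pixels are `NA`.
#'
#' @slot levels integer matrix (or 3D array), `NA` outside the mask.
#' @slot mask logical matrix/array.
#' @slot nLevels integer >= 2.
#' @slot bounds numeric length 2, the (low, high) intensities mapped to the
#'   level range.
#' @export
setClass("QuantizedROI",
  representation(levels = "array", mask = "array", nLevels = "integer",
                 bounds = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nLevels < 2L) msg <- c(msg, "nLevels must be >= 2")
    v <- object@levels[object@mask]
    v <- v[!is.na(v)]
    if (length(v) && (min(v) < 0L || max(v) >= object@nLevels))
      msg <- c(msg, "in-mask levels must lie in [0, nLevels - 1]")
    if (length(msg)) msg else TRUE
  })

#' Normalized co-occurrence matrix
#'
#' Symmetric gray-level co-occurrence probabilities for one offset
#' (direction and pixel distance); pairs are counted in both orders and
#' only when both pixels are in-mask.
#'
#' @slot probs `nLevels x nLevels` matrix of probabilities summing to 1.
#' @slot direction character label (`"0"`, `"45"`, `"90"`, `"135"`, or a 3D
#'   offset label such as `"1.0.0"`).
#' @slot distance integer pixel distance.
#' @slot nPairs integer, number of ordered pairs counted.
#' @export
setClass("CooccurrenceMatrix",
  representation(probs = "matrix", direction = "character",
                 distance = "integer", nPairs = "integer"),
  validity = function(object) {
    msg <- character()
    if (abs(sum(object@probs) - 1) > 1e-9)
      msg <- c(msg, "probabilities must sum to 1")
    if (max(abs(object@probs - t(object@probs))) > 1e-12)
      msg <- c(msg, "matrix must be symmetric")
    if (length(msg)) msg else TRUE
  })

#' Per-stratum feature table backed by SummarizedExperiment
#'
#' Rows are texture features (with their family in `rowData`), columns are
#' subjects. `metadata()` carries the stratum: matrix size, tissue label,
#' analysis mode (`"2D"`/`"3D"`) and normalization (`"raw"`/`"pm3sigma"`).
#'
#' @export
setClass("TextureFeatureSet", contains = "SummarizedExperiment")

#' Per-feature Lin's concordance between two matrix sizes
#'
#' One row per feature with Lin's concordance correlation coefficient and
#' its ingredients (Pearson correlation, per-matrix means and standard
#' deviations over subjects). Features with zero variance at both matrix
#' sizes are flagged undefined and excluded from averages.
#'
#' @slot table data.frame with columns `feature`, `family`, `rho_c`, `rho`,
#'   `mu_i`, `mu_j`, `sigma_i`, `sigma_j`, `defined`.
#' @slot pair integer length 2, the two matrix sizes (i, j).
#' @slot tissue,mode,normalization stratum labels.
#' @export
setClass("CCCResult",
  representation(table = "data.frame", pair = "integer", tissue = "character",
                 mode = "character", normalization = "character"))

#' Family-aggregated concordance per matrix-size transition
#'
#' @slot table tidy data.frame: `tissue`, `mode`, `normalization`, `pair`,
#'   `family` (`"ALL"` for the overall per-feature mean), `mean_ccc`,
#'   `n_defined`, `n_excluded`.
#' @slot meanChange data.frame with the mean absolute change of the average
#'   concordance across consecutive neighboring transitions.
#' @slot scope `"neighboring"` or `"all_pairs"`.
#' @export
setClass("TransitionReport",
  representation(table = "data.frame", meanChange = "data.frame",
                 scope = "character"))

#' SNR and sharpness comparator metrics
#'
#' @slot table data.frame: `matrix_size`, `tissue`, `snr_mean`,
#'   `sharpness_mean`, `estimator`, `n`.
#' @export
setClass("QualityReport", representation(table = "data.frame"))
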
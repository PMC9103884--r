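#' @rdname AcquisitionSpec-class
#' @export
setMethod("matrixSize", "AcquisitionSpec", function(x) x@matrixSize)

#' @rdname AcquisitionSpec-class
#' @export
setMethod("pixelSpacing", "AcquisitionSpec",
          function(x) x@fovMM / x@matrixSize)

#' @rdname AcquisitionSpec-class
#' @export
setMethod("noiseScale", "AcquisitionSpec", function(x) x@noiseScale)

#' @rdname AcquisitionSpec-class
#' @export
setMethod("referenceMatrix", "AcquisitionSpec", function(x) x@referenceMatrix)

setMethod("show", "AcquisitionSpec", function(object) {
  cat(sprintf("AcquisitionSpec: %d x %d px, FOV %g mm (%.3f mm/px), slice %g mm, noise sd %g @ %d\n",
              object@matrixSize, object@matrixSize, object@fovMM,
              object@fovMM / object@matrixSize, object@sliceThicknessMM,
              object@noiseScale, object@referenceMatrix))
})

setMethod("show", "TissuePhantomConfig", function(object) {
  cat(sprintf("TissuePhantomConfig '%s': granule %g px, directionality %g, contrast %g, base %g, seed %d\n",
              object@tissueClass, object@granuleScalePx, object@directionality,
              object@contrast, object@baseIntensity, object@seed))
})

#' @rdname PhantomSeries-class
#' @export
setMethod("nSubjects", "PhantomSeries", function(x) length(x@subjectIds))

#' @rdname PhantomSeries-class
#' @export
setMethod("matrixSizes", "PhantomSeries", function(x) x@matrixSizes)

#' @rdname PhantomSeries-class
#' @export
setMethod("tissueLabels", "PhantomSeries", function(x) x@tissues)

#' @rdname PhantomSeries-class
#' @export
setMethod("phantomImage", "PhantomSeries", function(x, subject, size, slice = 1L) {
  if (is.character(subject)) subject <- match(subject, x@subjectIds)
  stk <- x@images[[subject]][[as.character(size)]]
  if (is.null(stk)) stop("matrix size ", size, " not present in series")
  stk[, , slice]
})

#' @rdname PhantomSeries-class
#' @export
setMethod("phantomMask", "PhantomSeries", function(x, size, tissue) {
  m <- x@masks[[as.character(size)]][[tissue]]
  if (is.null(m)) stop("no mask for matrix ", size, " / tissue ", tissue)
  m
})

setMethod("show", "PhantomSeries", function(object) {
  cat("PhantomSeries:", nSubjects(object), "subjects,",
      object@nSlices, "slices/subject\n",
      " matrix sizes:", paste(object@matrixSizes, collapse = ", "), "\n",
      " tissues:", paste(object@tissues, collapse = ", "), "\n")
})

setMethod("show", "QuantizedROI", function(object) {
  cat(sprintf("QuantizedROI: %s, %d gray levels, bounds [%g, %g], %d in-mask px\n",
              paste(dim(object@levels), collapse = "x"), object@nLevels,
              object@bounds[1], object@bounds[2], sum(object@mask)))
})

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat(sprintf("CooccurrenceMatrix: Ng = %d, direction %s, distance %d, %d pairs\n",
              nrow(object@probs), object@direction, object@distance,
              object@nPairs))
})

#' @rdname TextureFeatureSet
#' @param x a `TextureFeatureSet`.
#' @return `featureValues()` returns the subjects-by-features numeric matrix.
#' @export
setMethod("featureValues", "TextureFeatureSet",
          function(x) t(SummarizedExperiment::assay(x, "features")))

#' @rdname TextureFeatureSet
#' @export
setMethod("featureFamilies", "TextureFeatureSet",
          function(x) as.character(SummarizedExperiment::rowData(x)$family))

#' @rdname TextureFeatureSet
#' @export
setMethod("matrixSize", "TextureFeatureSet",
          function(x) S4Vectors::metadata(x)$matrixSize)

#' @rdname TextureFeatureSet
#' @export
setMethod("normalizationMode", "TextureFeatureSet",
          function(x) S4Vectors::metadata(x)$normalization)

#' @rdname TextureFeatureSet
#' @export
setMethod("tissueLabel", "TextureFeatureSet",
          function(x) S4Vectors::metadata(x)$tissue)

#' @rdname CCCResult-class
#' @param x a `CCCResult`.
#' @export
setMethod("cccTable", "CCCResult", function(x) x@table)

setMethod("show", "CCCResult", function(object) {
  def <- object@table$defined
  cat(sprintf("CCCResult %d vs %d (%s, %s, %s): %d features, %d defined, mean rho_c %.3f\n",
              object@pair[1], object@pair[2], object@tissue, object@mode,
              object@normalization, nrow(object@table), sum(def),
              mean(object@table$rho_c[def])))
})

#' @rdname TransitionReport-class
#' @param x a `TransitionReport`.
#' @export
setMethod("transitionTable", "TransitionReport", function(x) x@table)

#' @rdname TransitionReport-class
#' @export
setMethod("meanChange", "TransitionReport", function(x) x@meanChange)

setMethod("show", "TransitionReport", function(object) {
  cat("TransitionReport (", object@scope, " scope)\n", sep = "")
  print(utils::head(object@table[object@table$family == "ALL", ], 12))
})

#' @rdname QualityReport-class
#' @param x a `QualityReport`.
#' @export
setMethod("qualityTable", "QualityReport", function(x) x@table)

setMethod("show", "QualityReport", function(object) {
  cat("QualityReport\n")
  print(object@table)
})
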
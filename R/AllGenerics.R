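#' @rdname AcquisitionSpec-class
#' @param object,x an object.
#' @export
setGeneric("matrixSize", function(x) standardGeneric("matrixSize"))

#' @rdname AcquisitionSpec-class
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname AcquisitionSpec-class
#' @export
setGeneric("noiseScale", function(x) standardGeneric("noiseScale"))

#' @rdname AcquisitionSpec-class
#' @export
setGeneric("referenceMatrix", function(x) standardGeneric("referenceMatrix"))

#' @rdname PhantomSeries-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname PhantomSeries-class
#' @export
setGeneric("matrixSizes", function(x) standardGeneric("matrixSizes"))

#' @rdname PhantomSeries-class
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))

#' @rdname PhantomSeries-class
#' @param subject subject index or id.
#' @param size one matrix size present in the series.
#' @param slice slice index.
#' @export
setGeneric("phantomImage",
           function(x, subject, size, slice = 1L) standardGeneric("phantomImage"))

#' @rdname PhantomSeries-class
#' @param tissue tissue label.
#' @export
setGeneric("phantomMask",
           function(x, size, tissue) standardGeneric("phantomMask"))

#' @rdname TextureFeatureSet
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname TextureFeatureSet
#' @export
setGeneric("featureFamilies", function(x) standardGeneric("featureFamilies"))

#' @rdname TextureFeatureSet
#' @export
setGeneric("normalizationMode", function(x) standardGeneric("normalizationMode"))

#' @rdname TextureFeatureSet
#' @export
setGeneric("tissueLabel", function(x) standardGeneric("tissueLabel"))

#' @rdname CCCResult-class
#' @export
setGeneric("cccTable", function(x) standardGeneric("cccTable"))

#' @rdname TransitionReport-class
#' @export
setGeneric("transitionTable", function(x) standardGeneric("transitionTable"))

#' @rdname TransitionReport-class
#' @export
setGeneric("meanChange", function(x) standardGeneric("meanChange"))

#' @rdname QualityReport-class
#' @export
setGeneric("qualityTable", function(x) standardGeneric("qualityTable"))
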
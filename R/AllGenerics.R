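#' @include AllClasses.R
NULL

#' @rdname IMSDataset-accessors
#' @export
setGeneric("intensityMatrix", function(object) standardGeneric("intensityMatrix"))

#' @rdname IMSDataset-accessors
#' @export
setGeneric("pixelCoords", function(object) standardGeneric("pixelCoords"))

#' @rdname IMSDataset-accessors
#' @export
setGeneric("mzValues", function(object) standardGeneric("mzValues"))

#' @rdname IMSDataset-accessors
#' @export
setGeneric("datasetName", function(object) standardGeneric("datasetName"))

#' @rdname IMSDataset-accessors
#' @export
setGeneric("nPixels", function(object) standardGeneric("nPixels"))

#' @rdname IMSDataset-accessors
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))

#' @rdname AnnotationMask-accessors
#' @export
setGeneric("targetClass", function(object) standardGeneric("targetClass"))

#' @rdname AnnotationMask-accessors
#' @export
setGeneric("maskLabels", function(object) standardGeneric("maskLabels"))

#' @rdname SpatialImage-accessors
#' @export
setGeneric("imageValues", function(object) standardGeneric("imageValues"))

#' @rdname SpatialImage-accessors
#' @export
setGeneric("imageLegend", function(object) standardGeneric("imageLegend"))

#' @rdname TreeEnsemble-accessors
#' @export
setGeneric("basePrediction", function(object) standardGeneric("basePrediction"))

#' @rdname TreeEnsemble-accessors
#' @export
setGeneric("learningRate", function(object) standardGeneric("learningRate"))

#' @rdname TreeEnsemble-accessors
#' @export
setGeneric("trees", function(object) standardGeneric("trees"))

#' @rdname ShapleyMatrix-accessors
#' @export
setGeneric("baseValue", function(object) standardGeneric("baseValue"))

#' @rdname ShapleyMatrix-accessors
#' @export
setGeneric("shapValues", function(object) standardGeneric("shapValues"))

#' @rdname ShapleyMatrix-accessors
#' @export
setGeneric("pixelIndices", function(object) standardGeneric("pixelIndices"))
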
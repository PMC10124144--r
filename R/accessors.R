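#' @include AllGenerics.R
NULL

#' Accessors for IMSDataset
#'
#' @param object an \linkS4class{IMSDataset}.
#' @return \code{intensityMatrix}: the m x n intensity matrix;
#'   \code{pixelCoords}: the m x 2 0-based (row, col) matrix;
#'   \code{mzValues}: the n m/z values; \code{datasetName}: the name;
#'   \code{nPixels}, \code{nFeatures}: dimensions.
#' @name IMSDataset-accessors
NULL

#' @rdname IMSDataset-accessors
#' @export
setMethod("intensityMatrix", "IMSDataset", function(object) object@intensities)

#' @rdname IMSDataset-accessors
#' @export
setMethod("pixelCoords", "IMSDataset", function(object) object@pixelCoords)

#' @rdname IMSDataset-accessors
#' @export
setMethod("mzValues", "IMSDataset", function(object) object@mzValues)

#' @rdname IMSDataset-accessors
#' @export
setMethod("datasetName", "IMSDataset", function(object) object@name)

#' @rdname IMSDataset-accessors
#' @export
setMethod("nPixels", "IMSDataset", function(object) nrow(object@intensities))

#' @rdname IMSDataset-accessors
#' @export
setMethod("nFeatures", "IMSDataset", function(object) ncol(object@intensities))

#' Accessors for AnnotationMask
#'
#' @param object an \linkS4class{AnnotationMask}.
#' @name AnnotationMask-accessors
NULL

#' @rdname AnnotationMask-accessors
#' @export
setMethod("targetClass", "AnnotationMask", function(object) object@className)

#' @rdname AnnotationMask-accessors
#' @export
setMethod("maskLabels", "AnnotationMask", function(object) object@labels)

#' Accessors for SpatialImage
#'
#' @param object a \linkS4class{SpatialImage}.
#' @name SpatialImage-accessors
NULL

#' @rdname SpatialImage-accessors
#' @export
setMethod("imageValues", "SpatialImage", function(object) object@values)

#' @rdname SpatialImage-accessors
#' @export
setMethod("imageLegend", "SpatialImage", function(object) object@legend)

#' @rdname SpatialImage-accessors
#' @export
setMethod("dim", "SpatialImage", function(x) dim(x@values))

#' Accessors for TreeEnsemble
#'
#' @param object a \linkS4class{TreeEnsemble}.
#' @name TreeEnsemble-accessors
NULL

#' @rdname TreeEnsemble-accessors
#' @export
setMethod("basePrediction", "TreeEnsemble", function(object) object@basePrediction)

#' @rdname TreeEnsemble-accessors
#' @export
setMethod("learningRate", "TreeEnsemble", function(object) object@learningRate)

#' @rdname TreeEnsemble-accessors
#' @export
setMethod("trees", "TreeEnsemble", function(object) object@trees)

#' @rdname TreeEnsemble-accessors
#' @export
setMethod("nFeatures", "TreeEnsemble", function(object) as.integer(object@nFeatures))

#' Accessors for ShapleyMatrix
#'
#' @param object a \linkS4class{ShapleyMatrix}.
#' @name ShapleyMatrix-accessors
NULL

#' @rdname ShapleyMatrix-accessors
#' @export
setMethod("baseValue", "ShapleyMatrix", function(object) object@baseValue)

#' @rdname ShapleyMatrix-accessors
#' @export
setMethod("shapValues", "ShapleyMatrix", function(object) object@values)

#' @rdname ShapleyMatrix-accessors
#' @export
setMethod("pixelIndices", "ShapleyMatrix", function(object) object@pixelIndices)

setMethod("show", "IMSDataset", function(object) {
  cat("IMSDataset '", object@name, "': ",
      nrow(object@intensities), " pixels x ",
      ncol(object@intensities), " m/z features\n", sep = "")
  cat("  m/z range: ", format(min(object@mzValues)), " - ",
      format(max(object@mzValues)), "\n", sep = "")
  cat("  grid: ", max(object@pixelCoords[, 1L]) + 1L, " x ",
      max(object@pixelCoords[, 2L]) + 1L, "\n", sep = "")
})

setMethod("show", "AnnotationMask", function(object) {
  tb <- table(factor(object@labels, c("POS", "NEG", "EXCLUDED")))
  cat("AnnotationMask for class '", object@className, "': ",
      tb[["POS"]], " POS / ", tb[["NEG"]], " NEG / ",
      tb[["EXCLUDED"]], " EXCLUDED\n", sep = "")
})

setMethod("show", "SpatialImage", function(object) {
  cat("SpatialImage ", nrow(object@values), " x ", ncol(object@values),
      " (", sum(!is.na(object@values)), " pixels): ",
      object@legend, "\n", sep = "")
})

setMethod("show", "TreeEnsemble", function(object) {
  cat("TreeEnsemble: ", length(object@trees), " trees, ",
      object@nFeatures, " features, base log-odds ",
      format(object@basePrediction, digits = 4),
      ", learning rate ", format(object@learningRate), "\n", sep = "")
})

setMethod("show", "ShapleyMatrix", function(object) {
  cat("ShapleyMatrix: ", nrow(object@values), " pixels x ",
      ncol(object@values), " features, base value ",
      format(object@baseValue, digits = 6), " (log-odds)\n", sep = "")
})
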
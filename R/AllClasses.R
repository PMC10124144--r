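#' @include shapMSI-package.R
NULL

#' IMSDataset: a peak-picked imaging mass spectrometry dataset
#'
#' Holds the pixels x features intensity matrix \eqn{X}, the 0-based
#' (row, col) grid coordinate of every pixel, and the m/z value of every
#' feature. Rows of the matrix are pixel mass spectra; columns are m/z bins.
#'
#' @slot intensities numeric matrix, m pixels x n features, finite and
#'   non-negative, in arbitrary ion-intensity units.
#' @slot pixelCoords integer matrix, m x 2, 0-based (row, col) per pixel,
#'   unique.
#' @slot mzValues numeric vector of n strictly increasing m/z values (Da).
#' @slot name character scalar naming the dataset.
#' @export
setClass("IMSDataset",
  representation(
    intensities = "matrix",
    pixelCoords = "matrix",
    mzValues = "numeric",
    name = "character"
  )
)

setValidity("IMSDataset", function(object) {
  X <- object@intensities
  co <- object@pixelCoords
  mz <- object@mzValues
  if (nrow(X) < 1L || ncol(X) < 1L)
    return("dataset must have at least one pixel and one feature")
  if (!is.numeric(X) || any(!is.finite(X)))
    return("intensities must be finite (no NaN/Inf/NA)")
  if (any(X < 0))
    return("intensities must be non-negative")
  if (nrow(co) != nrow(X) || ncol(co) != 2L)
    return("pixelCoords must be an m x 2 matrix matching the intensity rows")
  if (any(co < 0) || any(co != round(co)))
    return("pixel coordinates must be non-negative integers")
  dup <- duplicated(co)
  if (any(dup)) {
    d <- co[which(dup)[1L], ]
    return(sprintf("duplicate pixel coordinate (%d,%d)", d[1L], d[2L]))
  }
  if (length(mz) != ncol(X))
    return("length of mzValues must equal the number of intensity columns")
  if (any(!is.finite(mz)) || any(mz <= 0))
    return("m/z values must be positive and finite")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    return("m/z not strictly increasing")
  if (length(object@name) != 1L)
    return("name must be a single string")
  TRUE
})

#' SpatialImage: one value per pixel-grid cell
#'
#' A H x W grid of values over the acquisition raster of an
#' \linkS4class{IMSDataset}; cells with no acquired pixel are \code{NA}.
#' Carries ion images, class-prediction maps, and SHAP maps.
#'
#' @slot values numeric H x W matrix; \code{NA} marks cells without a pixel.
#' @slot legend character scalar describing what the values are.
#' @export
setClass("SpatialImage",
  representation(values = "matrix", legend = "character")
)

setValidity("SpatialImage", function(object) {
  v <- object@values
  if (nrow(v) < 1L || ncol(v) < 1L) return("image must be non-empty")
  if (all(is.na(v))) return("image must have at least one non-missing cell")
  if (any(is.nan(v) | is.infinite(v), na.rm = TRUE))
    return("image values must be finite or NA")
  if (length(object@legend) != 1L) return("legend must be a single string")
  TRUE
})

#' AnnotationMask: per-pixel class annotation for one tissue class
#'
#' Assigns every pixel of a dataset one of three codes for a named class:
#' \code{"POS"} (belongs to the class), \code{"NEG"} (belongs to the rest),
#' or \code{"EXCLUDED"} (ambiguous, e.g. organ borders, dropped from
#' training so the learner never sees unreliable examples).
#'
#' @slot className character scalar, the target class.
#' @slot labels character vector, one code per dataset pixel.
#' @export
setClass("AnnotationMask",
  representation(className = "character", labels = "character")
)

setValidity("AnnotationMask", function(object) {
  if (length(object@className) != 1L)
    return("className must be a single string")
  if (!all(object@labels %in% c("POS", "NEG", "EXCLUDED")))
    return("labels must be POS, NEG or EXCLUDED")
  if (length(object@labels) < 1L) return("empty mask")
  TRUE
})

#' TreeEnsemble: an additive log-odds model of regression trees
#'
#' The raw output is the log-odds
#' \eqn{f(x) = \tau_0 + \nu \sum_k \tau_k(x)}: a base prediction plus the
#' shrinkage-weighted sum of the regression trees' terminal values. Each
#' tree is a flat numeric matrix with one row per node and columns
#' \code{feature} (1-based, -1 at leaves), \code{threshold}, \code{left},
#' \code{right} (1-based node rows, -1 at leaves), \code{value} (leaf
#' output) and \code{cover} (count of training pixels routed through the
#' node; supplies the weights of observational Shapley expectations).
#' Routing is \code{x[feature] <= threshold} to the left child, identically
#' in training, prediction and Shapley computation.
#'
#' @slot basePrediction numeric scalar \eqn{\tau_0}, log-odds.
#' @slot learningRate numeric scalar \eqn{\nu} in (0, 1].
#' @slot trees list of node matrices.
#' @slot nFeatures integer scalar, width of admissible inputs.
#' @export
setClass("TreeEnsemble",
  representation(
    basePrediction = "numeric",
    learningRate = "numeric",
    trees = "list",
    nFeatures = "integer"
  )
)

.validate_tree <- function(tr, nfeat) {
  if (!is.matrix(tr) || ncol(tr) != 6L) return("tree node table must have 6 columns")
  leaf <- tr[, 1L] < 0
  if (any(!is.finite(tr[!leaf, 1L:4L]))) return("internal node fields must be finite")
  if (any(!is.finite(tr[leaf, 5L]))) return("leaf values must be finite")
  if (any(tr[, 6L] <= 0)) return("node covers must be positive")
  if (any(tr[!leaf, 1L] > nfeat)) return("tree uses a feature index beyond nFeatures")
  ii <- which(!leaf)
  for (i in ii) {
    l <- tr[i, 3L]; r <- tr[i, 4L]
    if (l < 1 || l > nrow(tr) || r < 1 || r > nrow(tr))
      return("child pointer out of range")
    if (abs(tr[i, 6L] - tr[l, 6L] - tr[r, 6L]) > 1e-4 * max(1, tr[i, 6L]))
      return("cover(parent) != cover(left) + cover(right)")
  }
  TRUE
}

setValidity("TreeEnsemble", function(object) {
  if (length(object@basePrediction) != 1L || !is.finite(object@basePrediction))
    return("basePrediction must be a finite scalar")
  if (length(object@learningRate) != 1L ||
      object@learningRate <= 0 || object@learningRate > 1)
    return("learningRate must lie in (0, 1]")
  if (length(object@nFeatures) != 1L || object@nFeatures < 1L)
    return("nFeatures must be a positive integer")
  for (tr in object@trees) {
    msg <- .validate_tree(tr, object@nFeatures)
    if (!isTRUE(msg)) return(msg)
  }
  TRUE
})

#' ShapleyMatrix: per-pixel, per-feature attributions on the log-odds scale
#'
#' Row i holds the Shapley values of all features for pixel
#' \code{pixelIndices[i]}; together with the base value \eqn{\varphi_0}
#' (the model's expected raw output), each row reconstructs the raw
#' log-odds output of the explained ensemble for that pixel (local
#' accuracy).
#'
#' @slot baseValue numeric scalar \eqn{\varphi_0}.
#' @slot values numeric matrix, covered pixels x features.
#' @slot pixelIndices integer vector of covered dataset rows (1-based).
#' @export
setClass("ShapleyMatrix",
  representation(
    baseValue = "numeric",
    values = "matrix",
    pixelIndices = "integer"
  )
)

setValidity("ShapleyMatrix", function(object) {
  if (length(object@baseValue) != 1L || !is.finite(object@baseValue))
    return("baseValue must be a finite scalar")
  if (any(!is.finite(object@values)))
    return("Shapley values must be finite")
  if (nrow(object@values) != length(object@pixelIndices))
    return("one pixel index per value row required")
  if (anyDuplicated(object@pixelIndices))
    return("pixel indices must be unique")
  TRUE
})
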
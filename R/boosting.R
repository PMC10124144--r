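#' @include phantom.R
NULL

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Construct a labeled pixel subset
#'
#' @param pixelIndices unique 1-based indices into the dataset's pixels.
#' @param labels class labels, -1 or +1, one per index.
#' @return a \code{LabeledSubset} (list with the two fields).
#' @export
labeledSubset <- function(pixelIndices, labels) {
  pixelIndices <- as.integer(pixelIndices)
  labels <- as.integer(labels)
  if (length(pixelIndices) != length(labels))
    stop("indices and labels differ in length")
  if (anyDuplicated(pixelIndices)) stop("pixel indices must be unique")
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be -1 or +1")
  structure(list(pixelIndices = pixelIndices, labels = labels),
            class = "LabeledSubset")
}

#' Turn an annotation mask into training labels
#'
#' POS pixels become +1, NEG pixels -1, EXCLUDED pixels are dropped.
#'
#' @param mask an \linkS4class{AnnotationMask}.
#' @return a [labeledSubset()].
#' @export
makeLabels <- function(mask) {
  lab <- maskLabels(mask)
  keep <- lab != "EXCLUDED"
  if (!any(lab == "POS") || !any(lab == "NEG"))
    stop("mask for class '", targetClass(mask),
         "' must contain at least one POS and one NEG pixel")
  labeledSubset(which(keep), ifelse(lab[keep] == "POS", 1L, -1L))
}

#' Downsample the negative class
#'
#' Keeps every positive pixel and samples negatives without replacement so
#' that positives make up approximately \code{posFraction} of the subset
#' (the class balance used when training one-versus-all tissue
#' classifiers). If there are too few negatives, all are kept with a
#' warning.
#'
#' @param ls a [labeledSubset()].
#' @param posFraction target positive-class share, in (0, 1); default 0.25.
#' @param seed integer seed.
#' @return a [labeledSubset()] with indices in ascending order.
#' @export
downsampleNegatives <- function(ls, posFraction = 0.25, seed = 1L) {
  if (posFraction <= 0 || posFraction >= 1)
    stop("posFraction must lie in (0, 1)")
  pos <- ls$pixelIndices[ls$labels == 1L]
  neg <- ls$pixelIndices[ls$labels == -1L]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present")
  target <- round(length(pos) * (1 - posFraction) / posFraction)
  if (target >= length(neg)) {
    if (target > length(neg))
      warning("only ", length(neg), " negatives available (", target,
              " requested); keeping all")
    keepNeg <- neg
  } else {
    keepNeg <- .with_seed(seed, sort(sample(neg, target)))
  }
  idx <- sort(c(pos, keepNeg))
  labeledSubset(idx, ifelse(idx %in% pos, 1L, -1L))
}

#' Stratified holdout split
#'
#' Splits a labeled subset into disjoint, exhaustive train and test parts,
#' preserving the class proportions to rounding.
#'
#' @param ls a [labeledSubset()].
#' @param testFraction share of each class assigned to the test part.
#' @param seed integer seed.
#' @return list with \code{train} and \code{test} [labeledSubset()]s.
#' @export
splitHoldout <- function(ls, testFraction = 0.25, seed = 1L) {
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie in (0, 1)")
  pos <- ls$pixelIndices[ls$labels == 1L]
  neg <- ls$pixelIndices[ls$labels == -1L]
  if (length(pos) < 2L || length(neg) < 2L)
    stop("each class needs at least 2 members to split")
  pick <- .with_seed(seed, {
    list(pos = sample(pos, round(testFraction * length(pos))),
         neg = sample(neg, round(testFraction * length(neg))))
  })
  testIdx <- sort(c(pick$pos, pick$neg))
  trainIdx <- sort(setdiff(ls$pixelIndices, testIdx))
  lab <- function(idx) ifelse(idx %in% pos, 1L, -1L)
  list(train = labeledSubset(trainIdx, lab(trainIdx)),
       test = labeledSubset(testIdx, lab(testIdx)))
}

#' Boosting configuration
#'
#' Hyperparameters of the gradient-boosted tree ensemble. The learning
#' rate (shrinkage) default of 0.3 and the probability threshold 0.5 used
#' downstream follow common practice for boosted log-odds classifiers of
#' IMS pixels; tree count, depth and the L2 leaf penalty are exposed here
#' with conventional defaults.
#'
#' @param nTrees number of boosting rounds K (default 100).
#' @param maxDepth maximum tree depth (default 4).
#' @param learningRate shrinkage \eqn{\nu} in (0, 1) (default 0.3).
#' @param lambda L2 penalty on leaf values (default 1).
#' @param rowSubsample fraction of training pixels drawn per round
#'   (default 0.8).
#' @param colSubsample fraction of features drawn per split node
#'   (default 0.8).
#' @param minChildCover minimum training pixels per child node (default 5).
#' @param seed integer seed for the subsampling.
#' @return a validated \code{TrainingConfig} (list).
#' @export
trainingConfig <- function(nTrees = 100L, maxDepth = 4L, learningRate = 0.3,
                           lambda = 1, rowSubsample = 0.8, colSubsample = 0.8,
                           minChildCover = 5L, seed = 1L) {
  stopifnot(nTrees >= 0, maxDepth >= 1,
            learningRate > 0, learningRate < 1,
            lambda >= 0,
            rowSubsample > 0, rowSubsample <= 1,
            colSubsample > 0, colSubsample <= 1,
            minChildCover >= 1)
  structure(list(nTrees = as.integer(nTrees), maxDepth = as.integer(maxDepth),
                 learningRate = learningRate, lambda = lambda,
                 rowSubsample = rowSubsample, colSubsample = colSubsample,
                 minChildCover = as.integer(minChildCover),
                 seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' Train a gradient-boosted tree ensemble on the logistic loss
#'
#' Second-order (Newton) boosting: the base prediction is the training-set
#' base-rate log-odds \eqn{\tau_0 = \ln(n_{pos}/n_{neg})}; each round fits a
#' regression tree to the gradient/hessian of the logistic negative
#' log-likelihood (\eqn{g_i = p_i - t_i}, \eqn{h_i = p_i(1-p_i)}) by exact
#' greedy split search with L2-penalized gain, leaf values
#' \eqn{-\sum g / (\sum h + \lambda)}, per-round row subsampling and
#' per-node column subsampling. After a tree is grown its node covers are
#' recomputed as the count of \emph{all} training pixels routed through
#' each node, so the observational Shapley expectations downstream refer
#' to the training distribution rather than the round's subsample.
#'
#' @param ds an \linkS4class{IMSDataset}.
#' @param ls a [labeledSubset()] of training pixels.
#' @param cfg a [trainingConfig()].
#' @return a \linkS4class{TreeEnsemble}.
#' @export
trainEnsemble <- function(ds, ls, cfg = trainingConfig()) {
  stopifnot(is(ds, "IMSDataset"), inherits(ls, "LabeledSubset"),
            inherits(cfg, "TrainingConfig"))
  X <- intensityMatrix(ds)[ls$pixelIndices, , drop = FALSE]
  if (any(!is.finite(X))) stop("non-finite intensities in training data")
  y <- ls$labels
  npos <- sum(y == 1L); nneg <- sum(y == -1L)
  if (npos == 0L || nneg == 0L) stop("training set must contain both classes")
  tau0 <- log(npos / nneg)
  tvec <- (y + 1L) / 2
  m <- nrow(X)
  Fhat <- rep(tau0, m)
  treeList <- vector("list", cfg$nTrees)
  .with_seed(cfg$seed, {
    for (k in seq_len(cfg$nTrees)) {
      p <- .sigmoid(Fhat)
      g <- p - tvec
      h <- p * (1 - p)
      rows <- if (cfg$rowSubsample < 1) {
        size <- min(m, max(2L * cfg$minChildCover,
                           floor(cfg$rowSubsample * m)))
        sort(sample.int(m, size))
      } else seq_len(m)
      tr <- cpp_build_tree(X, g, h, rows - 1L, cfg$maxDepth, cfg$lambda,
                           cfg$colSubsample, cfg$minChildCover)
      tr[, "cover"] <- cpp_tree_covers(tr, X)
      treeList[[k]] <- tr
      Fhat <- Fhat + cfg$learningRate * cpp_tree_predict(tr, X)
    }
  })
  new("TreeEnsemble", basePrediction = tau0, learningRate = cfg$learningRate,
      trees = treeList, nFeatures = ncol(X))
}

.as_input_matrix <- function(ens, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != nFeatures(ens))
    stop("input has ", ncol(x), " features; ensemble expects ",
         nFeatures(ens))
  if (any(!is.finite(x))) stop("non-finite input")
  x
}

#' Raw log-odds output of an ensemble
#'
#' \eqn{f(x) = \tau_0 + \nu \sum_k \tau_k(x)}.
#'
#' @param ens a \linkS4class{TreeEnsemble}.
#' @param x feature vector or matrix (rows = observations).
#' @return numeric vector of log-odds.
#' @export
predictRaw <- function(ens, x) {
  x <- .as_input_matrix(ens, x)
  if (length(trees(ens)) == 0L)
    return(rep(basePrediction(ens), nrow(x)))
  basePrediction(ens) + learningRate(ens) * cpp_ensemble_predict(trees(ens), x)
}

#' Predicted positive-class probability
#'
#' Sigmoid transform of the raw log-odds.
#'
#' @inheritParams predictRaw
#' @return probabilities in (0, 1).
#' @export
predictProbability <- function(ens, x) .sigmoid(predictRaw(ens, x))

#' Predicted class at a probability threshold
#'
#' +1 when the predicted probability is at least \code{eta} (ties go to
#' the positive class), else -1.
#'
#' @inheritParams predictRaw
#' @param eta probability threshold in (0, 1); default 0.5.
#' @return integer vector of -1/+1.
#' @export
predictClass <- function(ens, x, eta = 0.5) {
  if (eta <= 0 || eta >= 1) stop("eta must lie in (0, 1)")
  ifelse(predictProbability(ens, x) >= eta, 1L, -1L)
}

#' Imbalance-aware classification metrics
#'
#' Confusion counts plus precision, recall (sensitivity), specificity and
#' balanced accuracy (the arithmetic mean of sensitivity and specificity).
#' A rate whose denominator is zero is reported as \code{NA}, and balanced
#' accuracy is \code{NA} if either component is.
#'
#' @param predictions predicted labels, -1/+1.
#' @param truth true labels, -1/+1.
#' @return a \code{ClassificationMetrics} list with fields \code{TP},
#'   \code{FP}, \code{TN}, \code{FN}, \code{precision}, \code{recall},
#'   \code{specificity}, \code{balancedAccuracy}.
#' @export
evaluateClassifier <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("predictions and truth differ in length")
  if (!all(predictions %in% c(-1L, 1L)) || !all(truth %in% c(-1L, 1L)))
    stop("labels must be -1 or +1")
  TP <- sum(predictions == 1L & truth == 1L)
  FP <- sum(predictions == 1L & truth == -1L)
  TN <- sum(predictions == -1L & truth == -1L)
  FN <- sum(predictions == -1L & truth == 1L)
  rate <- function(num, den) if (den == 0L) NA_real_ else num / den
  recall <- rate(TP, TP + FN)
  specificity <- rate(TN, TN + FP)
  structure(list(
    TP = TP, FP = FP, TN = TN, FN = FN,
    precision = rate(TP, TP + FP),
    recall = recall,
    specificity = specificity,
    balancedAccuracy = if (is.na(recall) || is.na(specificity)) NA_real_
                       else (recall + specificity) / 2
  ), class = "ClassificationMetrics")
}

#' @export
print.ClassificationMetrics <- function(x, ...) {
  cat(sprintf(
    "TP %d  FP %d  TN %d  FN %d\nprecision %s  recall %s  specificity %s  balanced accuracy %s\n",
    x$TP, x$FP, x$TN, x$FN,
    format(x$precision, digits = 4), format(x$recall, digits = 4),
    format(x$specificity, digits = 4),
    format(x$balancedAccuracy, digits = 4)))
  invisible(x)
}

#' Class-prediction map over the whole sample
#'
#' Applies the classifier to every pixel (labeled and unlabeled) and
#' places the -1/+1 predictions on the acquisition grid.
#'
#' @param ens a \linkS4class{TreeEnsemble}.
#' @param ds an \linkS4class{IMSDataset}.
#' @param eta probability threshold (default 0.5).
#' @return a \linkS4class{SpatialImage} of -1/+1.
#' @export
predictionImage <- function(ens, ds, eta = 0.5) {
  pred <- predictClass(ens, intensityMatrix(ds), eta)
  valuesToImage(ds, as.numeric(pred),
                legend = sprintf("predicted class (eta = %g)", eta))
}
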
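#' @include serialize.R
NULL

#' Features used by a regression tree
#'
#' @param tree a tree node matrix (see \linkS4class{TreeEnsemble}).
#' @return sorted 1-based indices of the features the tree splits on.
#' @export
treeUsedFeatures <- function(tree) {
  sort(unique(as.integer(tree[tree[, 1L] > 0, 1L])))
}

#' Tree-path-dependent conditional expectation of a tree's output
#'
#' Estimates \eqn{E[\tau(x) | x_S]} by recursive traversal: at a node
#' splitting on a feature in the coalition \code{S}, follow the branch
#' \code{x} takes; at a node splitting on a feature outside \code{S},
#' average both children's expectations weighted by their covers (the
#' count of training observations routed through them); at a leaf, return
#' its value. This is the observational set function underlying the
#' package's Shapley values.
#'
#' @param tree a tree node matrix with positive covers.
#' @param x full feature vector.
#' @param S coalition: 1-based feature indices conditioned on.
#' @return the conditional expectation (scalar).
#' @export
treeExpectation <- function(tree, x, S = integer(0)) {
  rec <- function(i) {
    f <- tree[i, 1L]
    if (f < 0) return(tree[i, 5L])
    if (f %in% S) {
      if (x[f] <= tree[i, 2L]) rec(tree[i, 3L]) else rec(tree[i, 4L])
    } else {
      l <- tree[i, 3L]; r <- tree[i, 4L]
      cl <- tree[l, 6L]; cr <- tree[r, 6L]
      if (cl + cr <= 0) stop("zero cover at an internal node")
      (cl * rec(l) + cr * rec(r)) / (cl + cr)
    }
  }
  rec(1L)
}

# All E[tau(x)|S] for subsets of the used-feature set U, indexed by bitmask.
.subset_expectations <- function(tree, x, U) {
  D <- length(U)
  E <- numeric(2^D)
  for (mask in 0:(2^D - 1)) {
    S <- U[bitwAnd(mask, bitwShiftL(1L, seq_len(D) - 1L)) != 0L]
    E[mask + 1L] <- treeExpectation(tree, x, S)
  }
  E
}

#' Exact Shapley values of one tree by subset enumeration
#'
#' Brute-force oracle: for each used feature j,
#' \eqn{\varphi_j = \sum_{S \subseteq U \setminus j}
#' |S|!(D-|S|-1)!/D! \, [E(S \cup j) - E(S)]} over the tree's D distinct
#' used features. Unused features contribute identically zero, so the
#' cooperative game collapses to the D used features. Refuses D > 15.
#'
#' @param tree a tree node matrix.
#' @param x full feature vector.
#' @return numeric vector as long as \code{x}; exact zeros for unused
#'   features.
#' @export
treeShapleySubsets <- function(tree, x) {
  U <- treeUsedFeatures(tree)
  D <- length(U)
  phi <- numeric(length(x))
  if (D == 0L) return(phi)
  if (D > 15L) stop("subset oracle refuses more than 15 distinct features")
  E <- .subset_expectations(tree, x, U)
  wt <- factorial(0:(D - 1)) * factorial(D - 1 - 0:(D - 1)) / factorial(D)
  bits <- bitwShiftL(1L, seq_len(D) - 1L)
  for (jj in seq_len(D)) {
    bj <- bits[jj]
    others <- setdiff(seq_len(D), jj)
    for (mask in 0:(2^D - 1)) {
      if (bitwAnd(mask, bj) != 0L) next
      s <- sum(bitwAnd(mask, bits) != 0L)
      phi[U[jj]] <- phi[U[jj]] +
        wt[s + 1L] * (E[bitwOr(mask, bj) + 1L] - E[mask + 1L])
    }
  }
  phi
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = max(1L, length(v) > 0L)))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- .permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

#' Exact Shapley values of one tree by ordering enumeration
#'
#' Literal definition: average over all D! orderings of the tree's used
#' features of the change in the tree-path-dependent expectation as each
#' feature is introduced. Refuses D > 8.
#'
#' @inheritParams treeShapleySubsets
#' @return numeric vector as long as \code{x}.
#' @export
treeShapleyOrderings <- function(tree, x) {
  U <- treeUsedFeatures(tree)
  D <- length(U)
  phi <- numeric(length(x))
  if (D == 0L) return(phi)
  if (D > 8L) stop("ordering oracle refuses more than 8 distinct features")
  E <- .subset_expectations(tree, x, U) # memo table keyed by bitmask
  bits <- bitwShiftL(1L, seq_len(D) - 1L)
  perms <- .permutations(seq_len(D))
  for (p in seq_len(nrow(perms))) {
    mask <- 0L
    for (jj in perms[p, ]) {
      nxt <- bitwOr(mask, bits[jj])
      phi[U[jj]] <- phi[U[jj]] + E[nxt + 1L] - E[mask + 1L]
      mask <- nxt
    }
  }
  phi / nrow(perms)
}

#' Exact Shapley values of one tree in polynomial time
#'
#' The tree-path-dependent algorithm: a single traversal maintains, for
#' every root-to-node path, the proportion of feature subsets of each
#' cardinality flowing down the path (extend/unwind recurrences over
#' cover fractions and routing indicators). Agrees with the brute-force
#' oracles wherever those are feasible.
#'
#' @inheritParams treeShapleySubsets
#' @return numeric vector as long as \code{x}.
#' @export
treeShapleyPath <- function(tree, x) {
  as.numeric(cpp_tree_shapley(tree, matrix(as.numeric(x), nrow = 1L)))
}

#' Observational Shapley values for every pixel of a dataset
#'
#' By linearity of the Shapley operator over the additive ensemble,
#' \code{values[i, j]} is the learning-rate-weighted sum of the per-tree
#' attributions of feature j at pixel i, and the base value is
#' \eqn{\varphi_0 = \tau_0 + \nu \sum_k E[\tau_k]} (the model's expected
#' raw output under the empty coalition). All pixels -- labeled and
#' unlabeled -- are covered by default, so the explanation spans the whole
#' tissue.
#'
#' @param ens a \linkS4class{TreeEnsemble}.
#' @param ds an \linkS4class{IMSDataset} with matching feature count.
#' @param pixels optional 1-based pixel indices to cover (default: all).
#' @return a \linkS4class{ShapleyMatrix}.
#' @export
ensembleShapley <- function(ens, ds, pixels = NULL) {
  stopifnot(is(ens, "TreeEnsemble"), is(ds, "IMSDataset"))
  if (nFeatures(ens) != nFeatures(ds))
    stop("ensemble expects ", nFeatures(ens), " features; dataset has ",
         nFeatures(ds))
  if (is.null(pixels)) pixels <- seq_len(nPixels(ds))
  X <- intensityMatrix(ds)[pixels, , drop = FALSE]
  if (length(trees(ens)) == 0L) {
    vals <- matrix(0, nrow(X), ncol(X))
    phi0 <- basePrediction(ens)
  } else {
    vals <- learningRate(ens) * cpp_ensemble_shapley(trees(ens), X)
    phi0 <- basePrediction(ens) + learningRate(ens) *
      sum(vapply(trees(ens), cpp_tree_mean, numeric(1)))
  }
  new("ShapleyMatrix", baseValue = phi0, values = vals,
      pixelIndices = as.integer(pixels))
}

#' Verify local accuracy of a Shapley matrix
#'
#' For every covered pixel, the base value plus the row sum of the
#' attributions must reconstruct the ensemble's raw log-odds output.
#'
#' @param sm a \linkS4class{ShapleyMatrix}.
#' @param ens the explained \linkS4class{TreeEnsemble}.
#' @param ds the explained \linkS4class{IMSDataset}.
#' @param tol flagging tolerance (default 1e-6).
#' @return list with \code{maxDeviation}, \code{offendingPixels} (dataset
#'   indices with deviation above \code{tol}) and \code{ok}.
#' @export
checkLocalAccuracy <- function(sm, ens, ds, tol = 1e-6) {
  stopifnot(is(sm, "ShapleyMatrix"))
  if (ncol(shapValues(sm)) != nFeatures(ds))
    stop("Shapley matrix and dataset are misaligned")
  X <- intensityMatrix(ds)[pixelIndices(sm), , drop = FALSE]
  raw <- predictRaw(ens, X)
  dev <- abs(baseValue(sm) + rowSums(shapValues(sm)) - raw)
  bad <- pixelIndices(sm)[dev > tol]
  list(maxDeviation = max(dev), offendingPixels = bad, ok = length(bad) == 0L)
}

#' Global SHAP scores
#'
#' The global score of feature j is the mean absolute Shapley value of j
#' over the covered pixels -- an experiment-wide measure of the feature's
#' predictive importance.
#'
#' @param sm a \linkS4class{ShapleyMatrix}.
#' @return numeric vector of non-negative scores, one per feature.
#' @export
globalShapScores <- function(sm) {
  v <- shapValues(sm)
  if (nrow(v) == 0L) stop("empty Shapley matrix")
  colMeans(abs(v))
}

#' Rank features by global SHAP score
#'
#' Descending score; ties broken by ascending m/z.
#'
#' @param scores global SHAP scores from [globalShapScores()].
#' @param mzValues m/z value per feature (same length).
#' @return data.frame with columns \code{rank}, \code{featureIndex}
#'   (1-based), \code{mz}, \code{globalScore}.
#' @export
rankFeatures <- function(scores, mzValues) {
  if (length(scores) != length(mzValues))
    stop("scores and mzValues differ in length")
  ord <- order(-scores, mzValues)
  data.frame(rank = seq_along(ord), featureIndex = ord,
             mz = mzValues[ord], globalScore = scores[ord])
}

#' Write a Shapley matrix export
#'
#' A delimited pixels x features matrix preceded by a one-line header
#' carrying the base value.
#'
#' @param sm a \linkS4class{ShapleyMatrix}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeShapleyMatrix <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("phi0,%s", .fmt_num(baseValue(sm))), con)
  writeLines(paste0("pixel,", paste0("f", seq_len(ncol(shapValues(sm))),
                                     collapse = ",")), con)
  v <- shapValues(sm)
  writeLines(paste(pixelIndices(sm),
                   apply(v, 1L, function(r) paste(.fmt_num(r), collapse = ",")),
                   sep = ","), con)
  invisible(path)
}

#' Write a feature ranking CSV
#'
#' @param ranking data.frame from [rankFeatures()].
#' @param path output file.
#' @param digits significant digits for the scores (fixed so reruns are
#'   byte-identical).
#' @return the path, invisibly.
#' @export
writeRanking <- function(ranking, path, digits = 12) {
  df <- data.frame(rank = ranking$rank,
                   feature_index = ranking$featureIndex,
                   mz = ranking$mz,
                   global_shap_score = signif(ranking$globalScore, digits))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
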
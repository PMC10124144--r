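#' @include boosting.R
NULL

# JSON tree schema (also the accepted import schema):
# {base_prediction, learning_rate, n_features,
#  trees: [{nodes: [{id, is_leaf, feature, threshold, left, right,
#                    value, cover}]}]}
# ids, feature indices and child ids are 0-based; routing is
# x[feature] <= threshold to `left`. Every node must carry `cover`.

#' Export a tree ensemble as JSON
#'
#' @param ens a \linkS4class{TreeEnsemble}.
#' @param path output file.
#' @return the path, invisibly.
#' @seealso [importEnsemble()]
#' @export
exportEnsemble <- function(ens, path) {
  stopifnot(is(ens, "TreeEnsemble"))
  treeRecs <- lapply(trees(ens), function(tr) {
    leaf <- tr[, 1L] < 0
    list(nodes = data.frame(
      id = seq_len(nrow(tr)) - 1L,
      is_leaf = leaf,
      feature = ifelse(leaf, NA_integer_, as.integer(tr[, 1L]) - 1L),
      threshold = ifelse(leaf, NA_real_, tr[, 2L]),
      left = ifelse(leaf, NA_integer_, as.integer(tr[, 3L]) - 1L),
      right = ifelse(leaf, NA_integer_, as.integer(tr[, 4L]) - 1L),
      value = ifelse(leaf, tr[, 5L], NA_real_),
      cover = tr[, 6L]
    ))
  })
  obj <- list(base_prediction = basePrediction(ens),
              learning_rate = learningRate(ens),
              n_features = nFeatures(ens),
              trees = treeRecs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

.nodes_to_matrix <- function(nodes) {
  ids <- vapply(nodes, function(nd) as.integer(nd$id), integer(1))
  if (!setequal(ids, seq_along(nodes) - 1L))
    stop("tree schema mismatch: node ids must be 0..k-1")
  nodes <- nodes[order(ids)]
  k <- length(nodes)
  tr <- matrix(NA_real_, k, 6L)
  colnames(tr) <- c("feature", "threshold", "left", "right", "value", "cover")
  for (i in seq_len(k)) {
    nd <- nodes[[i]]
    if (is.null(nd$cover))
      stop("cover required for observational Shapley values")
    isLeaf <- isTRUE(nd$is_leaf)
    if (isLeaf) {
      if (is.null(nd$value)) stop("tree schema mismatch: leaf without value")
      tr[i, ] <- c(-1, NA_real_, -1, -1, as.numeric(nd$value),
                   as.numeric(nd$cover))
    } else {
      if (is.null(nd$feature) || is.null(nd$threshold) ||
          is.null(nd$left) || is.null(nd$right))
        stop("tree schema mismatch: internal node missing fields")
      tr[i, ] <- c(as.numeric(nd$feature) + 1, as.numeric(nd$threshold),
                   as.numeric(nd$left) + 1, as.numeric(nd$right) + 1,
                   NA_real_, as.numeric(nd$cover))
    }
  }
  tr[is.na(tr[, 5L]) & tr[, 1L] > 0, 5L] <- 0
  tr
}

#' Import a JSON tree ensemble
#'
#' Reads the documented JSON tree schema (the format written by
#' [exportEnsemble()]). Every node must carry a \code{cover} field: the
#' cover weights define the observational (tree-path-dependent) Shapley
#' expectations, so an ensemble without them cannot be explained.
#'
#' @param path JSON file, or a JSON string.
#' @return a \linkS4class{TreeEnsemble}.
#' @export
importEnsemble <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("base_prediction", "learning_rate", "n_features", "trees"))
    if (is.null(obj[[f]])) stop("ensemble schema mismatch: missing ", f)
  treeList <- lapply(obj$trees, function(t) .nodes_to_matrix(t$nodes))
  new("TreeEnsemble",
      basePrediction = as.numeric(obj$base_prediction),
      learningRate = as.numeric(obj$learning_rate),
      trees = treeList,
      nFeatures = as.integer(obj$n_features))
}

# Round a double to the nearest float32-representable value.
.f32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}

# The largest float32 strictly below x (x a positive/negative float32).
.f32_prev <- function(x) {
  b <- readBin(writeBin(as.numeric(.f32(x)), raw(), size = 4L), "integer",
               n = 1L, size = 4L)
  b <- if (x > 0) b - 1L else if (x < 0) b + 1L else -2147483647L - 1L # -0 -> smallest denormal step
  readBin(writeBin(b, raw(), size = 4L), "numeric", n = 1L, size = 4L)
}

.xgb_node_to_rows <- function(node, env) {
  i <- length(env$rows) + 1L
  env$rows[[i]] <- rep(NA_real_, 6L) # reserve the slot; filled below
  if (is.null(node$cover))
    stop("cover required for observational Shapley values")
  if (!is.null(node$leaf)) {
    env$rows[[i]] <- c(-1, NA_real_, -1, -1, as.numeric(node$leaf),
                       as.numeric(node$cover))
    return(i)
  }
  f <- as.integer(sub("^f", "", node$split)) + 1L
  kids <- node$children
  kid_id <- vapply(kids, function(k) as.integer(k$nodeid), integer(1))
  li <- .xgb_node_to_rows(kids[[match(node$yes, kid_id)]], env)
  ri <- .xgb_node_to_rows(kids[[match(node$no, kid_id)]], env)
  # xgboost routes x < threshold (float32) to the yes branch; this package
  # routes x <= threshold left. Snapping the parsed threshold to float32
  # and stepping one float32 ulp down makes the two rules identical for
  # every float32-representable input.
  thr <- .f32_prev(as.numeric(node$split_condition))
  env$rows[[i]] <- c(f, thr, li, ri, NA_real_, as.numeric(node$cover))
  i
}

#' Convert an xgboost JSON dump into a TreeEnsemble
#'
#' Parses the output of \code{xgboost::xgb.dump(booster, dump_format =
#' "json", with_stats = TRUE)}. Dumped leaf values already include the
#' learning rate, so the returned ensemble uses a learning rate of 1;
#' covers are xgboost's hessian-sum node statistics. xgboost routes
#' \code{x < threshold} to the yes-branch while this package routes
#' \code{x <= threshold} left, so raw outputs match except for inputs that
#' hit a threshold exactly.
#'
#' @param dump character: the JSON dump (possibly split across lines).
#' @param nFeatures number of model features.
#' @param baseMargin the booster's bias on the margin scale (0 for a
#'   binary:logistic model trained with \code{base_score = 0.5}).
#' @return a \linkS4class{TreeEnsemble}.
#' @export
fromXGBoostDump <- function(dump, nFeatures, baseMargin = 0) {
  obj <- jsonlite::fromJSON(paste(dump, collapse = "\n"),
                            simplifyVector = FALSE)
  treeList <- lapply(obj, function(root) {
    env <- new.env()
    env$rows <- list()
    .xgb_node_to_rows(root, env)
    tr <- do.call(rbind, env$rows)
    colnames(tr) <- c("feature", "threshold", "left", "right", "value",
                      "cover")
    tr
  })
  new("TreeEnsemble", basePrediction = as.numeric(baseMargin),
      learningRate = 1.0, trees = treeList,
      nFeatures = as.integer(nFeatures))
}
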
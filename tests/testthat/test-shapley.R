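test_that("tree expectations condition on coalition features only", {
  tr <- depth2_tree()
  x <- c(0.2, 0.8) # routes left at feature 1, right at feature 2

  # fully conditioned: the leaf x routes to (left subtree, right leaf = 2)
  expect_equal(treeExpectation(tr, x, 1:2), 2)
  # empty coalition: cover-weighted mean of all leaves
  expect_equal(treeExpectation(tr, x, integer(0)),
               (40 * 1 + 20 * 2 + 10 * 3 + 30 * 4) / 100)
  # S = {feature 1}: route left, then mix leaves 1 and 2 by cover
  expect_equal(treeExpectation(tr, x, 1L), (40 * 1 + 20 * 2) / 60)
  # S = {feature 2}: mix the two subtrees, following feature 2 inside each
  expect_equal(treeExpectation(tr, x, 2L), (60 * 2 + 40 * 4) / 100)
})

test_that("stump and single-leaf attributions have closed forms", {
  expect_equal(treeShapleySubsets(leaf_tree(), c(1, 2)), c(0, 0))
  expect_equal(treeShapleyPath(leaf_tree(), c(1, 2)), c(0, 0))

  st <- stump_tree(leftValue = -1, rightValue = 1,
                   leftCover = 30, rightCover = 70)
  mean_leaf <- (30 * -1 + 70 * 1) / 100
  for (fn in list(treeShapleySubsets, treeShapleyOrderings,
                  treeShapleyPath)) {
    expect_equal(fn(st, c(3.0)), 1 - mean_leaf)
    expect_equal(fn(st, c(2.0)), -1 - mean_leaf)
  }
})

test_that("the three Shapley routes agree on the depth-2 reference tree", {
  tr <- depth2_tree()
  for (x in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    s <- treeShapleySubsets(tr, x)
    expect_lt(max(abs(treeShapleyOrderings(tr, x) - s)), 1e-12)
    expect_lt(max(abs(treeShapleyPath(tr, x) - s)), 1e-9)
    # local accuracy per tree: attributions bridge E(all) and E(empty)
    expect_equal(sum(s), treeExpectation(tr, x, 1:2) -
                   treeExpectation(tr, x, integer(0)))
  }
})

test_that("path algorithm matches the subset oracle on random trees", {
  set.seed(101)
  worst <- 0
  for (r in 1:60) {
    tr <- random_cover_tree(maxDepth = 5, nFeatures = 10)
    for (s in 1:5) {
      x <- rnorm(10)
      worst <- max(worst, max(abs(treeShapleyPath(tr, x) -
                                  treeShapleySubsets(tr, x))))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("ordering enumeration matches the subset oracle", {
  set.seed(102)
  worst <- 0
  for (r in 1:40) {
    tr <- random_cover_tree(maxDepth = 3, nFeatures = 5)
    x <- rnorm(5)
    worst <- max(worst, max(abs(treeShapleyOrderings(tr, x) -
                                treeShapleySubsets(tr, x))))
  }
  expect_lt(worst, 1e-12)
})

test_that("oracles refuse infeasible feature counts", {
  set.seed(103)
  # a chain tree over 16 distinct features
  deep <- local({
    nodes <- list()
    build <- function(f, cover) {
      i <- length(nodes) + 1L
      nodes[[i]] <<- NA
      if (f > 16L) {
        nodes[[i]] <<- c(-1, NA, -1, -1, rnorm(1), cover)
        return(i)
      }
      li <- build(f + 1L, cover / 2)
      ri <- length(nodes) + 1L
      nodes[[ri]] <<- c(-1, NA, -1, -1, rnorm(1), cover / 2)
      nodes[[i]] <<- c(f, 0, li, ri, NA, cover)
      i
    }
    build(1L, 2^17)
    do.call(rbind, nodes)
  })
  expect_error(treeShapleySubsets(deep, rnorm(16)), "15")
  expect_error(treeShapleyOrderings(deep, rnorm(16)), "8")
  # the path algorithm handles it and satisfies local accuracy
  phi <- treeShapleyPath(deep, rnorm(16))
  xx <- rnorm(16)
  expect_equal(sum(treeShapleyPath(deep, xx)),
               treeExpectation(deep, xx, 1:16) - treeExpectation(deep, xx),
               tolerance = 1e-9)
})

test_that("dummy features receive exactly zero attribution", {
  tr <- depth2_tree() # uses features 1 and 2 of a 5-feature input
  x <- c(0.3, 0.9, 5, -2, 7)
  for (fn in list(treeShapleySubsets, treeShapleyPath)) {
    phi <- fn(tr, x)
    expect_identical(phi[3:5], c(0, 0, 0))
  }
  fit <- phantom_fit(seed = 11, nTrees = 30L)
  used <- sort(unique(unlist(lapply(trees(fit$ens), treeUsedFeatures))))
  unused <- setdiff(seq_len(nFeatures(fit$ens)), used)
  if (length(unused)) {
    sm <- ensembleShapley(fit$ens, fit$phantom$dataset,
                          pixels = seq(1, 1024, by = 7))
    expect_true(all(shapValues(sm)[, unused] == 0))
  }
})

test_that("structurally interchangeable features get equal attributions", {
  tr <- symmetric_tree()
  for (x in list(c(-1, -1), c(1, 1))) {
    phi <- treeShapleyPath(tr, x)
    expect_lt(abs(phi[1L] - phi[2L]), 1e-9)
    phiS <- treeShapleySubsets(tr, x)
    expect_lt(abs(phiS[1L] - phiS[2L]), 1e-12)
  }
})

test_that("ensemble attributions are the shrinkage-weighted per-tree sums", {
  fit <- phantom_fit(seed = 12, nTrees = 12L)
  ds <- fit$phantom$dataset
  pix <- c(1L, 500L, 1024L)
  sm <- ensembleShapley(fit$ens, ds, pixels = pix)
  X <- intensityMatrix(ds)
  for (i in seq_along(pix)) {
    manual <- Reduce(`+`, lapply(trees(fit$ens), function(tr)
      treeShapleySubsets(tr, X[pix[i], ])))
    expect_equal(shapValues(sm)[i, ], learningRate(fit$ens) * manual,
                 tolerance = 1e-9)
  }
})

test_that("local accuracy holds for trained ensembles and K = 0", {
  fit <- phantom_fit(seed = 13, nTrees = 50L)
  ds <- fit$phantom$dataset
  sm <- ensembleShapley(fit$ens, ds)
  la <- checkLocalAccuracy(sm, fit$ens, ds, tol = 1e-6)
  expect_true(la$ok)
  expect_lt(la$maxDeviation, 1e-6)

  # detector flags a perturbed entry
  smBad <- new("ShapleyMatrix", baseValue = baseValue(sm),
               values = `[<-`(shapValues(sm), 7L, 3L,
                              shapValues(sm)[7L, 3L] + 0.01),
               pixelIndices = pixelIndices(sm))
  laBad <- checkLocalAccuracy(smBad, fit$ens, ds, tol = 1e-6)
  expect_false(laBad$ok)
  expect_equal(laBad$offendingPixels, 7L)

  ens0 <- new("TreeEnsemble", basePrediction = 1.5, learningRate = 0.3,
              trees = list(), nFeatures = nFeatures(ds))
  sm0 <- ensembleShapley(ens0, ds)
  expect_true(all(shapValues(sm0) == 0))
  expect_equal(baseValue(sm0), 1.5)
  expect_equal(checkLocalAccuracy(sm0, ens0, ds)$maxDeviation, 0)

  badEns <- new("TreeEnsemble", basePrediction = 0, learningRate = 0.3,
                trees = list(), nFeatures = 3L)
  expect_error(ensembleShapley(badEns, ds), "features")
})

test_that("global scores are mean absolute attributions", {
  sm <- new("ShapleyMatrix", baseValue = 0,
            values = cbind(c(0.5, -1.5, 1.0), c(0, 0, 0)),
            pixelIndices = 1:3)
  gs <- globalShapScores(sm)
  expect_equal(gs, c(1.0, 0))
  sm2 <- new("ShapleyMatrix", baseValue = 0, values = 2 * shapValues(sm),
             pixelIndices = 1:3)
  expect_equal(globalShapScores(sm2), 2 * gs)
})

test_that("feature ranking is by descending score with m/z tie-break", {
  r <- rankFeatures(c(0.2, 1.0, 0.2), c(300.0, 400.0, 350.0))
  expect_equal(r$featureIndex, c(2L, 1L, 3L))
  expect_equal(r$rank, 1:3)
  expect_equal(r$mz, c(400, 300, 350))

  r2 <- rankFeatures(c(0.5, 0.5, 0.5), c(320, 310, 330))
  expect_equal(r2$mz, c(310, 320, 330))

  # permutation invariance of the (mz, score) sequence
  sc <- c(0.9, 0.1, 0.4, 0.4); mz <- c(500, 410, 430, 420)
  perm <- c(3L, 1L, 4L, 2L)
  a <- rankFeatures(sc, mz)[, c("mz", "globalScore")]
  b <- rankFeatures(sc[perm], mz[perm])[, c("mz", "globalScore")]
  expect_equal(a, b, ignore_attr = TRUE)
  expect_error(rankFeatures(c(1, 2), c(100, 200, 300)), "length")
})

test_that("attributions agree with the established TreeSHAP implementation", {
  library(xgboost)
  ph <- generatePhantom(twoRegionPhantomConfig(seed = 21))
  X <- round_f32(intensityMatrix(ph$dataset))
  ds <- IMSDataset(X, pixelCoords(ph$dataset), mzValues(ph$dataset))
  ls <- makeLabels(ph$masks$A)
  bst <- xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                  base_score = 0.5, lambda = 1),
    data = xgb.DMatrix(X[ls$pixelIndices, ],
                       label = as.integer(ls$labels == 1)),
    nrounds = 20)
  ens <- fromXGBoostDump(xgb.dump(bst, dump_format = "json",
                                  with_stats = TRUE), ncol(X))
  idx <- as.integer(seq(1, nrow(X), length.out = 100L))
  ref <- predict(bst, X[idx, ], predcontrib = TRUE)
  sm <- ensembleShapley(ens, ds, pixels = idx)
  expect_lt(max(abs(ref[, seq_len(ncol(X))] - shapValues(sm))), 1e-4)
  expect_lt(abs(ref[1L, ncol(X) + 1L] - baseValue(sm)), 1e-4)
})

test_that("Shapley matrix export carries the base value header", {
  d <- withr::local_tempdir()
  sm <- new("ShapleyMatrix", baseValue = -0.25,
            values = matrix(c(0.1, -0.2, 0, 0.5), 2, 2),
            pixelIndices = c(1L, 2L))
  p <- writeShapleyMatrix(sm, file.path(d, "sm.csv"))
  lines <- readLines(p)
  expect_match(lines[1L], "^phi0,-0.25")
  expect_length(lines, 4L)
})
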
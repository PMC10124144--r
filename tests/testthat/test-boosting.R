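test_that("masks map to one-vs-all labels and EXCLUDED pixels are dropped", {
  m <- AnnotationMask("organ", c("POS", "NEG", "EXCLUDED", "NEG"))
  ls <- makeLabels(m)
  expect_equal(ls$pixelIndices, c(1L, 2L, 4L))
  expect_equal(ls$labels, c(1L, -1L, -1L))

  m2 <- AnnotationMask("organ", c(rep("POS", 3), rep("NEG", 5),
                                  rep("EXCLUDED", 2)))
  expect_length(makeLabels(m2)$labels, 8L)

  expect_error(makeLabels(AnnotationMask("organ", rep("POS", 4))), "NEG")
})

test_that("negative downsampling hits the target class balance", {
  ls <- labeledSubset(1:100, c(rep(1L, 10), rep(-1L, 90)))
  out <- downsampleNegatives(ls, 0.25, seed = 3)
  expect_equal(sum(out$labels == 1L), 10L)
  expect_equal(sum(out$labels == -1L), 30L)
  expect_true(all(out$pixelIndices[out$labels == 1L] %in% 1:10))

  short <- labeledSubset(1:30, c(rep(1L, 10), rep(-1L, 20)))
  expect_warning(kept <- downsampleNegatives(short, 0.25, seed = 3),
                 "keeping all")
  expect_equal(sum(kept$labels == -1L), 20L)

  expect_identical(downsampleNegatives(ls, 0.25, seed = 9)$pixelIndices,
                   downsampleNegatives(ls, 0.25, seed = 9)$pixelIndices)
  expect_error(downsampleNegatives(ls, 1.2), "posFraction")
})

test_that("holdout split is stratified, exhaustive and seeded", {
  ls <- labeledSubset(1:16, rep(c(1L, -1L), each = 8))
  sp <- splitHoldout(ls, 0.25, seed = 4)
  expect_equal(sum(sp$test$labels == 1L), 2L)
  expect_equal(sum(sp$test$labels == -1L), 2L)
  expect_setequal(c(sp$train$pixelIndices, sp$test$pixelIndices), 1:16)
  expect_length(intersect(sp$train$pixelIndices, sp$test$pixelIndices), 0L)
  sp2 <- splitHoldout(ls, 0.25, seed = 4)
  expect_identical(sp$test$pixelIndices, sp2$test$pixelIndices)
  expect_error(splitHoldout(labeledSubset(1:3, c(1L, -1L, -1L)), 0.25),
               "at least 2")
})

test_that("K = 0 yields the base-rate log-odds everywhere", {
  ds <- tiny_dataset()
  ls <- labeledSubset(1:4, c(1L, -1L, -1L, -1L))
  ens <- trainEnsemble(ds, ls, trainingConfig(nTrees = 0L))
  expect_equal(basePrediction(ens), log(1 / 3))
  expect_equal(predictRaw(ens, intensityMatrix(ds)),
               rep(log(1 / 3), 4))
})

test_that("a perfectly separating feature is learned to perfection", {
  set.seed(8)
  m <- 60L
  X <- cbind(c(runif(m / 2, 6, 9), runif(m / 2, 1, 4)),
             matrix(runif(m * 3), m, 3))
  y <- c(rep(1L, m / 2), rep(-1L, m / 2)) # POS iff x1 > 5
  ds <- IMSDataset(X, cbind(0:(m - 1), rep(0L, m)), c(1, 2, 3, 4) * 100)
  ls <- labeledSubset(1:m, y)
  ens <- trainEnsemble(ds, ls, trainingConfig(
    nTrees = 10L, maxDepth = 1L, rowSubsample = 1, colSubsample = 1,
    seed = 1))
  met <- evaluateClassifier(predictClass(ens, X), y)
  expect_equal(met$balancedAccuracy, 1.0)
  # only the separating feature should be split on
  expect_setequal(unique(unlist(lapply(trees(ens), treeUsedFeatures))), 1L)
})

test_that("cover is conserved at every internal node of trained trees", {
  fit <- phantom_fit(seed = 2, nTrees = 20L)
  for (tr in trees(fit$ens)) {
    internal <- which(tr[, 1L] > 0)
    for (i in internal) {
      expect_equal(unname(tr[i, 6L]), unname(tr[tr[i, 3L], 6L] + tr[tr[i, 4L], 6L]))
    }
    # root cover equals the full training-set size, not the subsample
    expect_equal(unname(tr[1L, 6L]), length(fit$split$train$labels))
  }
})

test_that("training loss is non-increasing without subsampling", {
  ph <- generatePhantom(twoRegionPhantomConfig(seed = 4))
  ls <- makeLabels(ph$masks$A)
  cfg <- trainingConfig(nTrees = 25L, rowSubsample = 1, colSubsample = 1,
                        seed = 1)
  ens <- trainEnsemble(ph$dataset, ls, cfg)
  X <- intensityMatrix(ph$dataset)[ls$pixelIndices, ]
  t <- (ls$labels + 1L) / 2
  loss_at <- function(k) {
    part <- new("TreeEnsemble", basePrediction = basePrediction(ens),
                learningRate = learningRate(ens),
                trees = trees(ens)[seq_len(k)],
                nFeatures = nFeatures(ens))
    p <- predictProbability(part, X)
    -mean(t * log(p) + (1 - t) * log(1 - p))
  }
  losses <- vapply(0:25, loss_at, numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("raw prediction follows the additive log-odds form", {
  # empty tree list
  ens0 <- new("TreeEnsemble", basePrediction = 0.4, learningRate = 0.5,
              trees = list(), nFeatures = 1L)
  expect_equal(predictRaw(ens0, 3), 0.4)
  # two stumps, each +1 for x > 2.5, nu = 0.5, tau0 = 0
  st <- stump_tree()
  ens <- new("TreeEnsemble", basePrediction = 0, learningRate = 0.5,
             trees = list(st, st), nFeatures = 1L)
  expect_equal(predictRaw(ens, 3.0), 1.0)
  # routing at equality goes LEFT
  ens1 <- new("TreeEnsemble", basePrediction = 0, learningRate = 1,
              trees = list(st), nFeatures = 1L)
  expect_equal(predictRaw(ens1, 2.5), -1.0)
  expect_error(predictRaw(ens1, c(1, 2)), "features")
  expect_error(predictRaw(ens1, NaN), "non-finite")
})

test_that("probabilities and class calls follow the sigmoid and threshold", {
  mk <- function(tau0) new("TreeEnsemble", basePrediction = tau0,
                           learningRate = 0.3, trees = list(),
                           nFeatures = 1L)
  expect_equal(predictProbability(mk(0), 1), 0.5)
  expect_equal(predictProbability(mk(log(3)), 1), 0.75)
  expect_equal(predictProbability(mk(-log(3)), 1), 0.25)
  # tie at eta goes positive
  expect_equal(predictClass(mk(0), 1, eta = 0.5), 1L)
  expect_equal(predictClass(mk(log(0.49 / 0.51)), 1, eta = 0.5), -1L)
  expect_equal(predictClass(mk(log(9)), 1, eta = 0.95), -1L)
  expect_error(predictClass(mk(0), 1, eta = 1), "eta")
  # monotone in eta: raising eta never flips -1 to +1
  fit <- phantom_fit(seed = 3, nTrees = 15L)
  X <- intensityMatrix(fit$phantom$dataset)
  etas <- c(0.2, 0.4, 0.6, 0.8)
  calls <- vapply(etas, function(e) predictClass(fit$ens, X, e),
                  integer(nrow(X)))
  for (j in seq_len(ncol(calls) - 1L))
    expect_true(all(calls[, j] >= calls[, j + 1L]))
})

test_that("classification metrics handle defined and undefined rates", {
  met <- evaluateClassifier(c(1, 1, 1, -1, -1, -1),
                            c(1, 1, -1, -1, -1, -1))
  expect_equal(met$TP, 2L); expect_equal(met$FP, 1L)
  expect_equal(met$TN, 3L); expect_equal(met$FN, 0L)
  expect_equal(met$recall, 1.0)
  expect_equal(met$specificity, 0.75)
  expect_equal(met$balancedAccuracy, 0.875)
  expect_equal(met$precision, 2 / 3)

  allneg <- evaluateClassifier(rep(-1, 5), rep(-1, 5))
  expect_true(is.na(allneg$recall))
  expect_true(is.na(allneg$balancedAccuracy))

  perfect <- evaluateClassifier(c(1, -1, 1), c(1, -1, 1))
  expect_equal(unlist(perfect[c("precision", "recall", "specificity",
                                "balancedAccuracy")]),
               c(precision = 1, recall = 1, specificity = 1,
                 balancedAccuracy = 1))
  expect_error(evaluateClassifier(c(1, -1), c(1, -1, 1)), "length")
  expect_error(evaluateClassifier(c(1, 0), c(1, -1)), "labels")
})

test_that("prediction maps recover the positive region", {
  fit <- phantom_fit(seed = 5, nTrees = 60L)
  img <- predictionImage(fit$ens, fit$phantom$dataset)
  expect_identical(dim(img), dim(ionImage(fit$phantom$dataset, 1L)))
  pred_pos <- which(imageToValues(img, fit$phantom$dataset) == 1)
  true_pos <- which(fit$phantom$groundTruth$membership == 1L)
  jacc <- length(intersect(pred_pos, true_pos)) /
    length(union(pred_pos, true_pos))
  expect_gte(jacc, 0.95)

  # constant positive ensemble predicts +1 everywhere
  cens <- new("TreeEnsemble", basePrediction = 2, learningRate = 0.3,
              trees = list(), nFeatures = nFeatures(fit$phantom$dataset))
  img2 <- predictionImage(cens, fit$phantom$dataset)
  expect_true(all(imageValues(img2) == 1, na.rm = TRUE))
})

test_that("JSON export/import round-trips ensembles exactly", {
  d <- withr::local_tempdir()
  fit <- phantom_fit(seed = 6, nTrees = 10L)
  p <- exportEnsemble(fit$ens, file.path(d, "ens.json"))
  ens2 <- importEnsemble(p)
  X <- intensityMatrix(fit$phantom$dataset)[1:50, ]
  expect_equal(predictRaw(ens2, X), predictRaw(fit$ens, X), tolerance = 1e-12)
  expect_equal(length(trees(ens2)), length(trees(fit$ens)))
})

test_that("the import schema is validated and reads stumps directly", {
  js <- '{"base_prediction": 0, "learning_rate": 1, "n_features": 1,
          "trees": [{"nodes": [
            {"id":0,"is_leaf":false,"feature":0,"threshold":2.5,
             "left":1,"right":2,"cover":100},
            {"id":1,"is_leaf":true,"value":-1.0,"cover":40},
            {"id":2,"is_leaf":true,"value":1.0,"cover":60}]}]}'
  ens <- importEnsemble(js)
  expect_equal(predictRaw(ens, 3.0), 1.0)
  expect_equal(predictRaw(ens, 2.0), -1.0)

  noCover <- '{"base_prediction": 0, "learning_rate": 1, "n_features": 1,
               "trees": [{"nodes": [{"id":0,"is_leaf":true,"value":1}]}]}'
  expect_error(importEnsemble(noCover), "cover required")
  expect_error(importEnsemble('{"trees": []}'), "schema mismatch")
})

test_that("imported external boosters reproduce the external margins", {
  library(xgboost)
  ph <- generatePhantom(twoRegionPhantomConfig(seed = 9))
  X <- round_f32(intensityMatrix(ph$dataset))
  ls <- makeLabels(ph$masks$A)
  bst <- xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                  base_score = 0.5, lambda = 1),
    data = xgb.DMatrix(X[ls$pixelIndices, ], label = as.integer(ls$labels == 1)),
    nrounds = 20)
  ens <- fromXGBoostDump(xgb.dump(bst, dump_format = "json",
                                  with_stats = TRUE), ncol(X))
  idx <- as.integer(seq(1L, nrow(X), length.out = 100L))
  expect_lt(max(abs(predict(bst, X[idx, ], outputmargin = TRUE) -
                    predictRaw(ens, X[idx, ]))), 1e-6)
})

test_that("training is deterministic under a fixed seed", {
  ph <- generatePhantom(twoRegionPhantomConfig(seed = 1))
  ls <- makeLabels(ph$masks$A)
  cfg <- trainingConfig(nTrees = 8L, seed = 42)
  e1 <- trainEnsemble(ph$dataset, ls, cfg)
  e2 <- trainEnsemble(ph$dataset, ls, cfg)
  expect_identical(trees(e1), trees(e2))
})
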
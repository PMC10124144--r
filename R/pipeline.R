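#' @include shap_maps.R
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.read_kv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop("config line without '=': ", lines[which(eq < 0)[1L]])
  keys <- trimws(substr(lines, 1L, eq - 1L))
  vals <- trimws(substr(lines, eq + 1L, nchar(lines)))
  data.frame(key = keys, value = vals)
}

.kv_one <- function(kv, key, default = NULL, as = identity) {
  v <- kv$value[kv$key == key]
  if (length(v) == 0L) return(default)
  if (length(v) > 1L) stop("config key '", key, "' given more than once")
  as(v)
}

.parse_primitive <- function(tokens) {
  if (tokens[1L] == "rect") {
    stopifnot(length(tokens) == 5L)
    v <- as.numeric(tokens[2:5])
    rectRegion(v[1L], v[2L], v[3L], v[4L])
  } else if (tokens[1L] == "ellipse") {
    stopifnot(length(tokens) == 5L)
    v <- as.numeric(tokens[2:5])
    ellipseRegion(v[1L], v[2L], v[3L], v[4L])
  } else stop("unknown region primitive: ", tokens[1L])
}

#' Read a phantom configuration file
#'
#' Flat key/value schema (\code{key = value}, \code{#} comments, repeated
#' keys where noted): \code{grid_h}, \code{grid_w}, \code{n_features},
#' \code{baseline_log_mean}, \code{noise_sigma}, \code{seed};
#' repeatable \code{region = <name> rect r0 c0 r1 c1} (or
#' \code{ellipse cr cc rr rc}); repeatable
#' \code{marker = <feature> <region> UP|DOWN <effect>}; repeatable
#' \code{correlated = <a> <b> <rho>}; optional \code{artifact_region},
#' \code{artifact_bleed = rect ...}, \code{artifact_features} (space
#' separated), \code{artifact_fraction}.
#'
#' @param path config file.
#' @return a [phantomConfig()].
#' @export
readPhantomConfigFile <- function(path) {
  kv <- .read_kv(path)
  regLines <- kv$value[kv$key == "region"]
  if (length(regLines) == 0L) stop("phantom config needs at least one region")
  regions <- list()
  for (rl in regLines) {
    tok <- strsplit(rl, "\\s+")[[1L]]
    regions[[tok[1L]]] <- .parse_primitive(tok[-1L])
  }
  mkLines <- kv$value[kv$key == "marker"]
  markers <- do.call(rbind, lapply(mkLines, function(ml) {
    tok <- strsplit(ml, "\\s+")[[1L]]
    stopifnot(length(tok) == 4L)
    data.frame(feature = as.integer(tok[1L]), region = tok[2L],
               direction = tok[3L], effectSize = as.numeric(tok[4L]))
  }))
  cpLines <- kv$value[kv$key == "correlated"]
  correlated <- if (length(cpLines)) {
    do.call(rbind, lapply(cpLines, function(cl) {
      tok <- strsplit(cl, "\\s+")[[1L]]
      data.frame(a = as.integer(tok[1L]), b = as.integer(tok[2L]),
                 rho = as.numeric(tok[3L]))
    }))
  } else NULL
  artifact <- NULL
  aReg <- .kv_one(kv, "artifact_region")
  if (!is.null(aReg)) {
    artifact <- list(
      region = aReg,
      bleed = .parse_primitive(strsplit(.kv_one(kv, "artifact_bleed"),
                                        "\\s+")[[1L]]),
      features = as.integer(strsplit(.kv_one(kv, "artifact_features"),
                                     "\\s+")[[1L]]),
      fraction = .kv_one(kv, "artifact_fraction", as = as.numeric))
  }
  phantomConfig(
    gridH = .kv_one(kv, "grid_h", as = as.integer),
    gridW = .kv_one(kv, "grid_w", as = as.integer),
    regions = regions,
    nFeatures = .kv_one(kv, "n_features", as = as.integer),
    markers = markers,
    baselineLogMean = .kv_one(kv, "baseline_log_mean", 0, as.numeric),
    noiseSigma = .kv_one(kv, "noise_sigma", 0.3, as.numeric),
    correlatedPairs = correlated,
    artifact = artifact,
    seed = .kv_one(kv, "seed", 1L, as.integer))
}

#' Discovery pipeline configuration
#'
#' @param datasetDir dataset bundle directory (NULL when \code{phantom}
#'   is given).
#' @param maskFiles named character vector of mask files, one per class
#'   (names are class names); ignored when \code{phantom} is given.
#' @param phantom optional [phantomConfig()]: generate the inputs instead
#'   of loading them.
#' @param classes class name(s) to run one-versus-all.
#' @param training a [trainingConfig()]; its seed is overridden by the
#'   derived stage seed.
#' @param eta probability threshold (default 0.5).
#' @param posFraction positive share after negative downsampling
#'   (default 0.25).
#' @param testFraction held-out share (default 0.25).
#' @param scope explanation scope, \code{"all_pixels"} or
#'   \code{"labeled_only"}.
#' @param topK number of reported candidates (default 10).
#' @param directionThreshold direction-call threshold (default 0.3).
#' @param accuracyFloor minimum held-out balanced accuracy below which no
#'   ranking is written (default 0.8).
#' @param seed master seed; every stage seed is derived from it.
#' @param outDir output directory.
#' @return a validated \code{PipelineConfig} (list).
#' @export
pipelineConfig <- function(datasetDir = NULL, maskFiles = NULL,
                           phantom = NULL, classes,
                           training = trainingConfig(),
                           eta = 0.5, posFraction = 0.25,
                           testFraction = 0.25,
                           scope = c("all_pixels", "labeled_only"),
                           topK = 10L, directionThreshold = 0.3,
                           accuracyFloor = 0.8, seed = 1L, outDir) {
  scope <- match.arg(scope)
  stopifnot(eta > 0, eta < 1, posFraction > 0, posFraction < 1,
            testFraction > 0, testFraction < 1, topK >= 1)
  if (is.null(phantom)) {
    if (is.null(datasetDir) || !dir.exists(datasetDir))
      stop("dataset directory not found: ", datasetDir)
    if (is.null(maskFiles) || is.null(names(maskFiles)))
      stop("named mask files are required without a phantom")
    missing <- maskFiles[!file.exists(maskFiles)]
    if (length(missing)) stop("mask file not found: ", missing[1L])
    if (!all(classes %in% names(maskFiles)))
      stop("no mask for class: ",
           paste(setdiff(classes, names(maskFiles)), collapse = ", "))
  }
  structure(list(datasetDir = datasetDir, maskFiles = maskFiles,
                 phantom = phantom, classes = classes, training = training,
                 eta = eta, posFraction = posFraction,
                 testFraction = testFraction, scope = scope,
                 topK = as.integer(topK),
                 directionThreshold = directionThreshold,
                 accuracyFloor = accuracyFloor, seed = as.integer(seed),
                 outDir = outDir),
            class = "PipelineConfig")
}

#' Read a discovery pipeline configuration file
#'
#' Flat key/value schema: \code{dataset_dir} or \code{phantom_config}
#' (path to a [readPhantomConfigFile()] file) or \code{phantom = two_region
#' | artifact}; repeatable \code{mask = <class> <file>}; repeatable
#' \code{class = <name>}; \code{n_trees}, \code{max_depth},
#' \code{learning_rate}, \code{lambda}, \code{row_subsample},
#' \code{col_subsample}, \code{min_child_cover}; \code{eta},
#' \code{pos_fraction}, \code{test_fraction}, \code{scope}, \code{top_k},
#' \code{direction_threshold}, \code{accuracy_floor}, \code{seed},
#' \code{out_dir}.
#'
#' @param path config file.
#' @param seed optional master-seed override.
#' @param outDir optional output-directory override.
#' @return a [pipelineConfig()].
#' @export
readPipelineConfigFile <- function(path, seed = NULL, outDir = NULL) {
  kv <- .read_kv(path)
  seed <- if (!is.null(seed)) as.integer(seed)
          else .kv_one(kv, "seed", 1L, as.integer)
  phantom <- NULL
  ph <- .kv_one(kv, "phantom")
  phFile <- .kv_one(kv, "phantom_config")
  if (!is.null(phFile)) {
    phantom <- readPhantomConfigFile(phFile)
  } else if (!is.null(ph)) {
    phantom <- switch(ph,
      two_region = twoRegionPhantomConfig(seed = seed),
      artifact = artifactPhantomConfig(seed = seed),
      stop("unknown built-in phantom: ", ph))
  }
  maskFiles <- NULL
  mLines <- kv$value[kv$key == "mask"]
  if (length(mLines)) {
    parts <- strsplit(mLines, "\\s+")
    maskFiles <- vapply(parts, `[`, character(1), 2L)
    names(maskFiles) <- vapply(parts, `[`, character(1), 1L)
  }
  classes <- kv$value[kv$key == "class"]
  if (length(classes) == 0L) {
    classes <- if (!is.null(phantom)) names(phantom$regions)
               else names(maskFiles)
  }
  training <- trainingConfig(
    nTrees = .kv_one(kv, "n_trees", 100L, as.integer),
    maxDepth = .kv_one(kv, "max_depth", 4L, as.integer),
    learningRate = .kv_one(kv, "learning_rate", 0.3, as.numeric),
    lambda = .kv_one(kv, "lambda", 1, as.numeric),
    rowSubsample = .kv_one(kv, "row_subsample", 0.8, as.numeric),
    colSubsample = .kv_one(kv, "col_subsample", 0.8, as.numeric),
    minChildCover = .kv_one(kv, "min_child_cover", 5L, as.integer))
  pipelineConfig(
    datasetDir = .kv_one(kv, "dataset_dir"),
    maskFiles = maskFiles, phantom = phantom, classes = classes,
    training = training,
    eta = .kv_one(kv, "eta", 0.5, as.numeric),
    posFraction = .kv_one(kv, "pos_fraction", 0.25, as.numeric),
    testFraction = .kv_one(kv, "test_fraction", 0.25, as.numeric),
    scope = .kv_one(kv, "scope", "all_pixels"),
    topK = .kv_one(kv, "top_k", 10L, as.integer),
    directionThreshold = .kv_one(kv, "direction_threshold", 0.3, as.numeric),
    accuracyFloor = .kv_one(kv, "accuracy_floor", 0.8, as.numeric),
    seed = seed,
    outDir = if (!is.null(outDir)) outDir
             else .kv_one(kv, "out_dir", "shapmsi_out"))
}

.metrics_json <- function(metrics, path) {
  jsonlite::write_json(
    lapply(unclass(metrics), function(v) if (is.na(v)) NULL else signif(v, 12)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run the discovery workflow for one class
#'
#' Executes the full chain: load (or generate) the dataset and mask,
#' build one-versus-all labels, downsample negatives, split a stratified
#' holdout, train the boosted ensemble, evaluate on the holdout, explain
#' every pixel with observational Shapley values, rank features by global
#' SHAP score, and write the top-k report. If the held-out balanced
#' accuracy is below the configured floor, no ranking is written (an
#' explanation is only as good as its underlying model) and a warning
#' artifact is emitted instead. Deterministic given the master seed:
#' stage seeds are derived from it, and rerunning with an identical
#' configuration reproduces every artifact byte for byte.
#'
#' @param cfg a [pipelineConfig()].
#' @param class class to run (default: first configured class).
#' @return the run manifest (list), invisibly.
#' @export
runDiscovery <- function(cfg, class = cfg$classes[1L]) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  outDir <- file.path(cfg$outDir, class)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- list(class = class, seed = cfg$seed,
              stage_seeds = list(downsample = .derive_seed(cfg$seed, 1L),
                                 split = .derive_seed(cfg$seed, 2L),
                                 train = .derive_seed(cfg$seed, 3L)),
              parameters = c(unclass(cfg$training),
                             list(eta = cfg$eta,
                                  pos_fraction = cfg$posFraction,
                                  test_fraction = cfg$testFraction,
                                  scope = cfg$scope, top_k = cfg$topK,
                                  direction_threshold = cfg$directionThreshold,
                                  accuracy_floor = cfg$accuracyFloor)))
  if (!is.null(cfg$phantom)) {
    ph <- .stage("generatePhantom", generatePhantom(cfg$phantom))
    ds <- ph$dataset
    mask <- .stage("regionMask", {
      if (!class %in% names(ph$masks)) stop("unknown region: ", class)
      ph$masks[[class]]
    })
  } else {
    ds <- .stage("loadDataset", loadDataset(cfg$datasetDir))
    mask <- .stage("loadMask",
                   loadMask(cfg$maskFiles[[class]], ds, className = class))
  }
  log$data_shape <- c(pixels = nPixels(ds), features = nFeatures(ds))

  ls0 <- .stage("makeLabels", makeLabels(mask))
  lsb <- .stage("downsampleNegatives",
                downsampleNegatives(ls0, cfg$posFraction,
                                    log$stage_seeds$downsample))
  sp <- .stage("splitHoldout",
               splitHoldout(lsb, cfg$testFraction, log$stage_seeds$split))
  log$training_shape <- c(train = length(sp$train$labels),
                          test = length(sp$test$labels),
                          positives = sum(sp$train$labels == 1L))
  tc <- cfg$training
  tc$seed <- log$stage_seeds$train
  ens <- .stage("trainEnsemble", trainEnsemble(ds, sp$train, tc))
  exportEnsemble(ens, file.path(outDir, "model.json"))

  Xtest <- intensityMatrix(ds)[sp$test$pixelIndices, , drop = FALSE]
  metrics <- .stage("evaluate",
                    evaluateClassifier(predictClass(ens, Xtest, cfg$eta),
                                       sp$test$labels))
  .metrics_json(metrics, file.path(outDir, "metrics.json"))
  predMap <- .stage("predictionImage", predictionImage(ens, ds, cfg$eta))
  writeImage(predMap, file.path(outDir, "prediction_map.csv"))
  renderDiverging(predMap, file.path(outDir, "prediction_map.png"))

  manifest <- list(class = class, out_dir = outDir,
                   files = c("model.json", "metrics.json",
                             "prediction_map.csv", "prediction_map.png"),
                   metrics = unclass(metrics))
  ba <- metrics$balancedAccuracy
  if (is.na(ba) || ba < cfg$accuracyFloor) {
    jsonlite::write_json(
      list(warning = "held-out balanced accuracy below the model-quality floor; ranking withheld",
           balanced_accuracy = ba, floor = cfg$accuracyFloor),
      file.path(outDir, "quality_warning.json"), auto_unbox = TRUE,
      digits = NA)
    manifest$status <- "model_quality_floor"
    manifest$files <- c(manifest$files, "quality_warning.json")
  } else {
    pixels <- .stage("ensembleShapley", {
      if (cfg$scope == "labeled_only") ls0$pixelIndices
      else seq_len(nPixels(ds))
    })
    sm <- .stage("ensembleShapley", ensembleShapley(ens, ds, pixels))
    writeShapleyMatrix(sm, file.path(outDir, "shapley_matrix.csv"))
    ranking <- .stage("rankFeatures",
                      rankFeatures(globalShapScores(sm), mzValues(ds)))
    writeRanking(ranking, file.path(outDir, "ranking.csv"))
    .stage("reportTopK",
           reportTopK(ds, sm, ranking, cfg$topK, file.path(outDir, "topk"),
                      cfg$directionThreshold))
    manifest$status <- "ok"
    manifest$files <- c(manifest$files, "shapley_matrix.csv", "ranking.csv",
                        file.path("topk", "topk_summary.csv"),
                        file.path("topk", "topk_manifest.json"))
  }
  log$status <- manifest$status
  jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the discovery workflow for several classes
#'
#' Independent one-versus-all runs sharing one dataset; per-class outputs
#' land in per-class subdirectories of the configured output directory.
#' A failing class does not disturb the others.
#'
#' @param cfg a [pipelineConfig()] with two or more classes.
#' @return named list with one manifest (or error condition) per class.
#' @export
runMulticlass <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  if (length(cfg$classes) < 2L)
    stop("runMulticlass needs at least two classes")
  out <- lapply(cfg$classes, function(cl) {
    tryCatch(runDiscovery(cfg, cl), error = function(e) e)
  })
  names(out) <- cfg$classes
  out
}
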
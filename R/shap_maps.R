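#' @include shapley.R
NULL

#' SHAP map of one feature
#'
#' Places one feature's per-pixel Shapley values on the acquisition grid.
#' Positive values mark pixels where the feature pushes the classifier
#' toward the class of interest, negative values where it pushes away;
#' magnitude is the strength of the influence.
#'
#' @param sm a \linkS4class{ShapleyMatrix}.
#' @param featureIndex 1-based feature index.
#' @param ds the explained \linkS4class{IMSDataset}.
#' @return a \linkS4class{SpatialImage}.
#' @export
shapMap <- function(sm, featureIndex, ds) {
  n <- ncol(shapValues(sm))
  if (length(featureIndex) != 1L || featureIndex < 1L || featureIndex > n)
    stop("featureIndex out of range 1..", n)
  valuesToImage(ds, shapValues(sm)[, featureIndex], pixels = pixelIndices(sm),
                legend = sprintf("Shapley value (log-odds), m/z %.4f",
                                 mzValues(ds)[featureIndex]))
}

# Diverging blue-white-red colour for t in [-1, 1].
.diverging_rgb <- function(t) {
  pos <- pmax(t, 0); neg <- pmax(-t, 0)
  r <- 1 - neg * (1 - 0.129) - pos * (1 - 0.698)
  g <- 1 - neg * (1 - 0.400) - pos * (1 - 0.094)
  b <- 1 - neg * (1 - 0.675) - pos * (1 - 0.168)
  cbind(r, g, b)
}

#' Render a SpatialImage with a symmetric diverging scale
#'
#' Writes a PNG raster with limits at plus/minus the maximum absolute
#' value (so zero is always the neutral white midpoint and sign is never
#' visually distorted), positive values in red, negative in blue, missing
#' cells in grey. A vertical colour bar is appended on the right, and the
#' numeric scale limits are written to a machine-readable sidecar
#' \code{<path>.json} legend.
#'
#' @param img a \linkS4class{SpatialImage}.
#' @param path output PNG path.
#' @param scale upscaling factor (integer pixel replication).
#' @return the path, invisibly.
#' @export
renderDiverging <- function(img, path, scale = 4L) {
  v <- imageValues(img)
  if (all(is.na(v))) stop("cannot render an all-missing image")
  lim <- max(abs(v), na.rm = TRUE)
  if (lim == 0) lim <- 1 # degenerate all-zero map: flat midpoint at +/-1
  H <- nrow(v); W <- ncol(v)
  t <- as.vector(v) / lim
  rgb <- .diverging_rgb(ifelse(is.na(t), 0, t))
  bg <- is.na(t)
  rgb[bg, ] <- 0.85 # background grey for missing cells
  arr <- array(0, c(H, W, 3L))
  for (ch in 1:3) arr[, , ch] <- matrix(rgb[, ch], H, W)
  # colour bar: 1 column gap + 2 columns spanning +lim (top) to -lim
  barT <- seq(1, -1, length.out = H)
  barRGB <- .diverging_rgb(barT)
  full <- array(1, c(H, W + 3L, 3L))
  full[, seq_len(W), ] <- arr
  for (ch in 1:3) {
    full[, W + 2L, ch] <- barRGB[, ch]
    full[, W + 3L, ch] <- barRGB[, ch]
  }
  if (scale > 1L) {
    idxH <- rep(seq_len(H), each = scale)
    idxW <- rep(seq_len(W + 3L), each = scale)
    full <- full[idxH, idxW, , drop = FALSE]
  }
  png::writePNG(full, path)
  jsonlite::write_json(
    list(legend = imageLegend(img), limit_negative = -lim,
         limit_positive = lim, colour = "blue (negative) / white (zero) / red (positive)"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Correlative / anticorrelative direction call for a feature
#'
#' Operationalizes the joint reading of ion image and SHAP map: the rank
#' correlation between a feature's measured intensity and its Shapley
#' values over the evaluated pixels. High intensity coinciding with
#' positive Shapley values (statistic above the threshold) means the
#' feature's \emph{presence} is indicative of the class (CORRELATIVE);
#' a statistic below the negative threshold means its \emph{absence} is
#' indicative (ANTICORRELATIVE); otherwise INDETERMINATE. Fewer than 10
#' usable pixels, or constant intensity or Shapley values, yield
#' INDETERMINATE with statistic 0.
#'
#' @param ds the explained \linkS4class{IMSDataset}.
#' @param sm a \linkS4class{ShapleyMatrix}.
#' @param featureIndex 1-based feature index.
#' @param evalPixels optional dataset pixel indices to evaluate (default:
#'   all covered pixels).
#' @param threshold verdict threshold on the rank correlation (default 0.3).
#' @return a \code{DirectionCall} list: \code{verdict},
#'   \code{statistic}, \code{nPixels}.
#' @export
directionCall <- function(ds, sm, featureIndex, evalPixels = NULL,
                          threshold = 0.3) {
  n <- ncol(shapValues(sm))
  if (featureIndex < 1L || featureIndex > n)
    stop("featureIndex out of range 1..", n)
  rows <- if (is.null(evalPixels)) seq_along(pixelIndices(sm))
          else match(evalPixels, pixelIndices(sm))
  if (any(is.na(rows))) stop("evalPixels not covered by the Shapley matrix")
  px <- pixelIndices(sm)[rows]
  ion <- intensityMatrix(ds)[px, featureIndex]
  phi <- shapValues(sm)[rows, featureIndex]
  out <- function(verdict, stat) {
    structure(list(verdict = verdict, statistic = stat,
                   nPixels = length(rows)), class = "DirectionCall")
  }
  if (length(rows) < 10L || length(unique(ion)) < 2L ||
      length(unique(phi)) < 2L)
    return(out("INDETERMINATE", 0))
  stat <- cor(ion, phi, method = "spearman")
  verdict <- if (stat > threshold) "CORRELATIVE"
             else if (stat < -threshold) "ANTICORRELATIVE"
             else "INDETERMINATE"
  out(verdict, stat)
}

#' @export
print.DirectionCall <- function(x, ...) {
  cat(sprintf("%s (rank correlation %.3f over %d pixels)\n",
              x$verdict, x$statistic, x$nPixels))
  invisible(x)
}

#' Pixels where a feature is most relevant
#'
#' The pixels whose absolute Shapley value exceeds the given quantile of
#' the absolute values over all covered pixels.
#'
#' @param sm a \linkS4class{ShapleyMatrix}.
#' @param featureIndex 1-based feature index.
#' @param quantile quantile in (0, 1) (0 allowed: strictly above the
#'   minimum).
#' @return dataset pixel indices (1-based).
#' @export
relevanceRegion <- function(sm, featureIndex, quantile = 0.9) {
  if (quantile < 0 || quantile >= 1) stop("quantile must lie in [0, 1)")
  a <- abs(shapValues(sm)[, featureIndex])
  thr <- stats::quantile(a, quantile, names = FALSE)
  pixelIndices(sm)[a > thr]
}

#' Report the top-k candidate markers
#'
#' For each of the k top-ranked features, writes the ion image raster and
#' the SHAP map raster, makes the direction call, and appends a row to a
#' summary CSV; a JSON manifest lists every file written.
#'
#' @param ds the explained \linkS4class{IMSDataset}.
#' @param sm a \linkS4class{ShapleyMatrix} covering the dataset.
#' @param ranking data.frame from [rankFeatures()].
#' @param k number of features to report, 1..n.
#' @param outdir output directory (created if needed).
#' @param threshold direction-call threshold.
#' @return the manifest (list), invisibly.
#' @export
reportTopK <- function(ds, sm, ranking, k, outdir, threshold = 0.3) {
  n <- nrow(ranking)
  if (k < 1L || k > n) stop("k out of range 1..", n)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create directory ", outdir)
  files <- character(0)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    fi <- ranking$featureIndex[i]
    ionPath <- file.path(outdir, sprintf("rank%02d_f%03d_ion.png", i, fi))
    shapPath <- file.path(outdir, sprintf("rank%02d_f%03d_shap.png", i, fi))
    renderDiverging(ionImage(ds, fi), ionPath)
    renderDiverging(shapMap(sm, fi, ds), shapPath)
    dc <- directionCall(ds, sm, fi, threshold = threshold)
    rows[[i]] <- data.frame(
      rank = i, feature_index = fi, mz = ranking$mz[i],
      global_shap_score = signif(ranking$globalScore[i], 12),
      verdict = dc$verdict, statistic = signif(dc$statistic, 12))
    files <- c(files, ionPath, shapPath)
  }
  summaryPath <- file.path(outdir, "topk_summary.csv")
  write.csv(do.call(rbind, rows), summaryPath, row.names = FALSE,
            quote = FALSE)
  manifest <- list(k = k, summary = summaryPath,
                   rasters = files,
                   legends = paste0(files, ".json"))
  manifestPath <- file.path(outdir, "topk_manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(c(manifest, manifest_path = manifestPath))
}
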
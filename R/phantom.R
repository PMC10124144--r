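#' @include ims_data.R
NULL

# Evaluate code under a fixed RNG seed without disturbing the caller's
# random state.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic per-stage seed derivation from a master seed (kept < 2^31).
.derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 7919 + stage * 104729) %% 2147483629)
}

.region_pixels <- function(shape, coords) {
  r <- coords[, 1L]; c <- coords[, 2L]
  inside <- switch(shape$type,
    rect = r >= shape$row0 & r <= shape$row1 & c >= shape$col0 & c <= shape$col1,
    ellipse = ((r - shape$centerRow) / shape$radiusRow)^2 +
              ((c - shape$centerCol) / shape$radiusCol)^2 <= 1,
    stop("unknown region primitive: ", shape$type)
  )
  which(inside)
}

#' Rectangle and ellipse region primitives
#'
#' Geometric primitives (in 0-based grid coordinates, bounds inclusive)
#' used to lay out phantom tissue regions.
#'
#' @param row0,col0,row1,col1 rectangle corners.
#' @param centerRow,centerCol,radiusRow,radiusCol ellipse parameters.
#' @return a primitive description for [phantomConfig()].
#' @export
rectRegion <- function(row0, col0, row1, col1) {
  stopifnot(row1 >= row0, col1 >= col0)
  list(type = "rect", row0 = row0, col0 = col0, row1 = row1, col1 = col1)
}

#' @rdname rectRegion
#' @export
ellipseRegion <- function(centerRow, centerCol, radiusRow, radiusCol) {
  stopifnot(radiusRow > 0, radiusCol > 0)
  list(type = "ellipse", centerRow = centerRow, centerCol = centerCol,
       radiusRow = radiusRow, radiusCol = radiusCol)
}

#' Configure a synthetic IMS phantom
#'
#' Describes a region-structured pixel grid with planted over/under-expressed
#' marker features, log-normal intensity noise, optionally correlated feature
#' pairs and an artifact-bleed confound. Intensities are generated as
#' \code{exp(baselineLogMean + region/marker effects + N(0, noiseSigma))}:
#' multiplicative noise is the natural behaviour of ion counts. An UP marker
#' adds \code{effectSize} to the log intensity inside its region, a DOWN
#' marker subtracts it. The artifact adds \code{bleedFraction} times each
#' affected marker's signed effect inside the bleed region, mimicking
#' analyte delocalization during sample preparation.
#'
#' @param gridH,gridW grid height and width in pixels.
#' @param regions named list of region primitives ([rectRegion()] /
#'   [ellipseRegion()]); regions must not overlap and must be non-empty.
#' @param nFeatures number of m/z features.
#' @param markers data.frame with columns \code{feature} (1-based, distinct),
#'   \code{region}, \code{direction} ("UP"/"DOWN"), \code{effectSize}
#'   (positive, log-scale fold change).
#' @param baselineLogMean baseline of the log intensity.
#' @param noiseSigma standard deviation of the log-scale Gaussian noise.
#' @param correlatedPairs optional data.frame with columns \code{a},
#'   \code{b}, \code{rho}: pairs sharing a latent Gaussian with the given
#'   correlation.
#' @param artifact optional list \code{list(region=, bleed=<primitive>,
#'   features=<marker features>, fraction=<0..1>)}.
#' @param seed integer; all randomness flows from this one seed.
#' @return a validated phantom configuration (list).
#' @export
phantomConfig <- function(gridH, gridW, regions, nFeatures, markers,
                          baselineLogMean = 0, noiseSigma = 0.3,
                          correlatedPairs = NULL, artifact = NULL,
                          seed = 1L) {
  stopifnot(gridH >= 1, gridW >= 1, nFeatures >= 1,
            length(regions) >= 1, !is.null(names(regions)),
            noiseSigma >= 0)
  markers <- as.data.frame(markers)
  stopifnot(all(c("feature", "region", "direction", "effectSize") %in%
                names(markers)))
  if (anyDuplicated(markers$feature))
    stop("overlapping marker assignment: duplicated feature index")
  if (any(markers$feature < 1 | markers$feature > nFeatures))
    stop("marker feature index out of range")
  if (!all(markers$direction %in% c("UP", "DOWN")))
    stop("marker direction must be UP or DOWN")
  if (any(markers$effectSize <= 0))
    stop("marker effect sizes must be positive")
  if (!all(markers$region %in% names(regions)))
    stop("marker assigned to unknown region")
  coords <- cbind(rep(0:(gridH - 1L), each = gridW),
                  rep(0:(gridW - 1L), times = gridH))
  member <- integer(gridH * gridW)
  for (i in seq_along(regions)) {
    px <- .region_pixels(regions[[i]], coords)
    if (length(px) == 0L)
      stop("degenerate region '", names(regions)[i], "' covers 0 pixels")
    if (any(member[px] != 0L))
      stop("regions overlap at a pixel")
    member[px] <- i
  }
  if (!is.null(correlatedPairs)) {
    correlatedPairs <- as.data.frame(correlatedPairs)
    stopifnot(all(c("a", "b", "rho") %in% names(correlatedPairs)))
    if (any(abs(correlatedPairs$rho) > 1))
      stop("correlation rho must lie in [-1, 1]")
    if (anyDuplicated(c(correlatedPairs$a, correlatedPairs$b)))
      stop("correlated pairs must be disjoint")
  }
  if (!is.null(artifact)) {
    stopifnot(all(c("region", "bleed", "features", "fraction") %in%
                  names(artifact)))
    if (artifact$fraction < 0 || artifact$fraction > 1)
      stop("bleed fraction must lie in [0, 1]")
    if (!all(artifact$features %in% markers$feature))
      stop("artifact-affected features must be planted markers")
  }
  structure(list(
    gridH = as.integer(gridH), gridW = as.integer(gridW),
    regions = regions, nFeatures = as.integer(nFeatures),
    markers = markers, baselineLogMean = baselineLogMean,
    noiseSigma = noiseSigma, correlatedPairs = correlatedPairs,
    artifact = artifact, seed = as.integer(seed),
    coords = coords, membership = member
  ), class = "PhantomConfig")
}

#' Generate a synthetic IMS phantom
#'
#' Draws the intensity matrix, one one-versus-all annotation mask per
#' region, and a ground-truth record, deterministically from the seed in
#' the configuration.
#'
#' @param cfg a [phantomConfig()].
#' @return a list with elements \code{dataset} (\linkS4class{IMSDataset}),
#'   \code{masks} (named list of \linkS4class{AnnotationMask}), and
#'   \code{groundTruth} (marker table plus per-pixel region membership).
#' @export
generatePhantom <- function(cfg) {
  stopifnot(inherits(cfg, "PhantomConfig"))
  m <- cfg$gridH * cfg$gridW
  n <- cfg$nFeatures
  L <- matrix(cfg$baselineLogMean, m, n)
  memb <- cfg$membership
  regionIdx <- function(name) which(names(cfg$regions) == name)
  for (i in seq_len(nrow(cfg$markers))) {
    mk <- cfg$markers[i, ]
    px <- which(memb == regionIdx(mk$region))
    s <- if (mk$direction == "UP") 1 else -1
    L[px, mk$feature] <- L[px, mk$feature] + s * mk$effectSize
  }
  if (!is.null(cfg$artifact)) {
    bleedPx <- .region_pixels(cfg$artifact$bleed, cfg$coords)
    if (length(bleedPx) == 0L) stop("degenerate bleed region")
    for (f in cfg$artifact$features) {
      mk <- cfg$markers[cfg$markers$feature == f, ]
      s <- if (mk$direction == "UP") 1 else -1
      L[bleedPx, f] <- L[bleedPx, f] + cfg$artifact$fraction * s * mk$effectSize
    }
  }
  if (cfg$noiseSigma > 0) {
    Z <- .with_seed(cfg$seed, matrix(rnorm(m * n), m, n))
    cp <- cfg$correlatedPairs
    if (!is.null(cp) && nrow(cp) > 0) {
      for (i in seq_len(nrow(cp))) {
        a <- cp$a[i]; b <- cp$b[i]; rho <- cp$rho[i]
        Z[, b] <- rho * Z[, a] + sqrt(1 - rho^2) * Z[, b]
      }
    }
    L <- L + cfg$noiseSigma * Z
  }
  mz <- round(seq(300, 1200, length.out = n), 4)
  ds <- IMSDataset(exp(L), cfg$coords, mz, "phantom")
  gt <- structure(list(
    markers = cfg$markers,
    membership = memb,
    regionNames = names(cfg$regions),
    gridH = cfg$gridH, gridW = cfg$gridW,
    coords = cfg$coords
  ), class = "GroundTruth")
  masks <- lapply(names(cfg$regions), function(nm) regionMask(gt, nm))
  names(masks) <- names(cfg$regions)
  list(dataset = ds, masks = masks, groundTruth = gt)
}

#' One-versus-all annotation mask for a phantom region
#'
#' Labels the named region POS and everything else NEG, then excludes a
#' boundary ring of the given width on both sides of the region border
#' (pixels whose 8-neighbourhood within Chebyshev distance
#' \code{ringWidth} contains a pixel of the opposite side), mirroring the
#' practice of dropping hard-to-annotate organ borders from training.
#'
#' @param gt ground truth from [generatePhantom()].
#' @param region region name.
#' @param ringWidth exclusion ring width in pixels (default 1).
#' @return an \linkS4class{AnnotationMask}.
#' @export
regionMask <- function(gt, region, ringWidth = 1L) {
  stopifnot(inherits(gt, "GroundTruth"))
  ri <- match(region, gt$regionNames)
  if (is.na(ri)) stop("unknown region: ", region)
  H <- gt$gridH; W <- gt$gridW
  inR <- matrix(FALSE, H, W)
  inR[cbind(gt$coords[, 1L] + 1L, gt$coords[, 2L] + 1L)] <- gt$membership == ri
  excl <- matrix(FALSE, H, W)
  w <- as.integer(ringWidth)
  for (dr in -w:w) for (dc in -w:w) {
    if (dr == 0L && dc == 0L) next
    rs <- max(1L, 1L - dr):min(H, H - dr)
    cs <- max(1L, 1L - dc):min(W, W - dc)
    excl[rs, cs] <- excl[rs, cs] | (inR[rs, cs] != inR[rs + dr, cs + dc])
  }
  lab <- ifelse(excl, "EXCLUDED", ifelse(inR, "POS", "NEG"))
  AnnotationMask(region, lab[cbind(gt$coords[, 1L] + 1L, gt$coords[, 2L] + 1L)])
}

#' Reference two-region phantom configuration
#'
#' The package's canonical study phantom: a 32 x 32 grid with two
#' rectangular tissue regions, 50 m/z features and 5 planted markers for
#' region A (3 over-expressed, 2 under-expressed, log-scale effect 2.0,
#' about a 7.4-fold change) under log-normal noise of sigma 0.3.
#'
#' @param seed integer seed.
#' @param noiseSigma log-scale noise level.
#' @param effectSize log-scale marker effect.
#' @return a [phantomConfig()].
#' @export
twoRegionPhantomConfig <- function(seed = 1L, noiseSigma = 0.3,
                                   effectSize = 2.0) {
  phantomConfig(
    gridH = 32L, gridW = 32L,
    regions = list(
      A = rectRegion(4, 3, 27, 13),
      B = rectRegion(4, 18, 27, 28)
    ),
    nFeatures = 50L,
    markers = data.frame(
      feature = c(5L, 15L, 25L, 35L, 45L),
      region = "A",
      direction = c("UP", "UP", "UP", "DOWN", "DOWN"),
      effectSize = effectSize
    ),
    baselineLogMean = 0,
    noiseSigma = noiseSigma,
    seed = seed
  )
}

#' Artifact-bleed phantom configuration
#'
#' The two-region grid with a delocalization confound. The dominant UP
#' marker (feature 5, the strongest planted effect, so the classifier
#' leans on it and it tops the global ranking) bleeds into a pocket of
#' region B at \code{bleedFraction} of its effect -- by default 0.9,
#' i.e. delocalized analyte deposited at near-native intensity, as in
#' sample-preparation artifacts where the classifier cannot untangle the
#' contaminated region from the true class by that feature alone. Two
#' weaker clean markers (one over-, one under-expressed) remain spatially
#' specific, so their SHAP maps correct in the bleed pocket what the
#' dominant marker gets wrong there: globally top-ranked, spatially
#' unspecific.
#'
#' @param seed integer seed.
#' @param bleedFraction fraction of the dominant marker's effect deposited
#'   in the bleed pocket.
#' @return a [phantomConfig()].
#' @export
artifactPhantomConfig <- function(seed = 1L, bleedFraction = 0.9) {
  base <- twoRegionPhantomConfig(seed)
  phantomConfig(
    gridH = base$gridH, gridW = base$gridW,
    regions = base$regions,
    nFeatures = base$nFeatures,
    markers = data.frame(
      feature = c(5L, 15L, 35L),
      region = "A",
      direction = c("UP", "UP", "DOWN"),
      effectSize = c(2.5, 1.2, 1.2)
    ),
    baselineLogMean = base$baselineLogMean,
    noiseSigma = base$noiseSigma,
    artifact = list(region = "A", bleed = rectRegion(10, 20, 18, 26),
                    features = 5L, fraction = bleedFraction),
    seed = seed
  )
}
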
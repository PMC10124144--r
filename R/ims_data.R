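#' @include accessors.R
NULL

.fmt_num <- function(x) sprintf("%.17g", x)

.grid_dims <- function(ds) {
  co <- pixelCoords(ds)
  c(max(co[, 1L]) + 1L, max(co[, 2L]) + 1L)
}

#' Construct an IMSDataset
#'
#' @param intensities numeric m x n matrix of pixel spectra (rows) by m/z
#'   features (columns); finite, non-negative.
#' @param pixelCoords m x 2 integer matrix of 0-based (row, col) grid
#'   coordinates, one per pixel.
#' @param mzValues strictly increasing positive m/z values, one per column.
#' @param name dataset name.
#' @return a validated \linkS4class{IMSDataset}.
#' @examples
#' ds <- IMSDataset(matrix(1, 4, 3), cbind(c(0, 0, 1, 1), c(0, 1, 0, 1)),
#'                  c(100, 200, 300), "tiny")
#' nPixels(ds)
#' @export
IMSDataset <- function(intensities, pixelCoords, mzValues, name = "dataset") {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  pixelCoords <- as.matrix(pixelCoords)
  storage.mode(pixelCoords) <- "integer"
  dimnames(intensities) <- NULL
  dimnames(pixelCoords) <- NULL
  new("IMSDataset", intensities = intensities, pixelCoords = pixelCoords,
      mzValues = as.numeric(mzValues), name = as.character(name))
}

#' Construct an AnnotationMask
#'
#' @param className name of the target tissue class.
#' @param labels character vector of \code{"POS"}, \code{"NEG"},
#'   \code{"EXCLUDED"}, one per dataset pixel (in dataset pixel order).
#' @return a validated \linkS4class{AnnotationMask}.
#' @export
AnnotationMask <- function(className, labels) {
  new("AnnotationMask", className = as.character(className),
      labels = as.character(labels))
}

#' Load an IMS dataset bundle
#'
#' Reads the delimited-text interchange bundle: \code{intensities.csv}
#' (m rows x n columns, header row of m/z strings), \code{pixels.csv}
#' (columns \code{row,col}, 0-based) and \code{mz.csv} (one m/z per line).
#' Pixels are brought into canonical row-major order (by grid row, then
#' column), and all dataset invariants are checked.
#'
#' @param dir directory containing the three files.
#' @param name dataset name; defaults to the directory's basename.
#' @return an \linkS4class{IMSDataset}.
#' @seealso [writeDataset()]
#' @export
loadDataset <- function(dir, name = basename(normalizePath(dir))) {
  fi <- file.path(dir, "intensities.csv")
  fp <- file.path(dir, "pixels.csv")
  fm <- file.path(dir, "mz.csv")
  for (f in c(fi, fp, fm))
    if (!file.exists(f)) stop("bundle file missing: ", f)
  X <- as.matrix(read.csv(fi, header = TRUE, check.names = FALSE))
  co <- as.matrix(read.csv(fp, header = TRUE))
  mz <- scan(fm, what = double(), quiet = TRUE)
  if (nrow(X) == 0L) stop("empty dataset: no pixels in bundle")
  if (nrow(co) != nrow(X))
    stop("shape mismatch: ", nrow(X), " intensity rows vs ",
         nrow(co), " pixel coordinates")
  if (length(mz) != ncol(X))
    stop("shape mismatch: ", ncol(X), " intensity columns vs ",
         length(mz), " m/z values")
  dup <- duplicated(co)
  if (any(dup)) {
    d <- co[which(dup)[1L], ]
    stop(sprintf("duplicate pixel coordinate (%d,%d)", d[1L], d[2L]))
  }
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("m/z not strictly increasing")
  if (any(!is.finite(X)))
    stop("intensity table contains NaN/Inf/NA")
  ord <- order(co[, 1L], co[, 2L])
  IMSDataset(X[ord, , drop = FALSE], co[ord, , drop = FALSE], mz, name)
}

#' Write an IMS dataset bundle
#'
#' Writes the delimited-text bundle read by [loadDataset()]; intensities
#' are serialized at full double precision, so a load/write round trip is
#' the identity to well below 1e-12.
#'
#' @param ds an \linkS4class{IMSDataset}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeDataset <- function(ds, dir) {
  stopifnot(is(ds, "IMSDataset"))
  validObject(ds)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  X <- intensityMatrix(ds)
  mz <- mzValues(ds)
  lines <- c(paste(.fmt_num(mz), collapse = ","),
             apply(X, 1L, function(r) paste(.fmt_num(r), collapse = ",")))
  writeLines(lines, file.path(dir, "intensities.csv"))
  co <- pixelCoords(ds)
  writeLines(c("row,col", paste(co[, 1L], co[, 2L], sep = ",")),
             file.path(dir, "pixels.csv"))
  writeLines(.fmt_num(mz), file.path(dir, "mz.csv"))
  invisible(dir)
}

#' Ion image of one m/z feature
#'
#' Places one intensity column on the acquisition grid; grid cells without
#' an acquired pixel are \code{NA}.
#'
#' @param ds an \linkS4class{IMSDataset}.
#' @param featureIndex 1-based feature (column) index.
#' @return a \linkS4class{SpatialImage}.
#' @export
ionImage <- function(ds, featureIndex) {
  stopifnot(is(ds, "IMSDataset"))
  n <- nFeatures(ds)
  if (length(featureIndex) != 1L || featureIndex < 1L || featureIndex > n)
    stop("featureIndex out of range 1..", n)
  valuesToImage(ds, intensityMatrix(ds)[, featureIndex],
                legend = sprintf("ion intensity, m/z %.4f",
                                 mzValues(ds)[featureIndex]))
}

#' Place per-pixel values on the acquisition grid
#'
#' @param ds an \linkS4class{IMSDataset}.
#' @param values numeric vector with one value per covered pixel.
#' @param pixels 1-based dataset pixel indices the values belong to
#'   (default: all pixels, in order).
#' @param legend description of the values.
#' @return a \linkS4class{SpatialImage}.
#' @export
valuesToImage <- function(ds, values, pixels = seq_len(nPixels(ds)),
                          legend = "values") {
  stopifnot(length(values) == length(pixels))
  d <- .grid_dims(ds)
  grid <- matrix(NA_real_, d[1L], d[2L])
  co <- pixelCoords(ds)[pixels, , drop = FALSE]
  grid[cbind(co[, 1L] + 1L, co[, 2L] + 1L)] <- values
  new("SpatialImage", values = grid, legend = legend)
}

#' Flatten a SpatialImage back to per-pixel values
#'
#' Inverse of [valuesToImage()] over covered pixels.
#'
#' @param img a \linkS4class{SpatialImage}.
#' @param ds the source \linkS4class{IMSDataset}.
#' @return numeric vector, one value per dataset pixel.
#' @export
imageToValues <- function(img, ds) {
  co <- pixelCoords(ds)
  imageValues(img)[cbind(co[, 1L] + 1L, co[, 2L] + 1L)]
}

#' Write a SpatialImage as a CSV grid
#'
#' @param img a \linkS4class{SpatialImage}.
#' @param path output file; missing cells are written as \code{NA}.
#' @return the path, invisibly.
#' @export
writeImage <- function(img, path) {
  v <- imageValues(img)
  lines <- apply(v, 1L, function(r) {
    s <- ifelse(is.na(r), "NA", .fmt_num(r))
    paste(s, collapse = ",")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Load an annotation mask grid
#'
#' Reads an integer grid (no header) whose cells encode 1 = POS, 0 = NEG,
#' -1 = EXCLUDED, and aligns it to the dataset's pixels.
#'
#' @param path CSV grid file.
#' @param ds the \linkS4class{IMSDataset} the mask annotates.
#' @param className class name; defaults to the file name stripped of a
#'   \code{mask_} prefix.
#' @return an \linkS4class{AnnotationMask}.
#' @export
loadMask <- function(path, ds,
                     className = sub("^mask_", "",
                                     tools::file_path_sans_ext(basename(path)))) {
  g <- as.matrix(read.csv(path, header = FALSE))
  d <- .grid_dims(ds)
  if (nrow(g) < d[1L] || ncol(g) < d[2L])
    stop("mask grid (", nrow(g), "x", ncol(g),
         ") too small for dataset grid (", d[1L], "x", d[2L], ")")
  co <- pixelCoords(ds)
  codes <- g[cbind(co[, 1L] + 1L, co[, 2L] + 1L)]
  if (any(is.na(codes)))
    stop("a dataset pixel is absent from the mask grid")
  bad <- setdiff(unique(codes), c(1, 0, -1))
  if (length(bad))
    stop("unknown label code: ", paste(bad, collapse = ", "))
  labels <- c("EXCLUDED", "NEG", "POS")[codes + 2L]
  AnnotationMask(className, labels)
}

#' Write an annotation mask as a CSV grid
#'
#' Cells covered by a pixel carry 1/0/-1 for POS/NEG/EXCLUDED; grid cells
#' with no pixel are written as -1 (they can never enter training).
#'
#' @param mask an \linkS4class{AnnotationMask}.
#' @param ds the annotated \linkS4class{IMSDataset}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, ds, path) {
  stopifnot(length(maskLabels(mask)) == nPixels(ds))
  d <- .grid_dims(ds)
  g <- matrix(-1L, d[1L], d[2L])
  co <- pixelCoords(ds)
  code <- c(POS = 1L, NEG = 0L, EXCLUDED = -1L)[maskLabels(mask)]
  g[cbind(co[, 1L] + 1L, co[, 2L] + 1L)] <- code
  writeLines(apply(g, 1L, paste, collapse = ","), path)
  invisible(path)
}
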
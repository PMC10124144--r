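# A minimal 2 x 2 grid dataset with 3 features; column j of the intensity
# matrix is j * (1, 2, 3, 4) so placement is easy to eyeball.
tiny_dataset <- function() {
  X <- outer(c(1, 2, 3, 4), c(1, 10, 100))
  co <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  IMSDataset(X, co, c(100.5, 200.5, 300.5), "tiny")
}

write_tiny_bundle <- function(dir, mz = c(100.5, 200.5, 300.5),
                              coords = rbind(c(0, 0), c(0, 1),
                                             c(1, 0), c(1, 1)),
                              X = matrix(1, 4, 3)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c(paste(mz, collapse = ","),
               apply(X, 1, paste, collapse = ",")),
             file.path(dir, "intensities.csv"))
  writeLines(c("row,col", paste(coords[, 1], coords[, 2], sep = ",")),
             file.path(dir, "pixels.csv"))
  writeLines(as.character(mz), file.path(dir, "mz.csv"))
  dir
}

# Round a numeric matrix to float32-representable values (for comparisons
# against single-precision reference implementations).
round_f32 <- function(M) {
  v <- readBin(writeBin(as.vector(M), raw(), size = 4L), "numeric",
               n = length(M), size = 4L)
  matrix(v, nrow(M), ncol(M))
}

# Small trained setup reused across tests: phantom A-vs-rest classifier.
phantom_fit <- function(seed = 1L, nTrees = 50L, noiseSigma = 0.3) {
  ph <- generatePhantom(twoRegionPhantomConfig(seed = seed,
                                               noiseSigma = noiseSigma))
  ls0 <- makeLabels(ph$masks$A)
  lsb <- downsampleNegatives(ls0, 0.25, seed = seed + 100L)
  sp <- splitHoldout(lsb, 0.25, seed = seed + 200L)
  ens <- trainEnsemble(ph$dataset, sp$train,
                       trainingConfig(nTrees = nTrees, seed = seed + 300L))
  list(phantom = ph, labels = ls0, balanced = lsb, split = sp, ens = ens)
}
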
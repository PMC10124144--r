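# Hand-written node matrices (columns: feature, threshold, left, right,
# value, cover; 1-based indices, -1 at leaves).

stump_tree <- function(feature = 1, thr = 2.5, leftValue = -1,
                       rightValue = 1, leftCover = 30, rightCover = 70) {
  rbind(c(feature, thr, 2, 3, NA, leftCover + rightCover),
        c(-1, NA, -1, -1, leftValue, leftCover),
        c(-1, NA, -1, -1, rightValue, rightCover))
}

leaf_tree <- function(value = 0.7, cover = 10) {
  rbind(c(-1, NA, -1, -1, value, cover))
}

# The two-feature depth-2 tree with covers (60: 40/20 | 40: 10/30) and
# leaf values 1..4, split thresholds 0.5 on both features.
depth2_tree <- function() {
  rbind(c(1, 0.5, 2, 5, NA, 100),
        c(2, 0.5, 3, 4, NA, 60),
        c(-1, NA, -1, -1, 1, 40),
        c(-1, NA, -1, -1, 2, 20),
        c(2, 0.5, 6, 7, NA, 40),
        c(-1, NA, -1, -1, 3, 10),
        c(-1, NA, -1, -1, 4, 30))
}

# Random regression tree with conserved integer covers, for oracle sweeps.
# Uses the caller's RNG state.
random_cover_tree <- function(maxDepth = 5, nFeatures = 10,
                              rootCover = NULL) {
  rows <- list()
  grow <- function(depth, cover) {
    i <- length(rows) + 1L
    rows[[i]] <<- NA
    if (depth == 0L || cover < 2L || runif(1) < 0.25) {
      rows[[i]] <<- c(-1, NA, -1, -1, rnorm(1), cover)
      return(i)
    }
    cl <- sample(seq_len(cover - 1L), 1L)
    li <- grow(depth - 1L, cl)
    ri <- grow(depth - 1L, cover - cl)
    rows[[i]] <<- c(sample(nFeatures, 1L), rnorm(1), li, ri, NA, cover)
    i
  }
  if (is.null(rootCover)) rootCover <- sample(20:400, 1L)
  grow(maxDepth, rootCover)
  do.call(rbind, rows)
}

# Mirror-symmetric tree in features 1 and 2: equal covers, leaf values
# (a, b, b, c), thresholds 0 on both; any x with x1, x2 on the same side
# treats the two features interchangeably.
symmetric_tree <- function(a = -2, b = 0.5, c = 3) {
  rbind(c(1, 0, 2, 5, NA, 100),
        c(2, 0, 3, 4, NA, 50),
        c(-1, NA, -1, -1, a, 25),
        c(-1, NA, -1, -1, b, 25),
        c(2, 0, 6, 7, NA, 50),
        c(-1, NA, -1, -1, b, 25),
        c(-1, NA, -1, -1, c, 25))
}
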
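# Shared independent oracles, deliberately naive implementations.

# Per-pixel inside-circle test (oracle for rendered disk masks).
oracleDiskMask <- function(shape, center, radius) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

# Exhaustive maximum-total-IoU one-to-one matching: tries every injective
# assignment of predictions to ground-truth objects over pairs with
# IoU >= tau. Returns the number of matched pairs in the best assignment.
bruteForceMatch <- function(M, tau) {
  np <- nrow(M); ng <- ncol(M)
  best <- 0; bestTp <- 0L
  rec <- function(p, usedG, total, tp) {
    if (p > np) {
      if (total > best + 1e-12) { best <<- total; bestTp <<- tp }
      return(invisible())
    }
    rec(p + 1L, usedG, total, tp)  # leave prediction p unmatched
    for (g in seq_len(ng)) {
      if (!usedG[g] && M[p, g] >= tau) {
        usedG[g] <- TRUE
        rec(p + 1L, usedG, total + M[p, g], tp + 1L)
        usedG[g] <- FALSE
      }
    }
  }
  if (np > 0L && ng > 0L) rec(1L, logical(ng), 0, 0L)
  list(totalIoU = best, tp = bestTp)
}

# Random small instance layout: two label masks on a shared grid, each made
# of axis-aligned rectangles so overlaps are easy to reason about.
randomLayout <- function(nPred, nGt, shape = c(40, 40)) {
  place <- function(n) {
    m <- matrix(0L, shape[1], shape[2])
    for (i in seq_len(n)) {
      h <- sample(4:12, 1); w <- sample(4:12, 1)
      r0 <- sample(seq_len(shape[1] - h), 1)
      c0 <- sample(seq_len(shape[2] - w), 1)
      patch <- m[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
      patch[patch == 0L] <- i
      m[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- patch
    }
    # drop labels wiped out by later rectangles, relabel consecutively
    u <- sort(unique(m[m > 0L]))
    if (length(u)) m[m > 0L] <- match(m[m > 0L], u)
    m
  }
  list(pred = spheropick::LabelMask(place(nPred)),
       gt = spheropick::LabelMask(place(nGt)))
}

# Dense IoU matrix by direct per-pair pixel counting (independent of the
# package's tabulation).
naiveIoUMatrix <- function(predMask, gtMask) {
  p <- spheropick::maskData(predMask); g <- spheropick::maskData(gtMask)
  np <- max(0L, p); ng <- max(0L, g)
  M <- matrix(0, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    inter <- sum(p == i & g == j)
    M[i, j] <- inter / (sum(p == i) + sum(g == j) - inter)
  }
  M
}
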
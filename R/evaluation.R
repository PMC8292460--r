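# Instance-segmentation benchmarking: IoU, optimal one-to-one matching at a
# threshold, detection precision/sensitivity scoring and threshold curves.
#
# The precision score used here is the detection-quality form
# P = TP / (TP + FP + FN), which penalizes both spurious and missed objects;
# the classical precision TP / (TP + FP) is also reported (column
# `classical_precision`) for cross-tool comparison.

#' Intersection over union of two pixel sets
#'
#' @param objectA,objectB logical (or 0/1) matrices of identical shape, or
#'   integer vectors of pixel indices.
#' @return `|A n B| / |A u B|` in `[0, 1]`; 0 for disjoint sets.
#' @examples
#' a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
#' b <- matrix(FALSE, 20, 20); b[1:10, 6:15] <- TRUE
#' objectIoU(a, b)  # 1/3
#' @export
objectIoU <- function(objectA, objectB) {
  ia <- if (is.matrix(objectA)) which(objectA > 0) else as.integer(objectA)
  ib <- if (is.matrix(objectB)) which(objectB > 0) else as.integer(objectB)
  if (!length(ia) && !length(ib)) stop("both objects are empty")
  inter <- length(intersect(ia, ib))
  inter / (length(ia) + length(ib) - inter)
}

# Dense IoU matrix between all prediction/ground-truth label pairs.
iouMatrix <- function(predMask, gtMask) {
  np <- if (any(predMask > 0L)) max(predMask) else 0L
  ng <- if (any(gtMask > 0L)) max(gtMask) else 0L
  M <- matrix(0, np, ng)
  if (np == 0L || ng == 0L) return(M)
  pa <- tabulate(predMask[predMask > 0L], nbins = np)
  ga <- tabulate(gtMask[gtMask > 0L], nbins = ng)
  both <- predMask > 0L & gtMask > 0L
  if (any(both)) {
    code <- (as.integer(predMask[both]) - 1L) * ng + as.integer(gtMask[both])
    tab <- tabulate(code, nbins = np * ng)
    hit <- which(tab > 0L)
    for (h in hit) {
      p <- (h - 1L) %/% ng + 1L
      g <- (h - 1L) %% ng + 1L
      M[p, g] <- tab[h] / (pa[p] + ga[g] - tab[h])
    }
  }
  M
}

# Exact maximum-total-IoU one-to-one assignment over eligible pairs
# (iou >= tau), by bitmask dynamic programming over the smaller dimension.
# Deterministic: among equal-weight optima the reconstruction prefers
# leaving earlier rows unmatched last and matches ascending column indices
# first, which yields the lexicographically smallest (gt, pred) pairing.
# Returns data.frame(pred, gt, iou).
assignPairs <- function(M, tau) {
  np <- nrow(M); ng <- ncol(M)
  if (np == 0L || ng == 0L) return(data.frame(pred = integer(), gt = integer(),
                                              iou = numeric()))
  W <- M
  W[W < tau] <- 0  # ineligible pairs carry no weight and are never matched
  transposed <- FALSE
  if (ng > np) { W <- t(W); transposed <- TRUE }
  nr <- nrow(W); nc <- ncol(W)   # nc = smaller side
  if (nc > 14L) return(assignGreedy(M, tau))
  nstates <- bitwShiftL(1L, nc)
  # best[s + 1]: max total weight using rows 1..k with matched-column set s
  best <- rep(-Inf, nstates); best[1] <- 0
  choiceList <- vector("list", nr)
  for (r in seq_len(nr)) {
    newbest <- best  # row r unmatched
    pick <- integer(nstates)  # column chosen for row r reaching state s (0 = none)
    wr <- W[r, ]
    cols <- which(wr > 0)
    for (cc in cols) {
      bit <- bitwShiftL(1L, cc - 1L)
      fromStates <- which(best > -Inf) - 1L
      for (s in fromStates) {
        if (bitwAnd(s, bit) != 0L) next
        cand <- best[s + 1L] + wr[cc]
        ns <- bitwOr(s, bit)
        if (cand > newbest[ns + 1L] + 1e-12) {
          newbest[ns + 1L] <- cand
          pick[ns + 1L] <- cc
        }
      }
    }
    best <- newbest
    choiceList[[r]] <- pick
  }
  sBest <- which.max(best) - 1L
  # reconstruct
  pairs <- matrix(integer(0), ncol = 2)
  s <- sBest
  for (r in rev(seq_len(nr))) {
    cc <- choiceList[[r]][s + 1L]
    if (cc > 0L) {
      # verify this choice is consistent (the stored pick reached this state)
      pairs <- rbind(pairs, c(r, cc))
      s <- bitwAnd(s, bitwNot(bitwShiftL(1L, cc - 1L)))
    }
  }
  if (nrow(pairs)) {
    if (transposed) {
      out <- data.frame(pred = pairs[, 2], gt = pairs[, 1])
    } else {
      out <- data.frame(pred = pairs[, 1], gt = pairs[, 2])
    }
    out$iou <- M[cbind(out$pred, out$gt)]
    out <- out[out$iou >= tau, , drop = FALSE]
    out <- out[order(out$gt, out$pred), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else data.frame(pred = integer(), gt = integer(), iou = numeric())
}

# Greedy fallback for very crowded scenes: match descending IoU.
# Provably optimal when tau > 0.5 (matches are then mutually exclusive).
assignGreedy <- function(M, tau) {
  el <- which(M >= tau, arr.ind = TRUE)
  if (!nrow(el)) return(data.frame(pred = integer(), gt = integer(),
                                   iou = numeric()))
  w <- M[el]
  ord <- order(-w, el[, 2], el[, 1])
  el <- el[ord, , drop = FALSE]; w <- w[ord]
  usedP <- logical(nrow(M)); usedG <- logical(ncol(M))
  keep <- logical(nrow(el))
  for (i in seq_len(nrow(el))) {
    p <- el[i, 1]; g <- el[i, 2]
    if (!usedP[p] && !usedG[g]) { keep[i] <- TRUE; usedP[p] <- TRUE; usedG[g] <- TRUE }
  }
  out <- data.frame(pred = el[keep, 1], gt = el[keep, 2], iou = w[keep])
  out <- out[order(out$gt, out$pred), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match predicted to ground-truth objects at an IoU threshold
#'
#' Finds the one-to-one assignment maximizing total IoU over pairs with
#' IoU >= `tau` (exact assignment on the IoU matrix; ties broken toward
#' ascending ground-truth then prediction labels). Matched predictions are
#' true positives, unmatched predictions false positives, unmatched
#' ground-truth objects false negatives.
#'
#' @param pred,gt [LabelMask-class] objects of identical shape.
#' @param tau IoU threshold in `(0, 1)`.
#' @return list with `counts` (an [EvalCounts-class]) and `matches`
#'   (data.frame `pred`, `gt`, `iou`).
#' @export
matchObjects <- function(pred, gt, tau = 0.5) {
  stopifnot(is(pred, "LabelMask"), is(gt, "LabelMask"))
  if (!identical(dim(pred), dim(gt)))
    stop(sprintf("mask shapes differ: %d x %d vs %d x %d",
                 dim(pred)[1], dim(pred)[2], dim(gt)[1], dim(gt)[2]))
  if (tau <= 0 || tau >= 1) stop("'tau' must lie in (0, 1)")
  M <- iouMatrix(maskData(pred), maskData(gt))
  matches <- assignPairs(M, tau)
  np <- nrow(M); ng <- ncol(M)
  tp <- nrow(matches)
  list(counts = evalCounts(tp = tp, fp = np - tp, fn = ng - tp,
                           iouThreshold = tau),
       matches = matches)
}

#' Detection precision score
#'
#' `tp / (tp + fp + fn)` — a detection-quality score that penalizes both
#' spurious and missed objects (distinct from the classical precision
#' `tp / (tp + fp)`, see [classicalPrecision()]). An empty image with an
#' empty prediction (`tp = fp = fn = 0`) scores 1 by convention.
#'
#' @param counts an [EvalCounts-class].
#' @return score in `[0, 1]`.
#' @examples
#' precisionScore(evalCounts(tp = 1, fp = 0, fn = 1))  # 0.5
#' @export
precisionScore <- function(counts) {
  stopifnot(is(counts, "EvalCounts"))
  denom <- counts@tp + counts@fp + counts@fn
  if (denom == 0L) 1 else counts@tp / denom
}

#' Classical precision
#'
#' `tp / (tp + fp)`; 1 by convention when there are no predictions.
#'
#' @param counts an [EvalCounts-class].
#' @return score in `[0, 1]`.
#' @export
classicalPrecision <- function(counts) {
  stopifnot(is(counts, "EvalCounts"))
  denom <- counts@tp + counts@fp
  if (denom == 0L) 1 else counts@tp / denom
}

#' Detection sensitivity (recall)
#'
#' `tp / nGt`, the fraction of ground-truth objects detected.
#'
#' @param counts an [EvalCounts-class].
#' @return score in `[0, 1]`.
#' @examples
#' sensitivityScore(evalCounts(tp = 1, fp = 0, fn = 1))  # 0.5
#' @export
sensitivityScore <- function(counts) {
  stopifnot(is(counts, "EvalCounts"))
  if (counts@nGt == 0L)
    stop("sensitivity is undefined when there are no ground-truth objects")
  counts@tp / counts@nGt
}

#' Evaluate a dataset of prediction/ground-truth mask pairs
#'
#' Computes precision and sensitivity over a grid of IoU thresholds.
#' Pooled scope (the default aggregation) sums matched-object counts across
#' images at each threshold, then scores; per-image scope averages per-image
#' scores (images with no ground-truth objects are excluded from the
#' sensitivity average, and score detection precision 1 when the prediction
#' is also empty).
#'
#' @param pairs list; each element a list with `pred` and `gt`
#'   ([LabelMask-class], identical shapes within a pair).
#' @param taus strictly increasing IoU thresholds in `(0, 1)`; default
#'   `seq(0.5, 0.95, by = 0.05)`.
#' @param scope `"pooled"` or `"per_image"`.
#' @return an [EvalCurve-class].
#' @export
evaluateDataset <- function(pairs, taus = seq(0.5, 0.95, by = 0.05),
                            scope = c("pooled", "per_image")) {
  scope <- match.arg(scope)
  if (!length(pairs)) stop("need at least one (pred, gt) pair")
  if (!length(taus)) stop("threshold grid is empty")
  if (any(taus <= 0 | taus >= 1) || is.unsorted(taus, strictly = TRUE))
    stop("'taus' must be strictly increasing in (0, 1)")
  # IoU matrices are threshold-independent; compute once per image
  mats <- lapply(pairs, function(p) {
    stopifnot(is(p$pred, "LabelMask"), is(p$gt, "LabelMask"))
    if (!identical(dim(p$pred), dim(p$gt))) stop("mask shapes differ")
    iouMatrix(maskData(p$pred), maskData(p$gt))
  })
  rows <- lapply(taus, function(tau) {
    cnt <- lapply(mats, function(M) {
      tp <- nrow(assignPairs(M, tau))
      c(tp = tp, fp = nrow(M) - tp, fn = ncol(M) - tp)
    })
    if (scope == "pooled") {
      s <- Reduce(`+`, cnt)
      ec <- evalCounts(s["tp"], s["fp"], s["fn"], iouThreshold = tau)
      data.frame(tau = tau, precision = precisionScore(ec),
                 sensitivity = sensitivityScore(ec),
                 classical_precision = classicalPrecision(ec),
                 tp = ec@tp, fp = ec@fp, fn = ec@fn)
    } else {
      ecs <- lapply(cnt, function(s)
        evalCounts(s["tp"], s["fp"], s["fn"], iouThreshold = tau))
      prec <- mean(vapply(ecs, precisionScore, numeric(1)))
      hasGt <- vapply(ecs, function(e) e@nGt > 0L, logical(1))
      if (!any(hasGt)) stop("no image has ground-truth objects")
      sens <- mean(vapply(ecs[hasGt], sensitivityScore, numeric(1)))
      cprec <- mean(vapply(ecs, classicalPrecision, numeric(1)))
      s <- Reduce(`+`, cnt)
      data.frame(tau = tau, precision = prec, sensitivity = sens,
                 classical_precision = cprec,
                 tp = as.integer(s["tp"]), fp = as.integer(s["fp"]),
                 fn = as.integer(s["fn"]))
    }
  })
  new("EvalCurve", curve = do.call(rbind, rows), scope = scope)
}
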
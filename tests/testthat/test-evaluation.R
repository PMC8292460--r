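test_that("objectIoU counts pixels correctly and is symmetric", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  expect_equal(objectIoU(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[15:20, 15:20] <- TRUE
  expect_equal(objectIoU(a, b), 0)
  shifted <- matrix(FALSE, 20, 20); shifted[1:10, 6:15] <- TRUE
  expect_equal(objectIoU(a, shifted), 1 / 3)  # inter 50, union 150
  expect_equal(objectIoU(shifted, a), objectIoU(a, shifted))
  expect_error(objectIoU(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty")
})

test_that("matchObjects handles the canonical matching cases", {
  # perfect prediction: all matched at any threshold
  m <- matrix(0L, 30, 30)
  m[2:8, 2:8] <- 1L; m[12:18, 12:18] <- 2L; m[22:28, 22:28] <- 3L
  gt <- LabelMask(m)
  for (tau in c(0.3, 0.5, 0.9)) {
    cnt <- matchObjects(gt, gt, tau)$counts
    expect_identical(c(cnt@tp, cnt@fp, cnt@fn), c(3L, 0L, 0L))
  }

  # 2 GT, 1 prediction overlapping one GT at IoU 0.6
  g <- matrix(0L, 20, 40); g[1:10, 1:10] <- 1L; g[1:10, 21:30] <- 2L
  p <- matrix(0L, 20, 40); p[1:10, 3:10] <- 1L  # IoU = 80/100 = 0.8 >= 0.5
  res <- matchObjects(LabelMask(p), LabelMask(g), 0.5)
  expect_identical(c(res$counts@tp, res$counts@fp, res$counts@fn),
                   c(1L, 0L, 1L))
  expect_identical(res$matches$gt, 1L)

  # one GT split into two predicted halves, each IoU exactly 0.5
  g2 <- matrix(0L, 10, 20); g2[1:10, 1:10] <- 1L
  p2 <- matrix(0L, 10, 20); p2[1:5, 1:10] <- 1L; p2[6:10, 1:10] <- 2L
  res2 <- matchObjects(LabelMask(p2), LabelMask(g2), 0.5)
  expect_identical(c(res2$counts@tp, res2$counts@fp, res2$counts@fn),
                   c(1L, 1L, 0L))
  expect_error(matchObjects(LabelMask(matrix(0L, 5, 5)), LabelMask(g2), 0.5),
               "shapes differ")
})

test_that("precision and sensitivity follow the detection-score definitions", {
  expect_equal(precisionScore(evalCounts(1, 0, 1)), 0.5)
  expect_equal(precisionScore(evalCounts(4, 0, 0)), 1)
  expect_equal(precisionScore(evalCounts(0, 3, 2)), 0)
  expect_equal(precisionScore(evalCounts(0, 0, 0)), 1)  # empty convention
  expect_equal(classicalPrecision(evalCounts(1, 1, 3)), 0.5)
  expect_equal(sensitivityScore(evalCounts(3, 0, 0)), 1)
  expect_equal(sensitivityScore(evalCounts(1, 0, 1)), 0.5)
  expect_equal(sensitivityScore(evalCounts(0, 5, 5)), 0)
  expect_error(sensitivityScore(evalCounts(0, 2, 0)), "undefined")
})

test_that("assignment equals exhaustive search on random small layouts", {
  withr::with_seed(123, {
    for (rep in seq_len(60)) {
      lay <- randomLayout(sample(0:5, 1), sample(0:5, 1))
      M <- naiveIoUMatrix(lay$pred, lay$gt)
      for (tau in c(0.3, 0.5)) {
        res <- matchObjects(lay$pred, lay$gt, tau)
        bf <- bruteForceMatch(M, tau)
        expect_identical(res$counts@tp, bf$tp)
        expect_equal(sum(res$matches$iou), bf$totalIoU, tolerance = 1e-9)
      }
    }
  })
})

test_that("tp is non-increasing in the IoU threshold", {
  withr::with_seed(7, {
    for (rep in seq_len(10)) {
      lay <- randomLayout(sample(1:5, 1), sample(1:5, 1))
      tps <- vapply(seq(0.05, 0.95, by = 0.1), function(tau)
        matchObjects(lay$pred, lay$gt, tau)$counts@tp, integer(1))
      expect_true(all(diff(tps) <= 0L))
    }
  })
})

test_that("evaluateDataset pools counts and matches per-image brute force", {
  set <- makeBenchmarkSet(4, profile = "clean", seed = 19)
  pairs <- lapply(set, function(e)
    list(pred = segmentOtsu(e$image, objectFilterParams(minAreaPx = 50)),
         gt = e$mask))
  taus <- c(0.5, 0.75, 0.9)
  curve <- curveData(evaluateDataset(pairs, taus = taus, scope = "pooled"))
  expect_identical(nrow(curve), 3L)
  for (k in seq_along(taus)) {
    cnt <- lapply(pairs, function(p) {
      M <- naiveIoUMatrix(p$pred, p$gt)
      bf <- bruteForceMatch(M, taus[k])
      c(tp = bf$tp, np = nrow(M), ng = ncol(M))
    })
    s <- Reduce(`+`, cnt)
    expect_identical(curve$tp[k], as.integer(s["tp"]))
    expect_equal(curve$precision[k],
                 s["tp"] / (s["tp"] + (s["np"] - s["tp"]) + (s["ng"] - s["tp"])),
                 ignore_attr = TRUE)
    expect_equal(curve$sensitivity[k], s[["tp"]] / s[["ng"]])
  }
  # curves are non-increasing in tau
  expect_true(all(diff(curve$precision) <= 1e-12))
  expect_true(all(diff(curve$sensitivity) <= 1e-12))

  # perfect predictions give P = S = 1 everywhere
  perfect <- lapply(set, function(e) list(pred = e$mask, gt = e$mask))
  pc <- curveData(evaluateDataset(perfect))
  expect_identical(nrow(pc), 10L)  # default 0.50..0.95 grid
  expect_true(all(pc$precision == 1 & pc$sensitivity == 1))

  # per-image scope averages scores
  pi1 <- curveData(evaluateDataset(pairs, taus = 0.5, scope = "per_image"))
  perImg <- vapply(pairs, function(p) {
    bf <- bruteForceMatch(naiveIoUMatrix(p$pred, p$gt), 0.5)
    bf$tp / nObjects(p$gt)
  }, numeric(1))
  expect_equal(pi1$sensitivity, mean(perImg))
  expect_error(evaluateDataset(pairs, taus = numeric()), "empty")
  expect_error(evaluateDataset(pairs, taus = c(0.9, 0.5)), "increasing")
})

test_that("degrading the input never improves pooled otsu precision", {
  clean <- makeBenchmarkSet(5, profile = "clean", seed = 29)
  segAll <- function(set) lapply(set, function(e)
    list(pred = segmentOtsu(e$image, objectFilterParams(minAreaPx = 50)),
         gt = e$mask))
  pClean <- curveData(evaluateDataset(segAll(clean), taus = 0.5))$precision
  # same scenes with heavy added noise and defocus
  noisy <- lapply(clean, function(e) {
    s <- e$scene
    objs <- lapply(s@objects, function(o) { o@defocusSigmaPx <- 3; o })
    out <- renderScene(SceneSpec(s@imageShapePx, s@pixelSizeUm,
      s@backgroundLevel, s@illuminationGradient, noiseSigma = 0.08,
      objects = objs, artifacts = s@artifacts, seed = s@seed))
    list(image = out$image, mask = out$mask, scene = s)
  })
  pNoisy <- curveData(evaluateDataset(segAll(noisy), taus = 0.5))$precision
  expect_lte(pNoisy, pClean)
})
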
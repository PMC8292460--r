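test_that("resizePad follows the aspect-preserving 1024 rule", {
  # full-HD frame: scale 1024/1920, content 576 rows, 448 rows of padding
  img <- CalibratedImage(matrix(0.5, 1080, 1920), pixelSizeUm = 2)
  pp <- resizePad(img)
  expect_identical(dim(pp$image), c(1024L, 1024L))
  expect_equal(pp$transform@scale, 1024 / 1920)
  expect_identical(pp$transform@padRows, 448L)
  expect_identical(pp$transform@padCols, 0L)
  expect_equal(pixelSize(pp$image), 2 * 1920 / 1024)
  expect_true(all(imageData(pp$image)[577:1024, ] == 0))

  # already at target size: identity
  img2 <- CalibratedImage(matrix(0.25, 1024, 1024))
  pp2 <- resizePad(img2)
  expect_equal(pp2$transform@scale, 1)
  expect_identical(pp2$transform@padRows, 0L)
  expect_identical(imageData(pp2$image), imageData(img2))

  # upscale: 512 x 256 -> scale 2, content 1024 x 512, 512 columns padded
  pp3 <- resizePad(CalibratedImage(matrix(0.5, 512, 256)))
  expect_equal(pp3$transform@scale, 2)
  expect_identical(pp3$transform@padCols, 512L)
  expect_identical(pp3$transform@padRows, 0L)
})

test_that("unmapMask inverts resizePad within 2% object area", {
  base <- matrix(0L, 1080, 1920)
  base[seq(400, 680), seq(800, 1100)] <- 1L
  orig <- LabelMask(base, pixelSizeUm = 2)
  img <- CalibratedImage(matrix(0.5, 1080, 1920), pixelSizeUm = 2)
  t <- resizePad(img)$transform
  # forward-map the mask with nearest neighbour the way a segmenter sees it
  fwd <- EBImage::resize(maskData(orig), w = 1080 * t@scale,
                         h = round(1920 * t@scale), filter = "none")
  padded <- matrix(0L, 1024, 1024)
  padded[seq_len(nrow(fwd)), seq_len(ncol(fwd))] <- as.integer(fwd)
  back <- unmapMask(LabelMask(padded, pixelSizeUm = 2 / t@scale), t)
  expect_identical(dim(back), c(1080L, 1920L))
  expect_identical(sort(unique(as.vector(maskData(back)))), c(0L, 1L))
  a0 <- sum(maskData(orig) == 1L); a1 <- sum(maskData(back) == 1L)
  expect_lt(abs(a1 - a0) / a0, 0.02)
  expect_equal(pixelSize(back), 2)

  # identity transform round-trips exactly; all-zero stays all-zero
  sq <- matrix(0L, 1024, 1024); sq[100:200, 300:400] <- 1L
  idT <- resizePad(CalibratedImage(matrix(0.1, 1024, 1024)))$transform
  expect_identical(maskData(unmapMask(LabelMask(sq), idT)), sq)
  expect_true(all(maskData(unmapMask(LabelMask(matrix(0L, 1024, 1024)),
                                     t)) == 0L))
  # shape mismatch is an error
  expect_error(unmapMask(LabelMask(matrix(0L, 512, 512)), t), "512 x 512")
})

test_that("otsu segmentation recovers a dark disk with IoU >= 0.9", {
  sc <- SceneSpec(c(256, 256), objects = list(ObjectSpec(c(128, 128), 50)),
                  noiseSigma = 0, seed = 1)
  out <- renderScene(sc)
  seg <- segmentOtsu(out$image)
  expect_identical(nObjects(seg), 1L)
  expect_gte(objectIoU(maskData(seg) == 1L, maskData(out$mask) == 1L), 0.9)
})

test_that("constant images segment to zero objects", {
  img <- CalibratedImage(matrix(0.6, 64, 64))
  expect_identical(nObjects(segmentOtsu(img)), 0L)
  expect_identical(nObjects(segmentWatershed(img)), 0L)
})

test_that("a low-solidity bubble artifact is removed by a solidity filter", {
  obj <- list(ObjectSpec(c(80, 80), 40))
  art <- list(list(kind = "air_bubble", center = c(190, 190), radius = 30,
                   thickness = 7, arcStart = 0.3, arcSpan = 4.7, level = 0.5))
  out <- renderScene(SceneSpec(c(256, 256), objects = obj, artifacts = art,
                               noiseSigma = 0.01, seed = 3))
  permissive <- segmentOtsu(out$image, objectFilterParams(minAreaPx = 50))
  expect_identical(nObjects(permissive), 2L)
  # brute-force check that exactly one segmented object is ring-like
  sols <- vapply(seq_len(2), function(i)
    solidity(maskData(permissive) == i), numeric(1))
  expect_identical(sum(sols < 0.9), 1L)
  strict <- segmentOtsu(out$image,
                        objectFilterParams(minAreaPx = 50, minSolidity = 0.9))
  expect_identical(nObjects(strict), 1L)
  expect_gte(objectIoU(maskData(strict) == 1L, maskData(out$mask) == 1L), 0.9)
})

test_that("watershed splits near-touching disks that otsu merges", {
  sc <- SceneSpec(c(200, 300), objects = list(
    ObjectSpec(c(100, 100), 45, haloGain = 0),
    ObjectSpec(c(100, 191), 45, haloGain = 0)), seed = 1)
  out <- renderScene(sc)
  expect_identical(nObjects(segmentOtsu(out$image)), 1L)
  ws <- segmentWatershed(out$image)
  expect_identical(nObjects(ws), 2L)
  cnt <- matchObjects(ws, out$mask, 0.5)$counts
  expect_identical(cnt@tp, 2L)

  # a single disk still comes out whole with IoU >= 0.9
  single <- renderScene(SceneSpec(c(256, 256),
    objects = list(ObjectSpec(c(128, 128), 50)), seed = 1))
  ws1 <- segmentWatershed(single$image)
  expect_identical(nObjects(ws1), 1L)
  expect_gte(objectIoU(maskData(ws1) == 1L, maskData(single$mask) == 1L), 0.9)
})

test_that("object filters drop out-of-bounds areas and are idempotent", {
  m <- matrix(0L, 1200, 1200)
  m[2:8, 2:9] <- 1L                      # 56 px
  m[20:90, 20:90] <- 2L                  # 5041 px
  m[101:1101, 101:1101] <- 3L            # > 1e6 px
  mask <- LabelMask(m)
  f <- objectFilterParams(minAreaPx = 100, maxAreaPx = 1e5)
  kept <- applyObjectFilters(mask, f)
  expect_identical(nObjects(kept), 1L)
  expect_true(all(maskData(kept)[m == 2L] == 1L))
  expect_identical(maskData(applyObjectFilters(kept, f)), maskData(kept))

  # unbounded filters are the identity up to relabelling
  expect_identical(maskData(applyObjectFilters(mask)), maskData(mask))
  # everything removed leaves an all-zero mask
  none <- applyObjectFilters(mask, objectFilterParams(minAreaPx = 1e7))
  expect_true(all(maskData(none) == 0L))
})

test_that("mask labels stay consecutive and 8-connected through the pipeline", {
  set <- makeBenchmarkSet(3, profile = "default", seed = 31)
  for (e in set) {
    seg <- segmentOtsu(e$image, objectFilterParams(minAreaPx = 20))
    m <- maskData(seg)
    n <- nObjects(seg)
    expect_identical(sort(unique(m[m > 0L])), if (n) seq_len(n) else integer())
    for (i in seq_len(n))
      expect_identical(nObjects(applyObjectFilters(LabelMask(
        matrix(as.integer(m == i), nrow(m), ncol(m))))), 1L)
  }
})

test_that("the segmenter registry delegates and validates", {
  set <- makeBenchmarkSet(1, profile = "clean", seed = 41)
  img <- set[[1]]$image
  gt <- set[[1]]$mask
  # identity-on-ground-truth stub
  registerSegmenter("gt_stub", function(image, ...) gt)
  expect_identical(maskData(runSegmenter("gt_stub", img)), maskData(gt))
  # the registered otsu backend equals a direct call
  expect_identical(maskData(runSegmenter("otsu", img)),
                   maskData(segmentOtsu(img)))
  expect_error(runSegmenter("no_such_backend", img), "unknown segmenter")
  registerSegmenter("bad_shape", function(image, ...)
    LabelMask(matrix(0L, 8, 8)))
  expect_error(runSegmenter("bad_shape", img), "8 x 8")
  registerSegmenter("not_a_mask", function(image, ...) 42)
  expect_error(runSegmenter("not_a_mask", img), "did not return")
})
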
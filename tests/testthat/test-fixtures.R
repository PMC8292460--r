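test_that("rendered disk masks match the per-pixel inside-circle oracle", {
  shape <- c(128, 128)
  for (R in c(20, 35, 50)) {
    spec <- ObjectSpec(c(64, 64), R)
    m <- maskData(renderObjectMask(spec, shape))
    oracle <- oracleDiskMask(shape, c(64, 64), R)
    expect_identical(m == 1L, oracle)
    expect_lt(abs(sum(m) - pi * R^2) / (pi * R^2), 0.015)
  }
})

test_that("minimal-radius object is nonempty and contains its centre", {
  m <- maskData(renderObjectMask(ObjectSpec(c(64, 64), 2), c(128, 128)))
  expect_gt(sum(m), 0)
  expect_identical(m[64, 64], 1L)
})

test_that("object rendering is deterministic and single 8-connected", {
  spec <- ObjectSpec(c(60, 70), 30,
    irregularity = data.frame(order = c(2, 5), amplitude = c(0.2, 0.1),
                              phase = c(0.4, 2.2)))
  m1 <- renderObjectMask(spec, c(128, 128))
  m2 <- renderObjectMask(spec, c(128, 128))
  expect_identical(maskData(m1), maskData(m2))
  expect_identical(max(maskData(m1)), 1L)
  # single 8-connected component containing the centre
  expect_identical(nObjects(applyObjectFilters(m1)), 1L)
  expect_identical(maskData(m1)[60, 70], 1L)
})

test_that("objects that stick out of the image raise a bounds error", {
  expect_error(renderObjectMask(ObjectSpec(c(10, 64), 20), c(128, 128)),
               "beyond image bounds")
  expect_error(renderScene(SceneSpec(c(128, 128),
    objects = list(ObjectSpec(c(5, 64), 20)))), "object 1")
})

test_that("empty scenes are flat gradients with all-zero masks", {
  sc <- SceneSpec(c(64, 96), backgroundLevel = 0.75,
                  illuminationGradient = c(0.1, 0), noiseSigma = 0)
  out <- renderScene(sc)
  expect_true(all(maskData(out$mask) == 0L))
  img <- imageData(out$image)
  # each row is constant; gradient runs down rows
  expect_true(all(apply(img, 1, function(r) diff(range(r))) < 1e-12))
  expect_lt(img[1, 1], img[64, 1])
  expect_equal(mean(img), 0.75, tolerance = 1e-9)
})

test_that("scene masks label disjoint objects 1..n in list order with oracle areas", {
  centers <- list(c(60, 60), c(60, 180), c(180, 120))
  radii <- c(30, 25, 40)
  sc <- SceneSpec(c(240, 240), objects = Map(function(ctr, R)
    ObjectSpec(ctr, R), centers, radii), noiseSigma = 0, seed = 2)
  out <- renderScene(sc)
  m <- maskData(out$mask)
  expect_identical(sort(unique(as.vector(m))), c(0L, 1L, 2L, 3L))
  for (i in 1:3) {
    oracle <- oracleDiskMask(c(240, 240), centers[[i]], radii[i])
    expect_identical(m == i, oracle)
    expect_lt(abs(sum(m == i) - pi * radii[i]^2) / (pi * radii[i]^2), 0.015)
  }
})

test_that("overlapping objects are rejected", {
  sc <- SceneSpec(c(128, 128), objects = list(
    ObjectSpec(c(64, 50), 20), ObjectSpec(c(64, 80), 20)))
  expect_error(renderScene(sc), "overlap")
})

test_that("scene rendering is bit-deterministic including noise", {
  sc <- SceneSpec(c(128, 128), objects = list(ObjectSpec(c(64, 64), 30)),
                  noiseSigma = 0.05, illuminationGradient = c(0.03, -0.06),
                  seed = 99)
  a <- renderScene(sc); b <- renderScene(sc)
  expect_identical(imageData(a$image), imageData(b$image))
  expect_identical(maskData(a$mask), maskData(b$mask))
})

test_that("noise-free renders keep labelled pixels darker than background", {
  sc <- SceneSpec(c(200, 200), objects = list(
    ObjectSpec(c(70, 70), 35), ObjectSpec(c(140, 140), 30,
      irregularity = data.frame(order = 3, amplitude = 0.1, phase = 0))),
    illuminationGradient = c(0.08, 0.05), noiseSigma = 0, seed = 1)
  out <- renderScene(sc)
  img <- imageData(out$image)
  m <- maskData(out$mask)
  bg <- renderScene(SceneSpec(c(200, 200),
    illuminationGradient = c(0.08, 0.05), noiseSigma = 0, seed = 1))
  expect_true(all(img[m > 0L] < imageData(bg$image)[m > 0L]))
})

test_that("artifacts perturb the image but never the mask", {
  obj <- list(ObjectSpec(c(64, 64), 25))
  art <- list(list(kind = "air_bubble", center = c(150, 150), radius = 25,
                   thickness = 6, arcStart = 0.5, arcSpan = 4.5, level = 0.5))
  base <- renderScene(SceneSpec(c(200, 200), objects = obj, seed = 4))
  withArt <- renderScene(SceneSpec(c(200, 200), objects = obj,
                                   artifacts = art, seed = 4))
  expect_identical(maskData(base$mask), maskData(withArt$mask))
  expect_false(identical(imageData(base$image), imageData(withArt$image)))
})

test_that("benchmark sets are deterministic and honour the clean profile", {
  s1 <- makeBenchmarkSet(4, profile = "clean", seed = 11)
  s2 <- makeBenchmarkSet(4, profile = "clean", seed = 11)
  for (i in seq_along(s1)) {
    expect_identical(imageData(s1[[i]]$image), imageData(s2[[i]]$image))
    expect_identical(maskData(s1[[i]]$mask), maskData(s2[[i]]$mask))
  }
  for (e in s1) {
    expect_length(e$scene@artifacts, 0)
    for (o in e$scene@objects) expect_identical(o@defocusSigmaPx, 0)
  }
})

test_that("benchmark object sizes recompute to 200-250 um equivalent diameter", {
  set <- makeBenchmarkSet(8, profile = "round", seed = 21)
  for (e in set) {
    f <- extractFeatures(e$mask)
    expect_true(all(f$equivalent_diameter_um > 200 - 3 &
                    f$equivalent_diameter_um < 250 + 3))
  }
})

test_that("artifact profile guarantees artifacts; scene specs round-trip JSON", {
  set <- makeBenchmarkSet(3, profile = "artifact", seed = 7)
  expect_true(all(vapply(set, function(e) length(e$scene@artifacts),
                         integer(1)) >= 1L))
  tf <- tempfile(fileext = ".json")
  for (e in set[1:2]) {
    writeSceneSpec(e$scene, tf)
    back <- readSceneSpec(tf)
    reRendered <- renderScene(back)
    # JSON carries ~15-16 significant digits, so parameters can move by one
    # ulp; masks must survive exactly, intensities to numerical noise
    expect_identical(maskData(reRendered$mask), maskData(e$mask))
    expect_equal(imageData(reRendered$image), imageData(e$image),
                 tolerance = 1e-9)
  }
})
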
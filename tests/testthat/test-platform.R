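test_that("well centres follow SLAS geometry", {
  p96 <- plateLayout("96well")
  expect_equal(wellCenter(p96, "A1"), c(x_mm = 14.38, y_mm = 11.24))
  expect_equal(wellCenter(p96, "H12"), c(x_mm = 113.38, y_mm = 74.24))
  expect_equal(wellCenter(p96, "B7"),
               c(x_mm = 14.38 + 6 * 9, y_mm = 11.24 + 9))
  expect_error(wellCenter(p96, "Z9"), "outside layout")
  expect_error(wellCenter(p96, "A13"), "outside layout")
  expect_error(wellCenter(p96, "7B"), "malformed")
  p384 <- plateLayout("384well")
  expect_identical(length(wellIds(p384)), 384L)
  expect_equal(unname(wellCenter(p384, "P24") - wellCenter(p384, "A1")),
               c(23 * 4.5, 15 * 4.5))
})

test_that("image-to-stage mapping is a calibrated affine with exact round trip", {
  cal <- calibration(tipPx = c(100, 100), zMinMm = 2, umPerPx = 2)
  # tip pixel is the fixed point
  expect_equal(imageToStage(cal, c(100, 100), c(5, 5)),
               c(x_mm = 5, y_mm = 5))
  # +100 columns at 2 um/px -> +0.2 mm in x
  expect_equal(imageToStage(cal, c(100, 200), c(5, 5)),
               c(x_mm = 5.2, y_mm = 5))
  # sign flip negates the x displacement
  calNeg <- calibration(tipPx = c(100, 100), zMinMm = 2, umPerPx = 2,
                        axisSign = c(-1, 1))
  expect_equal(imageToStage(calNeg, c(100, 200), c(5, 5)),
               c(x_mm = 4.8, y_mm = 5))
  # round trip within 0.5 px on assorted points
  withr::with_seed(3, {
    for (i in 1:20) {
      px <- c(runif(1, 1, 512), runif(1, 1, 512))
      tgt <- imageToStage(cal, px, c(30, 40))
      back <- stageToImage(cal, tgt, c(30, 40))
      expect_lt(max(abs(back - px)), 0.5)
    }
  })
  expect_error(imageToStage(cal, c(NA, 1), c(0, 0)), "finite")
})

test_that("scan tiling covers wells with the expected tile counts", {
  # 10 mm square well, 5 mm field: exact 2x2 tiling; 50% overlap: 3x3
  big <- plateLayout("custom", rows = 1L, cols = 1L, pitchMm = 20,
                     a1OffsetMm = c(30, 30), wellDiameterMm = 10)
  expect_identical(nrow(planScan(big, "A1", fovMm = 5, overlapFraction = 0)), 4L)
  expect_identical(nrow(planScan(big, "A1", fovMm = 5, overlapFraction = 0.5)), 9L)
  # well smaller than the field: single centred tile
  small <- plateLayout("96well")
  one <- planScan(small, "D6", fovMm = 8, overlapFraction = 0)
  expect_identical(nrow(one), 1L)
  expect_equal(c(one$x_mm, one$y_mm), unname(wellCenter(small, "D6")))
  expect_error(planScan(small, "A1", fovMm = 0), "positive")
  expect_error(planScan(small, "A1", fovMm = 3, overlapFraction = 1), "overlap")

  # coverage: every grid point of each well inside at least one tile
  tiles <- planScan(small, c("A1", "B2"), fovMm = 3, overlapFraction = 0.1)
  for (wid in c("A1", "B2")) {
    ctr <- wellCenter(small, wid)
    half <- small@wellDiameterMm / 2
    tw <- tiles[tiles$well == wid, ]
    pts <- expand.grid(x = seq(ctr[1] - half, ctr[1] + half, length.out = 15),
                       y = seq(ctr[2] - half, ctr[2] + half, length.out = 15))
    covered <- vapply(seq_len(nrow(pts)), function(i)
      any(abs(tw$x_mm - pts$x[i]) <= 1.5 + 1e-9 &
          abs(tw$y_mm - pts$y[i]) <= 1.5 + 1e-9), logical(1))
    expect_true(all(covered))
  }
  # serpentine: consecutive rows alternate x direction
  grid <- planScan(big, "A1", fovMm = 3, overlapFraction = 0)
  ys <- unique(grid$y_mm)
  x1 <- grid$x_mm[grid$y_mm == ys[1]]
  x2 <- grid$x_mm[grid$y_mm == ys[2]]
  expect_identical(x2, rev(x1))
})

test_that("transfer plans have the contracted command structure", {
  cal <- calibration(tipPx = c(256, 256), zMinMm = 2, umPerPx = 2)
  tgt <- plateLayout("96well")
  recs <- data.frame(label = 1:2, stage_x_um = c(30000, 31000),
                     stage_y_um = c(20000, 20500))
  plan <- planTransfer(recs, tgt, c("A1", "A2"), cal)
  cmd <- planCommands(plan)
  expect_identical(sum(cmd$op == "Aspirate"), 2L)
  expect_identical(sum(cmd$op == "Dispense"), 2L)
  for (s in 1:2) {
    ia <- which(cmd$op == "Aspirate" & cmd$spheroid == s)
    id <- which(cmd$op == "Dispense" & cmd$spheroid == s)
    expect_lt(ia, id)
    # aspirate and dispense happen right after lowering to the floor
    expect_identical(cmd$op[c(ia - 1L, id - 1L)], rep("PipetteZ", 2))
    expect_equal(cmd$z[c(ia - 1L, id - 1L)], rep(2, 2))
  }
  # final command retracts the pipette
  expect_identical(cmd$op[nrow(cmd)], "PipetteX")
  # no pipette motion below the safe floor
  expect_true(all(cmd$z[cmd$op == "PipetteZ"] >= 2))

  # empty plan is just the retract command
  empty <- planTransfer(NULL, tgt, character(), cal)
  expect_identical(nrow(planCommands(empty)), 1L)
  expect_identical(planCommands(empty)$op, "PipetteX")

  # contract violations
  expect_error(planTransfer(recs, tgt, c("A1", "A2"), cal, volumeUl = 5),
               "outside allowed bounds")
  expect_error(planTransfer(recs, tgt, "A1", cal), "target well")
  noStage <- data.frame(label = 1, stage_x_um = NA_real_,
                        stage_y_um = NA_real_)
  expect_error(planTransfer(noStage, tgt, "A1", cal), "stage coordinates")
})

test_that("plans stay above the pipette floor over randomized inputs", {
  cal <- calibration(tipPx = c(256, 256), zMinMm = 3, umPerPx = 2)
  tgt <- plateLayout("96well")
  withr::with_seed(17, {
    for (rep in 1:10) {
      n <- sample(1:6, 1)
      recs <- data.frame(label = seq_len(n),
                         stage_x_um = runif(n, 0, 8e4),
                         stage_y_um = runif(n, 0, 6e4))
      plan <- planTransfer(recs, tgt, wellIds(tgt)[seq_len(n)], cal,
                           volumeUl = runif(1, 3, 4))
      cmd <- planCommands(plan)
      expect_true(all(cmd$z[cmd$op == "PipetteZ"] >= 3 - 1e-9))
      expect_true(validObject(plan))
    }
  })
})

test_that("gcode emission is deterministic with conserved syringe travel", {
  cal <- calibration(tipPx = c(256, 256), zMinMm = 2, umPerPx = 2)
  tgt <- plateLayout("96well")
  cfg <- gcodeConfig(ulToMm = 0.5)
  # empty plan: header and footer only
  empty <- emitGcode(planTransfer(NULL, tgt, character(), cal), cfg)
  expect_true(any(grepl("^G28", empty)))
  expect_true(any(grepl("^M84", empty)))
  expect_identical(sum(grepl("^G1 E", empty)), 0L)

  recs <- data.frame(label = 1, stage_x_um = 30000, stage_y_um = 20000)
  plan <- planTransfer(recs, tgt, "A1", cal, volumeUl = 3)
  g <- emitGcode(plan, cfg)
  # aspirate 3 ul at 0.5 mm/ul -> E-1.500; stage moves become comments
  expect_identical(sum(grepl("E-1.500", g, fixed = TRUE)), 1L)
  expect_identical(sum(grepl("^; STAGE MOVE", g)), 2L)
  expect_identical(g, emitGcode(plan, cfg))

  # volume conservation: summed aspirated E equals summed dispensed E
  recs4 <- data.frame(label = 1:4, stage_x_um = (1:4) * 1e4,
                      stage_y_um = (1:4) * 5e3)
  g4 <- emitGcode(planTransfer(recs4, tgt, c("A1", "B1", "C1", "D1"), cal,
                               volumeUl = 3.5), cfg)
  asp <- sum(as.numeric(sub("^G1 E-([0-9.]+) .*$", "\\1",
                            grep("^G1 E-", g4, value = TRUE))))
  disp <- sum(as.numeric(sub("^G1 E([0-9.]+) .*$", "\\1",
                             grep("^G1 E[0-9]", g4, value = TRUE))))
  expect_equal(asp, disp)
  expect_error(emitGcode(plan, list(feedXY = 100)), "ulToMm")
  expect_error(gcodeConfig(), "required")
})

test_that("success statistics reproduce the reported transfer rates", {
  # semi-automatic benchmark: 28 attempts, 26 picked up, 25 transferred
  semi <- c(rep("success", 25), "expel_error", rep("pick_up_error", 2))
  s <- successStats(semi)
  expect_identical(s$nAttempts, 28L)
  expect_identical(s$successRatePercent, 89L)
  expect_identical(unname(s$counts["expel_error"]), 1L)
  expect_identical(unname(s$counts["double_pick"]), 0L)
  # fully-automatic benchmark: 30 attempts, 24 successes
  full <- c(rep("success", 24), rep("pick_up_error", 4), "expel_error",
            "double_pick")
  expect_identical(successStats(full)$successRatePercent, 80L)
  # all successes
  expect_identical(successStats(rep("success", 7))$successRatePercent, 100L)
  expect_error(successStats(character()), "empty")
  expect_error(successStats(c("success", "evaporated")), "unknown outcome")
  # data.frame input with object ids
  df <- data.frame(object_id = 1:3,
                   outcome = c("success", "success", "double_pick"))
  expect_identical(successStats(df)$successRatePercent, 67L)
})
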
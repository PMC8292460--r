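# Virtual instrument layer: microplate geometry, image-to-stage calibration,
# serpentine scan tiling, transfer planning, Marlin-dialect G-code emission
# and transfer-outcome statistics.
#
# Axis conventions: stage x runs along image columns, y along rows, both in
# millimetres on the plate; pipette X is the horizontal effector axis and Z
# the vertical axis on the motion controller. The motorized stage sits on a
# separate controller, so stage moves are emitted as structured G-code
# comments rather than an invented protocol.

#' Built-in ANSI/SLAS microplate layouts
#'
#' Standard geometry for 24-, 96- and 384-well plates (9 mm pitch for
#' 96-well, 4.5 mm for 384, 19.3 mm for 24; 127.76 x 85.48 mm footprint).
#' All constants are overridable via the arguments.
#'
#' @param name `"24well"`, `"96well"` or `"384well"`, or any name when all
#'   geometry arguments are supplied.
#' @param rows,cols,pitchMm,a1OffsetMm,wellDiameterMm,footprintMm override
#'   the named defaults.
#' @return a [PlateLayout-class].
#' @examples
#' wellCenter(plateLayout("96well"), "H12")
#' @export
plateLayout <- function(name = "96well", rows = NULL, cols = NULL,
                        pitchMm = NULL, a1OffsetMm = NULL,
                        wellDiameterMm = NULL, footprintMm = NULL) {
  defaults <- list(
    "24well"  = list(rows = 4L, cols = 6L, pitchMm = 19.3,
                     a1OffsetMm = c(15.13, 13.49), wellDiameterMm = 15.6),
    "96well"  = list(rows = 8L, cols = 12L, pitchMm = 9.0,
                     a1OffsetMm = c(14.38, 11.24), wellDiameterMm = 6.35),
    "384well" = list(rows = 16L, cols = 24L, pitchMm = 4.5,
                     a1OffsetMm = c(12.13, 8.99), wellDiameterMm = 3.3))
  d <- defaults[[name]]
  if (is.null(d)) {
    if (is.null(rows) || is.null(cols) || is.null(pitchMm) ||
        is.null(a1OffsetMm) || is.null(wellDiameterMm))
      stop(sprintf("unknown layout '%s'; built-ins: %s (or supply full geometry)",
                   name, paste(names(defaults), collapse = ", ")))
    d <- list()
  }
  new("PlateLayout", name = name,
      rows = as.integer(rows %||% d$rows), cols = as.integer(cols %||% d$cols),
      pitchMm = as.numeric(pitchMm %||% d$pitchMm),
      a1OffsetMm = as.numeric(a1OffsetMm %||% d$a1OffsetMm),
      wellDiameterMm = as.numeric(wellDiameterMm %||% d$wellDiameterMm),
      footprintMm = as.numeric(footprintMm %||% c(127.76, 85.48)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# "B7" -> c(row = 2, col = 7); supports multi-letter rows (AA = 27).
parseWellId <- function(wellId) {
  m <- regmatches(wellId, regexec("^([A-Za-z]+)([0-9]+)$", wellId))[[1]]
  if (length(m) != 3L) stop(sprintf("malformed well id '%s'", wellId))
  letters_ <- toupper(strsplit(m[2], "")[[1]])
  row <- sum((match(letters_, LETTERS)) * 26L^(rev(seq_along(letters_)) - 1L))
  c(row = row, col = as.integer(m[3]))
}

#' Stage coordinates of a well centre
#'
#' @param layout a [PlateLayout-class].
#' @param wellId well identifier such as `"B7"` (letter = row, number =
#'   column).
#' @return named numeric `(x_mm, y_mm)` of the well centre.
#' @examples
#' wellCenter(plateLayout("96well"), "A1")
#' @export
wellCenter <- function(layout, wellId) {
  stopifnot(is(layout, "PlateLayout"))
  rc <- parseWellId(wellId)
  if (rc["row"] < 1L || rc["row"] > layout@rows ||
      rc["col"] < 1L || rc["col"] > layout@cols)
    stop(sprintf("well '%s' outside layout '%s' (%d rows x %d cols)",
                 wellId, layout@name, layout@rows, layout@cols))
  c(x_mm = layout@a1OffsetMm[1] + (rc[["col"]] - 1L) * layout@pitchMm,
    y_mm = layout@a1OffsetMm[2] + (rc[["row"]] - 1L) * layout@pitchMm)
}

#' All well ids of a layout in row-major order
#'
#' @param layout a [PlateLayout-class].
#' @return character vector, `A1, A2, ..`.
#' @export
wellIds <- function(layout) {
  stopifnot(is(layout, "PlateLayout"))
  as.vector(t(outer(LETTERS[seq_len(layout@rows)], seq_len(layout@cols),
                    paste0)))
}

#' Map an image point to the stage position that centres it under the tip
#'
#' The displacement from the calibrated tip pixel to the object pixel is
#' scaled by the pixel size and the axis signs, and added to the current
#' stage position: moving the stage by that displacement brings the object
#' under the capillary tip. [stageToImage()] is the inverse mapping.
#'
#' @param cal a [Calibration-class].
#' @param objectPx `(row, col)` image point.
#' @param currentStageMm `(x, y)` current stage position in mm.
#' @return named numeric `(x_mm, y_mm)` stage target.
#' @examples
#' cal <- calibration(tipPx = c(100, 100), zMinMm = 2, umPerPx = 2)
#' imageToStage(cal, c(100, 200), c(10, 10))  # +0.2 mm in x
#' @export
imageToStage <- function(cal, objectPx, currentStageMm) {
  stopifnot(is(cal, "Calibration"))
  validObject(cal)
  if (length(objectPx) != 2L || any(!is.finite(objectPx)))
    stop("'objectPx' must be finite (row, col)")
  dRow <- objectPx[1] - cal@tipPx[1]
  dCol <- objectPx[2] - cal@tipPx[2]
  c(x_mm = currentStageMm[1] + cal@axisSign[1] * dCol * cal@umPerPx / 1000,
    y_mm = currentStageMm[2] + cal@axisSign[2] * dRow * cal@umPerPx / 1000)
}

#' @rdname imageToStage
#' @param stageTargetMm `(x, y)` stage position to invert.
#' @return `stageToImage()` returns the `(row, col)` image point.
#' @export
stageToImage <- function(cal, stageTargetMm, currentStageMm) {
  stopifnot(is(cal, "Calibration"))
  dX <- (stageTargetMm[1] - currentStageMm[1]) * 1000 / cal@umPerPx
  dY <- (stageTargetMm[2] - currentStageMm[2]) * 1000 / cal@umPerPx
  c(row = cal@tipPx[1] + cal@axisSign[2] * dY,
    col = cal@tipPx[2] + cal@axisSign[1] * dX)
}

#' Plan a serpentine scan over plate wells
#'
#' Tiles each requested well's bounding square (side = well diameter) with
#' camera fields stepped by `fov * (1 - overlap)`, serpentine row order to
#' minimize stage travel. Every point of each well is covered by at least
#' one tile; a well smaller than the field gets a single centred tile.
#'
#' @param layout a [PlateLayout-class].
#' @param wells character vector of well ids.
#' @param fovMm camera field of view in mm (scalar or `(width, height)`).
#' @param overlapFraction tile overlap fraction in `[0, 1)`.
#' @return data.frame with columns `well`, `tile`, `x_mm`, `y_mm` in scan
#'   order.
#' @examples
#' nrow(planScan(plateLayout("96well"), "A1", fovMm = 3, overlapFraction = 0))
#' @export
planScan <- function(layout, wells, fovMm, overlapFraction = 0.1) {
  stopifnot(is(layout, "PlateLayout"))
  if (any(fovMm <= 0)) stop("'fovMm' must be positive")
  if (overlapFraction < 0 || overlapFraction >= 1)
    stop("'overlapFraction' must lie in [0, 1)")
  fov <- if (length(fovMm) == 1L) c(fovMm, fovMm) else as.numeric(fovMm)
  out <- lapply(wells, function(wid) {
    ctr <- unname(wellCenter(layout, wid))
    side <- layout@wellDiameterMm
    step <- fov * (1 - overlapFraction)
    nTiles <- as.integer(ifelse(side <= fov, 1,
                                ceiling((side - fov) / step - 1e-9) + 1))
    # centre the tile block on the well; block extent fov + (n-1)*step >= side
    x0 <- ctr[1] - (nTiles[1] - 1L) * step[1] / 2
    y0 <- ctr[2] - (nTiles[2] - 1L) * step[2] / 2
    rows <- lapply(seq_len(nTiles[2]), function(iy) {
      xs <- x0 + (seq_len(nTiles[1]) - 1L) * step[1]
      if (iy %% 2L == 0L) xs <- rev(xs)  # serpentine
      data.frame(well = wid, x_mm = xs, y_mm = y0 + (iy - 1L) * step[2])
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  data.frame(well = out$well,
             tile = stats::ave(seq_len(nrow(out)), out$well, FUN = seq_along),
             x_mm = out$x_mm, y_mm = out$y_mm)
}

#' Plan the pick-and-place transfer of selected spheroids
#'
#' Emits, per spheroid, the command sequence: centre the object under the
#' tip (stage move), bring the pipette over it, lower to the safe floor,
#' aspirate, lift, move the stage to the target well, lower, dispense, lift.
#' The plan ends by retracting the pipette out of the field of view.
#'
#' @param records data.frame of selected spheroids with `stage_x_um` and
#'   `stage_y_um` columns (e.g. [extractFeatures()] output filtered by
#'   [applyCriteria()]).
#' @param targetLayout a [PlateLayout-class] for the destination plate.
#' @param targetWells character vector of destination well ids (at least as
#'   many as records; used in order).
#' @param cal a [Calibration-class].
#' @param volumeUl aspiration volume per spheroid in microlitres (default
#'   3.5, the midpoint of the standard 3-4 ul carry volume).
#' @param volumeBoundsUl allowed `(low, high)` volume bounds (default
#'   `c(3, 4)`).
#' @param pipetteOverMm pipette X position above the imaging field, mm.
#' @param pipetteRetractMm pipette X park position out of the field, mm.
#' @param zUpMm pipette travel height, mm.
#' @return a [TransferPlan-class].
#' @export
planTransfer <- function(records, targetLayout, targetWells, cal,
                         volumeUl = 3.5, volumeBoundsUl = c(3, 4),
                         pipetteOverMm = 20, pipetteRetractMm = 0,
                         zUpMm = NULL) {
  stopifnot(is(targetLayout, "PlateLayout"), is(cal, "Calibration"))
  n <- if (is.null(records)) 0L else nrow(records)
  if (volumeUl < volumeBoundsUl[1] || volumeUl > volumeBoundsUl[2])
    stop(sprintf("volume %.2f ul outside allowed bounds [%g, %g] ul",
                 volumeUl, volumeBoundsUl[1], volumeBoundsUl[2]))
  if (n > length(targetWells))
    stop(sprintf("%d spheroid(s) but only %d target well(s)", n,
                 length(targetWells)))
  zUp <- zUpMm %||% (cal@zMinMm + 10)
  if (zUp < cal@zMinMm) stop("'zUpMm' is below the safe pipette floor")
  cmd <- function(op, x = NA_real_, y = NA_real_, z = NA_real_,
                  vol = NA_real_, spheroid = NA_integer_)
    data.frame(op = op, x = x, y = y, z = z, vol = vol, spheroid = spheroid)
  rows <- list()
  meta <- list()
  for (i in seq_len(n)) {
    sx <- records$stage_x_um[i]; sy <- records$stage_y_um[i]
    if (is.na(sx) || is.na(sy))
      stop(sprintf("record %d has no stage coordinates; image it with a stage origin",
                   i))
    src <- c(sx, sy) / 1000  # um -> mm
    tgt <- wellCenter(targetLayout, targetWells[i])
    rows <- c(rows, list(
      cmd("MoveStage", x = src[1], y = src[2], spheroid = i),
      cmd("PipetteX", x = pipetteOverMm, spheroid = i),
      cmd("PipetteZ", z = cal@zMinMm, spheroid = i),
      cmd("Aspirate", vol = volumeUl, spheroid = i),
      cmd("PipetteZ", z = zUp, spheroid = i),
      cmd("MoveStage", x = tgt[1], y = tgt[2], spheroid = i),
      cmd("PipetteZ", z = cal@zMinMm, spheroid = i),
      cmd("Dispense", vol = volumeUl, spheroid = i),
      cmd("PipetteZ", z = zUp, spheroid = i)))
    meta[[i]] <- data.frame(spheroid = i, source_x_mm = src[1],
                            source_y_mm = src[2],
                            target_well = targetWells[i])
  }
  rows <- c(rows, list(cmd("PipetteX", x = pipetteRetractMm)))  # retract
  new("TransferPlan", commands = do.call(rbind, rows),
      zMinMm = cal@zMinMm, volumeBoundsUl = as.numeric(volumeBoundsUl),
      meta = if (n) do.call(rbind, meta) else
        data.frame(spheroid = integer(), source_x_mm = numeric(),
                   source_y_mm = numeric(), target_well = character()))
}

#' G-code emission configuration
#'
#' @param ulToMm extruder-axis millimetres per microlitre of the syringe
#'   pump (required; depends on syringe bore and drive).
#' @param feedXY,feedZ,feedE feed rates in mm/min for pipette X, Z and
#'   extruder moves.
#' @return list of settings for [emitGcode()].
#' @export
gcodeConfig <- function(ulToMm, feedXY = 1200, feedZ = 600, feedE = 120) {
  if (missing(ulToMm) || is.null(ulToMm) || !is.finite(ulToMm) || ulToMm <= 0)
    stop("'ulToMm' (extruder mm per microlitre) is required and must be positive")
  list(ulToMm = ulToMm, feedXY = feedXY, feedZ = feedZ, feedE = feedE)
}

#' Emit Marlin-dialect G-code for a transfer plan
#'
#' Pipette X/Z moves map to `G1 X../Z.. F..`; aspirate and dispense map to
#' extruder moves `G1 E.. F..` with distance = volume x `ulToMm` (negative E
#' = intake, positive = expel). Stage moves are emitted as structured
#' comments (`; STAGE MOVE ...`) because the stage runs on a separate
#' controller. Output is deterministic for a given plan and config.
#'
#' @param plan a [TransferPlan-class].
#' @param config from [gcodeConfig()].
#' @return character vector of G-code lines.
#' @examples
#' cal <- calibration(c(100, 100), zMinMm = 2, umPerPx = 2)
#' plan <- planTransfer(NULL, plateLayout("96well"), character(), cal)
#' emitGcode(plan, gcodeConfig(ulToMm = 0.5))
#' @export
emitGcode <- function(plan, config) {
  stopifnot(is(plan, "TransferPlan"))
  validObject(plan)
  if (is.null(config$ulToMm)) stop("'config$ulToMm' is missing")
  num <- function(v) formatC(v, format = "f", digits = 3)
  lines <- c("; spheropick transfer plan",
             sprintf("; spheroids: %d", nrow(plan@meta)),
             "G21 ; millimetre units",
             "G90 ; absolute positioning",
             "M83 ; relative extruder",
             "G28 X Z ; home pipette axes")
  cmdsToLines <- function(r) {
    switch(r$op,
      MoveStage = sprintf("; STAGE MOVE X%s Y%s", num(r$x), num(r$y)),
      PipetteX = sprintf("G1 X%s F%d", num(r$x), as.integer(config$feedXY)),
      PipetteZ = sprintf("G1 Z%s F%d", num(r$z), as.integer(config$feedZ)),
      Aspirate = sprintf("G1 E-%s F%d ; aspirate %.2f ul",
                         num(r$vol * config$ulToMm),
                         as.integer(config$feedE), r$vol),
      Dispense = sprintf("G1 E%s F%d ; dispense %.2f ul",
                         num(r$vol * config$ulToMm),
                         as.integer(config$feedE), r$vol))
  }
  cmd <- plan@commands
  body <- vapply(seq_len(nrow(cmd)), function(i) cmdsToLines(cmd[i, ]),
                 character(1))
  c(lines, body, "M84 ; disable steppers", "; end of plan")
}

#' Transfer success statistics
#'
#' Tallies a transfer outcome log into attempt counts, per-error-type counts
#' and a nearest-integer success-rate percentage.
#'
#' @param log data.frame with an `outcome` column (and optionally
#'   `object_id`), or a character vector of outcomes. Outcomes must be one
#'   of `success`, `pick_up_error`, `expel_error`, `double_pick`.
#' @return list with `nAttempts`, `nSuccess`, `successRatePercent`
#'   (nearest integer) and `counts` (named tally over all four outcomes).
#' @examples
#' log <- c(rep("success", 25), "expel_error", rep("pick_up_error", 2))
#' successStats(log)$successRatePercent  # 89
#' @export
successStats <- function(log) {
  outcomes <- if (is.data.frame(log)) log$outcome else as.character(log)
  if (!length(outcomes)) stop("transfer log is empty")
  valid <- c("success", "pick_up_error", "expel_error", "double_pick")
  bad <- setdiff(unique(outcomes), valid)
  if (length(bad))
    stop(sprintf("unknown outcome(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "), paste(valid, collapse = ", ")))
  counts <- vapply(valid, function(v) sum(outcomes == v), integer(1))
  n <- length(outcomes)
  ns <- counts[["success"]]
  list(nAttempts = n, nSuccess = ns,
       successRatePercent = as.integer(floor(100 * ns / n + 0.5)),
       counts = counts)
}

#' Read a transfer log CSV
#'
#' @param path CSV with columns `object_id`, `outcome`.
#' @return data.frame.
#' @export
readTransferLog <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
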
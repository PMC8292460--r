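#' @import methods
NULL

#' CalibratedImage: a 2D intensity raster with physical pixel size
#'
#' Container for a single-channel brightfield image. Intensities are stored as
#' a numeric matrix in `[0, 1]` (rows = image rows, columns = image columns);
#' `pixelSizeUm` gives the physical edge length of one pixel in micrometres.
#' An optional stage position records where on the motorized stage the image
#' was acquired, so that object centroids can be mapped back to absolute stage
#' coordinates.
#'
#' @slot image numeric matrix of intensities in `[0, 1]`.
#' @slot pixelSizeUm positive scalar, micrometres per pixel.
#' @slot stageUm numeric of length 0 or 2: stage `(x, y)` of pixel (1,1), in
#'   micrometres (x along image columns, y along image rows).
#'
#' @seealso [CalibratedImage()], [LabelMask-class]
#' @export
setClass("CalibratedImage",
  representation(image = "matrix", pixelSizeUm = "numeric", stageUm = "numeric"))

setValidity("CalibratedImage", function(object) {
  msg <- character()
  if (!is.numeric(object@image) || length(dim(object@image)) != 2L)
    msg <- c(msg, "'image' must be a numeric matrix")
  else if (any(!is.finite(object@image)))
    msg <- c(msg, "'image' must contain only finite values")
  else if (min(object@image) < 0 || max(object@image) > 1)
    msg <- c(msg, "'image' intensities must lie in [0, 1]")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be a single positive number")
  if (!length(object@stageUm) %in% c(0L, 2L))
    msg <- c(msg, "'stageUm' must have length 0 or 2")
  if (length(msg)) msg else TRUE
})

#' Create a CalibratedImage
#'
#' @param image numeric matrix of intensities in `[0, 1]`.
#' @param pixelSizeUm micrometres per pixel (default 1).
#' @param stageUm optional stage `(x, y)` of pixel (1,1) in micrometres.
#' @return A [CalibratedImage-class] object.
#' @examples
#' img <- CalibratedImage(matrix(0.75, 64, 64), pixelSizeUm = 2)
#' dim(img)
#' @export
CalibratedImage <- function(image, pixelSizeUm = 1, stageUm = numeric()) {
  storage.mode(image) <- "double"
  new("CalibratedImage", image = image, pixelSizeUm = as.numeric(pixelSizeUm),
      stageUm = as.numeric(stageUm))
}

#' LabelMask: an integer instance mask aligned to an image
#'
#' Each pixel holds the identity of the object covering it: 0 for background,
#' `1..n` for object instances. Labels are consecutive.
#'
#' @slot mask integer matrix, 0 = background, positive values = instances.
#' @slot pixelSizeUm positive scalar, micrometres per pixel.
#'
#' @seealso [LabelMask()], [extractFeatures()]
#' @export
setClass("LabelMask",
  representation(mask = "matrix", pixelSizeUm = "numeric"))

setValidity("LabelMask", function(object) {
  msg <- character()
  if (!is.integer(object@mask) || length(dim(object@mask)) != 2L)
    msg <- c(msg, "'mask' must be an integer matrix")
  else {
    lab <- object@mask[object@mask != 0L]
    if (length(lab) && min(lab) < 0L)
      msg <- c(msg, "labels must be non-negative")
    u <- sort(unique(lab))
    if (length(u) && !identical(u, seq_len(max(u))))
      msg <- c(msg, "labels must be consecutive 1..n")
  }
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Create a LabelMask
#'
#' @param mask integer matrix (0 background, 1..n objects). Non-integer input
#'   is rounded and coerced.
#' @param pixelSizeUm micrometres per pixel (default 1).
#' @return A [LabelMask-class] object.
#' @examples
#' m <- matrix(0L, 32, 32); m[10:20, 10:20] <- 1L
#' LabelMask(m, pixelSizeUm = 2)
#' @export
LabelMask <- function(mask, pixelSizeUm = 1) {
  if (!is.integer(mask)) {
    mask <- round(mask)
    storage.mode(mask) <- "integer"
  }
  new("LabelMask", mask = mask, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' ObjectSpec: parametric description of one synthetic spheroid
#'
#' A spheroid boundary is modelled as a truncated Fourier radial perturbation
#' of a circle, `r(theta) = R * (1 + sum_k a_k cos(k theta + phi_k))` with
#' harmonic orders `k >= 2`. Bounded amplitudes (`sum |a_k| < 0.5`) keep the
#' curve simple, closed and star-shaped around the centre.
#'
#' @slot centerPx numeric `(row, col)` centre in pixel coordinates.
#' @slot radiusPx base radius R in pixels (>= 2).
#' @slot irregularity data.frame with columns `order` (integer k >= 2),
#'   `amplitude` (`[0, 0.3)`) and `phase` (radians); zero rows = perfect disk.
#' @slot interiorLevel interior intensity as a fraction of the local
#'   background (spheroids are darker, so < 1).
#' @slot haloGain brightness gain of the thin bright halo ring just outside
#'   the boundary, as a fraction of local background (0 disables the halo).
#' @slot defocusSigmaPx Gaussian defocus blur scale in pixels (0 = in focus).
#' @export
setClass("ObjectSpec",
  representation(centerPx = "numeric", radiusPx = "numeric",
                 irregularity = "data.frame", interiorLevel = "numeric",
                 haloGain = "numeric", defocusSigmaPx = "numeric"))

setValidity("ObjectSpec", function(object) {
  msg <- character()
  if (length(object@centerPx) != 2L || any(!is.finite(object@centerPx)))
    msg <- c(msg, "'centerPx' must be finite (row, col)")
  if (length(object@radiusPx) != 1L || !is.finite(object@radiusPx) ||
      object@radiusPx < 2)
    msg <- c(msg, "'radiusPx' must be a single number >= 2")
  irr <- object@irregularity
  if (!all(c("order", "amplitude", "phase") %in% names(irr)))
    msg <- c(msg, "'irregularity' needs columns order, amplitude, phase")
  else if (nrow(irr)) {
    if (any(irr$order < 2 | irr$order != round(irr$order)))
      msg <- c(msg, "harmonic orders must be integers >= 2")
    if (any(irr$amplitude < 0 | irr$amplitude >= 0.3))
      msg <- c(msg, "amplitudes must lie in [0, 0.3)")
    if (sum(abs(irr$amplitude)) >= 0.5)
      msg <- c(msg, "sum of |amplitudes| must be < 0.5")
  }
  if (object@interiorLevel < 0 || object@interiorLevel > 1)
    msg <- c(msg, "'interiorLevel' must lie in [0, 1]")
  if (object@haloGain < 0)
    msg <- c(msg, "'haloGain' must be >= 0")
  if (object@defocusSigmaPx < 0)
    msg <- c(msg, "'defocusSigmaPx' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create an ObjectSpec
#'
#' @param centerPx `(row, col)` centre in pixels.
#' @param radiusPx base radius in pixels (>= 2).
#' @param irregularity data.frame (`order`, `amplitude`, `phase`) of Fourier
#'   boundary harmonics; default none (perfect disk).
#' @param interiorLevel interior intensity fraction of local background.
#' @param haloGain halo brightness gain fraction (default 0.1, the bright rim
#'   typical of brightfield spheroids).
#' @param defocusSigmaPx Gaussian defocus sigma in pixels.
#' @return An [ObjectSpec-class].
#' @examples
#' ObjectSpec(c(100, 120), radiusPx = 50)
#' @export
ObjectSpec <- function(centerPx, radiusPx,
                       irregularity = data.frame(order = integer(),
                                                 amplitude = numeric(),
                                                 phase = numeric()),
                       interiorLevel = 0.5, haloGain = 0.1,
                       defocusSigmaPx = 0) {
  new("ObjectSpec", centerPx = as.numeric(centerPx),
      radiusPx = as.numeric(radiusPx), irregularity = irregularity,
      interiorLevel = as.numeric(interiorLevel),
      haloGain = as.numeric(haloGain),
      defocusSigmaPx = as.numeric(defocusSigmaPx))
}

#' SceneSpec: full description of one synthetic brightfield scene
#'
#' Everything needed to render one image/ground-truth pair deterministically:
#' geometry and optics of every object, illumination, artifacts and the noise
#' seed. Identical SceneSpecs (including seed) render bit-identical output.
#'
#' @slot imageShapePx integer `(height, width)` in pixels.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot backgroundLevel background intensity fraction of dynamic range.
#' @slot illuminationGradient numeric `(per-height, per-width)` fractional
#'   intensity change across the image (0 = flat illumination).
#' @slot noiseSigma additive Gaussian noise sigma (intensity fraction).
#' @slot objects list of [ObjectSpec-class].
#' @slot artifacts list of artifact descriptors, each a list with `kind`
#'   in `air_bubble`, `plate_border`, `plastic_defect` plus geometry fields
#'   (see [renderScene()]).
#' @slot seed integer seed for the scene's noise generator.
#' @export
setClass("SceneSpec",
  representation(imageShapePx = "integer", pixelSizeUm = "numeric",
                 backgroundLevel = "numeric",
                 illuminationGradient = "numeric", noiseSigma = "numeric",
                 objects = "list", artifacts = "list", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@imageShapePx) != 2L || any(object@imageShapePx < 1L))
    msg <- c(msg, "'imageShapePx' must be positive (height, width)")
  if (object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be positive")
  if (object@backgroundLevel < 0 || object@backgroundLevel > 1)
    msg <- c(msg, "'backgroundLevel' must lie in [0, 1]")
  if (length(object@illuminationGradient) != 2L)
    msg <- c(msg, "'illuminationGradient' must have length 2")
  if (object@noiseSigma < 0)
    msg <- c(msg, "'noiseSigma' must be >= 0")
  for (i in seq_along(object@objects)) {
    o <- object@objects[[i]]
    if (!is(o, "ObjectSpec")) { msg <- c(msg, "objects must be ObjectSpec"); break }
    ctr <- o@centerPx
    if (ctr[1] < 1 || ctr[1] > object@imageShapePx[1] ||
        ctr[2] < 1 || ctr[2] > object@imageShapePx[2])
      msg <- c(msg, sprintf("object %d centre lies outside image bounds", i))
  }
  for (a in object@artifacts)
    if (!is.list(a) || is.null(a$kind) ||
        !a$kind %in% c("air_bubble", "plate_border", "plastic_defect")) {
      msg <- c(msg, "artifact 'kind' must be air_bubble, plate_border or plastic_defect")
      break
    }
  if (length(object@seed) != 1L)
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Create a SceneSpec
#'
#' @param imageShapePx `(height, width)` in pixels.
#' @param pixelSizeUm micrometres per pixel.
#' @param backgroundLevel background intensity (default 0.75 of dynamic
#'   range, a bright brightfield background).
#' @param illuminationGradient `(per-height, per-width)` fractional change.
#' @param noiseSigma additive Gaussian noise sigma.
#' @param objects list of [ObjectSpec-class].
#' @param artifacts list of artifact descriptors (see [renderScene()]).
#' @param seed integer noise seed.
#' @return A [SceneSpec-class].
#' @export
SceneSpec <- function(imageShapePx, pixelSizeUm = 1, backgroundLevel = 0.75,
                      illuminationGradient = c(0, 0), noiseSigma = 0,
                      objects = list(), artifacts = list(), seed = 1L) {
  new("SceneSpec", imageShapePx = as.integer(imageShapePx),
      pixelSizeUm = as.numeric(pixelSizeUm),
      backgroundLevel = as.numeric(backgroundLevel),
      illuminationGradient = as.numeric(illuminationGradient),
      noiseSigma = as.numeric(noiseSigma), objects = objects,
      artifacts = artifacts, seed = as.integer(seed))
}

#' PreprocessTransform: record of a resize-and-pad preprocessing step
#'
#' Stores the scale and zero-padding applied by [resizePad()] so that masks
#' predicted on the preprocessed frame can be mapped back to the original
#' geometry with [unmapMask()].
#'
#' @slot scale scale ratio applied to the original image.
#' @slot padRows rows of zero padding added at the bottom.
#' @slot padCols columns of zero padding added at the right.
#' @slot originalShape integer `(height, width)` of the original image.
#' @export
setClass("PreprocessTransform",
  representation(scale = "numeric", padRows = "integer", padCols = "integer",
                 originalShape = "integer"))

setValidity("PreprocessTransform", function(object) {
  msg <- character()
  if (object@scale <= 0) msg <- c(msg, "'scale' must be positive")
  if (object@padRows < 0L || object@padCols < 0L)
    msg <- c(msg, "padding must be non-negative")
  if (length(object@originalShape) != 2L || any(object@originalShape < 1L))
    msg <- c(msg, "'originalShape' must be positive (height, width)")
  if (length(msg)) msg else TRUE
})

#' ObjectFilterParams: bounds for post-segmentation object filtering
#'
#' Objects outside the area bounds or below the shape bounds are removed by
#' [applyObjectFilters()]; this mirrors the standard practice of discarding
#' too-small, too-large or irregular blobs after classical segmentation.
#'
#' @slot minAreaPx minimum object area, pixels.
#' @slot maxAreaPx maximum object area, pixels.
#' @slot minSolidity minimum solidity in `[0, 1]` (low values keep ring- or
#'   streak-shaped artifacts).
#' @slot minCircularity minimum circularity in `[0, 1]`.
#' @export
setClass("ObjectFilterParams",
  representation(minAreaPx = "numeric", maxAreaPx = "numeric",
                 minSolidity = "numeric", minCircularity = "numeric"))

setValidity("ObjectFilterParams", function(object) {
  msg <- character()
  if (object@minAreaPx < 0) msg <- c(msg, "'minAreaPx' must be >= 0")
  if (object@maxAreaPx <= object@minAreaPx)
    msg <- c(msg, "'minAreaPx' must be < 'maxAreaPx'")
  if (object@minSolidity < 0 || object@minSolidity > 1)
    msg <- c(msg, "'minSolidity' must lie in [0, 1]")
  if (object@minCircularity < 0 || object@minCircularity > 1)
    msg <- c(msg, "'minCircularity' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Create ObjectFilterParams
#'
#' Defaults are permissive (no filtering beyond empty-object removal).
#'
#' @param minAreaPx,maxAreaPx area bounds in pixels.
#' @param minSolidity,minCircularity shape bounds in `[0, 1]`.
#' @return An [ObjectFilterParams-class].
#' @examples
#' objectFilterParams(minAreaPx = 100, maxAreaPx = 1e5, minSolidity = 0.9)
#' @export
objectFilterParams <- function(minAreaPx = 0, maxAreaPx = Inf,
                               minSolidity = 0, minCircularity = 0) {
  new("ObjectFilterParams", minAreaPx = as.numeric(minAreaPx),
      maxAreaPx = as.numeric(maxAreaPx), minSolidity = as.numeric(minSolidity),
      minCircularity = as.numeric(minCircularity))
}

#' SelectionCriteria: per-feature interval criteria for spheroid selection
#'
#' Each named interval constrains one feature column of a feature table
#' (closed, inclusive bounds; `NA` = unbounded). An optional preferred value
#' ranks the selected set by absolute distance to a target; an optional cap
#' truncates the ranked list.
#'
#' @slot intervals named list; each element `c(min, max)` (NA = unbounded).
#' @slot preferredFeature character (length 0 or 1): feature used to rank.
#' @slot preferredValue numeric (length 0 or 1): target value for ranking.
#' @slot maxCount integer (length 0 or 1): cap on the number selected.
#' @export
setClass("SelectionCriteria",
  representation(intervals = "list", preferredFeature = "character",
                 preferredValue = "numeric", maxCount = "integer"))

setValidity("SelectionCriteria", function(object) {
  msg <- character()
  iv <- object@intervals
  if (length(iv) && (is.null(names(iv)) || any(!nzchar(names(iv)))))
    msg <- c(msg, "intervals must be named by feature")
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2L)
      msg <- c(msg, sprintf("interval '%s' must be c(min, max)", nm))
    else if (!is.na(v[1]) && !is.na(v[2]) && v[1] > v[2])
      msg <- c(msg, sprintf("interval '%s' has min > max", nm))
  }
  if (length(object@preferredFeature) != length(object@preferredValue))
    msg <- c(msg, "preferred feature and value must both be set or both empty")
  if (length(object@maxCount) && object@maxCount < 0L)
    msg <- c(msg, "'maxCount' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create SelectionCriteria
#'
#' @param ... named interval criteria; each either `c(min, max)` or a list
#'   with elements `min` and/or `max` (e.g. `area_um2 = c(21000, 29000)`,
#'   `circularity = c(0.815, NA)`).
#' @param preferred optional `list(feature =, value =)` target for ranking.
#' @param maxCount optional cap on the number of selected records.
#' @return A [SelectionCriteria-class].
#' @examples
#' selectionCriteria(area_um2 = c(21000, 29000), circularity = c(0.815, NA))
#' @export
selectionCriteria <- function(..., preferred = NULL, maxCount = NULL) {
  iv <- list(...)
  iv <- lapply(iv, function(v) {
    if (is.list(v)) {
      lo <- if (is.null(v$min)) NA_real_ else as.numeric(v$min)
      hi <- if (is.null(v$max)) NA_real_ else as.numeric(v$max)
      c(lo, hi)
    } else as.numeric(v)
  })
  new("SelectionCriteria", intervals = iv,
      preferredFeature = if (is.null(preferred)) character() else preferred$feature,
      preferredValue = if (is.null(preferred)) numeric() else as.numeric(preferred$value),
      maxCount = if (is.null(maxCount)) integer() else as.integer(maxCount))
}

#' SelectionReport: outcome of applying selection criteria
#'
#' @slot selected data.frame of selected records in final (possibly ranked)
#'   order.
#' @slot rejected data.frame of rejected records with a `reason` column
#'   naming the first failed criterion.
#' @slot summary data.frame with per-feature `mean` and `sd` of the selected
#'   set (sample sd, n-1 denominator).
#' @export
setClass("SelectionReport",
  representation(selected = "data.frame", rejected = "data.frame",
                 summary = "data.frame"))

#' EvalCounts: matched-object counts at one IoU threshold
#'
#' True positives are predicted objects matched one-to-one to ground-truth
#' objects at IoU at or above the threshold; false positives are unmatched
#' predictions; false negatives are unmatched ground-truth objects
#' ("Positive" = all ground-truth objects, so `tp + fn = nGt`).
#'
#' @slot tp,fp,fn integer counts.
#' @slot nGt integer ground-truth object count.
#' @slot iouThreshold matching threshold in `(0, 1)`.
#' @seealso [matchObjects()], [precisionScore()], [sensitivityScore()]
#' @export
setClass("EvalCounts",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 nGt = "integer", iouThreshold = "numeric"))

setValidity("EvalCounts", function(object) {
  msg <- character()
  if (any(c(object@tp, object@fp, object@fn, object@nGt) < 0L))
    msg <- c(msg, "counts must be >= 0")
  if (object@tp + object@fn != object@nGt)
    msg <- c(msg, "tp + fn must equal nGt")
  if (object@iouThreshold <= 0 || object@iouThreshold >= 1)
    msg <- c(msg, "'iouThreshold' must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Create an EvalCounts object
#'
#' @param tp,fp,fn true-positive, false-positive and false-negative counts.
#' @param iouThreshold matching IoU threshold in `(0, 1)`.
#' @return An [EvalCounts-class]; `nGt` is derived as `tp + fn`.
#' @examples
#' evalCounts(tp = 3, fp = 1, fn = 0, iouThreshold = 0.5)
#' @export
evalCounts <- function(tp, fp, fn, iouThreshold = 0.5) {
  new("EvalCounts", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), nGt = as.integer(tp + fn),
      iouThreshold = as.numeric(iouThreshold))
}

#' EvalCurve: precision/sensitivity across an IoU threshold grid
#'
#' @slot curve data.frame with columns `tau`, `precision`, `sensitivity`,
#'   `classical_precision`, `tp`, `fp`, `fn`.
#' @slot scope `"pooled"` (counts summed over images before scoring) or
#'   `"per_image"` (per-image scores averaged).
#' @seealso [evaluateDataset()]
#' @export
setClass("EvalCurve",
  representation(curve = "data.frame", scope = "character"))

#' PlateLayout: microplate well geometry
#'
#' ANSI/SLAS-style description of a rectangular well grid: well-to-well pitch
#' and the offset of well A1 from the plate origin (top-left corner; x along
#' columns, y along rows, in millimetres).
#'
#' @slot name layout name.
#' @slot rows,cols well grid dimensions.
#' @slot pitchMm well-to-well spacing in mm.
#' @slot a1OffsetMm `(x, y)` of well A1 centre from the plate origin, mm.
#' @slot wellDiameterMm well diameter in mm.
#' @slot footprintMm plate footprint `(width, height)` in mm.
#' @seealso [plateLayout()], [wellCenter()]
#' @export
setClass("PlateLayout",
  representation(name = "character", rows = "integer", cols = "integer",
                 pitchMm = "numeric", a1OffsetMm = "numeric",
                 wellDiameterMm = "numeric", footprintMm = "numeric"))

setValidity("PlateLayout", function(object) {
  msg <- character()
  if (object@rows < 1L || object@cols < 1L)
    msg <- c(msg, "rows and cols must be >= 1")
  if (object@pitchMm <= 0) msg <- c(msg, "'pitchMm' must be positive")
  if (length(object@a1OffsetMm) != 2L)
    msg <- c(msg, "'a1OffsetMm' must be (x, y)")
  if (length(object@footprintMm) != 2L)
    msg <- c(msg, "'footprintMm' must be (width, height)")
  else {
    r <- object@wellDiameterMm / 2
    xmax <- object@a1OffsetMm[1] + (object@cols - 1L) * object@pitchMm + r
    ymax <- object@a1OffsetMm[2] + (object@rows - 1L) * object@pitchMm + r
    if (xmax > object@footprintMm[1] + 1e-9 || ymax > object@footprintMm[2] + 1e-9)
      msg <- c(msg, "wells extend beyond the plate footprint")
    if (object@a1OffsetMm[1] - r < -1e-9 || object@a1OffsetMm[2] - r < -1e-9)
      msg <- c(msg, "well A1 extends beyond the plate origin")
  }
  if (length(msg)) msg else TRUE
})

#' Calibration: image-to-stage mapping for the capillary tip
#'
#' Produced by the calibration step in which the capillary tip is driven into
#' the camera field and its pixel position registered. Together with the
#' pixel size and axis orientation this maps any image point to the stage
#' displacement that brings it under the tip.
#'
#' @slot tipPx `(row, col)` pixel where the capillary tip appears.
#' @slot zMinMm lowest safe pipette height, mm.
#' @slot umPerPx micrometres per pixel.
#' @slot axisSign `(col-to-x, row-to-y)` signs, each +1 or -1.
#' @slot zTravelMm `(low, high)` actuator range, mm.
#' @seealso [imageToStage()]
#' @export
setClass("Calibration",
  representation(tipPx = "numeric", zMinMm = "numeric", umPerPx = "numeric",
                 axisSign = "numeric", zTravelMm = "numeric"))

setValidity("Calibration", function(object) {
  msg <- character()
  if (length(object@tipPx) != 2L || any(!is.finite(object@tipPx)))
    msg <- c(msg, "'tipPx' must be finite (row, col)")
  if (length(object@umPerPx) != 1L || object@umPerPx <= 0)
    msg <- c(msg, "'umPerPx' must be a single positive number")
  if (!all(object@axisSign %in% c(-1, 1)) || length(object@axisSign) != 2L)
    msg <- c(msg, "'axisSign' must be two values of +1 or -1")
  if (length(object@zTravelMm) != 2L || object@zTravelMm[1] > object@zTravelMm[2])
    msg <- c(msg, "'zTravelMm' must be (low, high)")
  else if (object@zMinMm < object@zTravelMm[1] || object@zMinMm > object@zTravelMm[2])
    msg <- c(msg, "'zMinMm' must lie within 'zTravelMm'")
  if (length(msg)) msg else TRUE
})

#' Create a Calibration
#'
#' @param tipPx `(row, col)` pixel position of the capillary tip.
#' @param zMinMm lowest safe pipette height in mm.
#' @param umPerPx micrometres per pixel.
#' @param axisSign `(col-to-x, row-to-y)` signs.
#' @param zTravelMm actuator `(low, high)` range in mm.
#' @return A [Calibration-class].
#' @examples
#' calibration(tipPx = c(256, 256), zMinMm = 2, umPerPx = 2)
#' @export
calibration <- function(tipPx, zMinMm, umPerPx, axisSign = c(1, 1),
                        zTravelMm = c(0, 50)) {
  new("Calibration", tipPx = as.numeric(tipPx), zMinMm = as.numeric(zMinMm),
      umPerPx = as.numeric(umPerPx), axisSign = as.numeric(axisSign),
      zTravelMm = as.numeric(zTravelMm))
}

#' TransferPlan: ordered abstract instrument commands
#'
#' A transfer plan is an ordered command table; each row is one of
#' `MoveStage(x, y)`, `PipetteX(mm)`, `PipetteZ(mm)`, `Aspirate(ul)` or
#' `Dispense(ul)`. The plan invariants guarantee physical sanity: one
#' aspirate before one dispense per spheroid, no pipette motion below the
#' safe height, and aspiration volumes within the configured bounds.
#'
#' @slot commands data.frame with columns `op`, `x`, `y`, `z`, `vol`,
#'   `spheroid` (NA where not applicable).
#' @slot zMinMm safe pipette height the plan was built against.
#' @slot volumeBoundsUl allowed `(low, high)` aspiration volume, microlitres.
#' @slot meta data.frame with one row per spheroid: `spheroid`,
#'   `source_x_mm`, `source_y_mm`, `target_well`.
#' @seealso [planTransfer()], [emitGcode()]
#' @export
setClass("TransferPlan",
  representation(commands = "data.frame", zMinMm = "numeric",
                 volumeBoundsUl = "numeric", meta = "data.frame"))

setValidity("TransferPlan", function(object) {
  msg <- character()
  cmd <- object@commands
  need <- c("op", "x", "y", "z", "vol", "spheroid")
  if (!all(need %in% names(cmd)))
    return("'commands' must have columns op, x, y, z, vol, spheroid")
  ops <- c("MoveStage", "PipetteX", "PipetteZ", "Aspirate", "Dispense")
  if (nrow(cmd) && !all(cmd$op %in% ops))
    msg <- c(msg, "unknown command op")
  zc <- cmd$z[cmd$op == "PipetteZ"]
  if (length(zc) && any(zc < object@zMinMm - 1e-9))
    msg <- c(msg, "a PipetteZ command moves below zMinMm")
  for (s in unique(stats::na.omit(cmd$spheroid))) {
    ia <- which(cmd$op == "Aspirate" & cmd$spheroid == s)
    id <- which(cmd$op == "Dispense" & cmd$spheroid == s)
    if (length(ia) != 1L || length(id) != 1L)
      msg <- c(msg, sprintf("spheroid %s must have exactly one Aspirate and one Dispense", s))
    else if (ia > id)
      msg <- c(msg, sprintf("spheroid %s dispenses before aspirating", s))
  }
  v <- cmd$vol[cmd$op == "Aspirate"]
  if (length(v) && (any(v < object@volumeBoundsUl[1] - 1e-9) ||
                    any(v > object@volumeBoundsUl[2] + 1e-9)))
    msg <- c(msg, "aspirate volume outside configured bounds")
  if (length(msg)) msg else TRUE
})
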
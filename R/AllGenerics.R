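#' Pixel size accessor
#'
#' Physical pixel edge length in micrometres per pixel.
#'
#' @param x a [CalibratedImage-class] or [LabelMask-class].
#' @return numeric scalar, micrometres per pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "CalibratedImage", function(x) x@pixelSizeUm)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "LabelMask", function(x) x@pixelSizeUm)

#' Stage position accessor
#'
#' @param x a [CalibratedImage-class].
#' @return numeric `(x, y)` stage position of pixel (1,1) in micrometres, or
#'   `numeric(0)` if unset.
#' @export
setGeneric("stagePosition", function(x) standardGeneric("stagePosition"))

#' @rdname stagePosition
#' @export
setMethod("stagePosition", "CalibratedImage", function(x) x@stageUm)

#' Raw pixel data accessors
#'
#' `imageData()` returns the intensity matrix of a [CalibratedImage-class];
#' `maskData()` returns the integer label matrix of a [LabelMask-class].
#'
#' @param x the object.
#' @return a matrix.
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname imageData
#' @export
setMethod("imageData", "CalibratedImage", function(x) x@image)

#' @rdname imageData
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' @rdname imageData
#' @export
setMethod("maskData", "LabelMask", function(x) x@mask)

#' Number of labelled objects in a mask
#'
#' @param x a [LabelMask-class].
#' @return integer count of object instances.
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname nObjects
#' @export
setMethod("nObjects", "LabelMask", function(x) {
  m <- x@mask
  if (all(m == 0L)) 0L else max(m)
})

#' @export
setMethod("dim", "CalibratedImage", function(x) dim(x@image))

#' @export
setMethod("dim", "LabelMask", function(x) dim(x@mask))

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@image)
  cat(sprintf("CalibratedImage: %d x %d px, %.4g um/px", d[1], d[2],
              object@pixelSizeUm))
  if (length(object@stageUm))
    cat(sprintf(", stage (%.1f, %.1f) um", object@stageUm[1], object@stageUm[2]))
  cat(sprintf("\n  intensity range [%.3f, %.3f]\n",
              min(object@image), max(object@image)))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("LabelMask: %d x %d px, %.4g um/px, %d object(s)\n",
              d[1], d[2], object@pixelSizeUm, nObjects(object)))
})

setMethod("show", "ObjectSpec", function(object) {
  cat(sprintf(
    "ObjectSpec: centre (%.1f, %.1f), R = %.1f px, %d harmonic(s), defocus %.1f px\n",
    object@centerPx[1], object@centerPx[2], object@radiusPx,
    nrow(object@irregularity), object@defocusSigmaPx))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d x %d px @ %.4g um/px, %d object(s), %d artifact(s), noise %.3f, seed %d\n",
    object@imageShapePx[1], object@imageShapePx[2], object@pixelSizeUm,
    length(object@objects), length(object@artifacts), object@noiseSigma,
    object@seed))
})

setMethod("show", "PreprocessTransform", function(object) {
  cat(sprintf(
    "PreprocessTransform: scale %.5f, pad (%d rows, %d cols), original %d x %d\n",
    object@scale, object@padRows, object@padCols,
    object@originalShape[1], object@originalShape[2]))
})

setMethod("show", "EvalCounts", function(object) {
  cat(sprintf("EvalCounts @ IoU >= %.2f: tp = %d, fp = %d, fn = %d (nGt = %d)\n",
              object@iouThreshold, object@tp, object@fp, object@fn, object@nGt))
})

setMethod("show", "EvalCurve", function(object) {
  cat(sprintf("EvalCurve (%s scope), %d threshold(s):\n", object@scope,
              nrow(object@curve)))
  print(object@curve, row.names = FALSE, digits = 4)
})

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport: %d selected, %d rejected\n",
              nrow(object@selected), nrow(object@rejected)))
  if (nrow(object@summary)) {
    cat("  selected-set summary:\n")
    print(object@summary, row.names = FALSE, digits = 6)
  }
})

setMethod("show", "PlateLayout", function(object) {
  cat(sprintf("PlateLayout '%s': %d x %d wells, pitch %.2f mm, A1 at (%.2f, %.2f) mm\n",
              object@name, object@rows, object@cols, object@pitchMm,
              object@a1OffsetMm[1], object@a1OffsetMm[2]))
})

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: tip at (%.1f, %.1f) px, %.4g um/px, z floor %.2f mm\n",
              object@tipPx[1], object@tipPx[2], object@umPerPx, object@zMinMm))
})

setMethod("show", "TransferPlan", function(object) {
  cat(sprintf("TransferPlan: %d command(s), %d spheroid(s), z floor %.2f mm\n",
              nrow(object@commands), nrow(object@meta), object@zMinMm))
})

#' Selection report accessors
#'
#' @param x a [SelectionReport-class].
#' @return `selected()`/`rejected()` return data.frames of records;
#'   `selectionSummary()` the per-feature mean/sd table of the selected set.
#' @export
setGeneric("selected", function(x) standardGeneric("selected"))

#' @rdname selected
#' @export
setMethod("selected", "SelectionReport", function(x) x@selected)

#' @rdname selected
#' @export
setGeneric("rejected", function(x) standardGeneric("rejected"))

#' @rdname selected
#' @export
setMethod("rejected", "SelectionReport", function(x) x@rejected)

#' @rdname selected
#' @export
setGeneric("selectionSummary", function(x) standardGeneric("selectionSummary"))

#' @rdname selected
#' @export
setMethod("selectionSummary", "SelectionReport", function(x) x@summary)

#' Evaluation curve accessor
#'
#' @param x an [EvalCurve-class].
#' @return data.frame with columns `tau`, `precision`, `sensitivity`,
#'   `classical_precision`, `tp`, `fp`, `fn`.
#' @export
setGeneric("curveData", function(x) standardGeneric("curveData"))

#' @rdname curveData
#' @export
setMethod("curveData", "EvalCurve", function(x) x@curve)

#' Transfer plan command table accessor
#'
#' @param x a [TransferPlan-class].
#' @return data.frame of ordered commands.
#' @export
setGeneric("planCommands", function(x) standardGeneric("planCommands"))

#' @rdname planCommands
#' @export
setMethod("planCommands", "TransferPlan", function(x) x@commands)
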
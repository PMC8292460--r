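# Classical instance segmentation: resize/pad preprocessing, Otsu and
# watershed pipelines, object filters, and a pluggable segmenter registry.
# The standard image operations (Gaussian smoothing, Otsu threshold, hole
# filling, distance transform, watershed, resampling) are delegated to
# EBImage; labelling is 8-connected (see label8 in utils.R).

#' Downscale an image to fit 1024 x 1024 with aspect ratio kept
#'
#' Rescales by `targetPx / max(height, width)` (bilinear), anchors the
#' content at the top-left and zero-pads right/bottom to exactly
#' `targetPx x targetPx`. The physical pixel size is rescaled by the inverse
#' factor so morphometrics stay in true units. The returned transform lets
#' [unmapMask()] take predictions back to the original geometry.
#'
#' @param image a [CalibratedImage-class].
#' @param targetPx output side length in pixels (default 1024).
#' @return list with `image` (preprocessed [CalibratedImage-class]) and
#'   `transform` ([PreprocessTransform-class]).
#' @examples
#' img <- CalibratedImage(matrix(0.5, 1080, 1920), pixelSizeUm = 2)
#' pp <- resizePad(img)
#' dim(pp$image); pp$transform
#' @export
resizePad <- function(image, targetPx = 1024L) {
  stopifnot(is(image, "CalibratedImage"))
  m <- imageData(image)
  h <- nrow(m); w <- ncol(m)
  stopifnot(h >= 1, w >= 1)
  scale <- targetPx / max(h, w)
  nh <- as.integer(round(h * scale)); nw <- as.integer(round(w * scale))
  content <- if (nh == h && nw == w) m else
    EBImage::resize(m, w = nh, h = nw)  # EBImage: first dim, second dim
  content <- clamp01(content)
  out <- matrix(0, targetPx, targetPx)
  out[seq_len(nh), seq_len(nw)] <- content
  t <- new("PreprocessTransform", scale = scale,
           padRows = as.integer(targetPx - nh),
           padCols = as.integer(targetPx - nw),
           originalShape = c(h, w))
  list(image = CalibratedImage(out, pixelSizeUm = image@pixelSizeUm / scale,
                               stageUm = image@stageUm),
       transform = t)
}

#' Map a mask predicted on the preprocessed frame back to original geometry
#'
#' Strips the zero padding and rescales with nearest-neighbour interpolation
#' (label identities preserved exactly).
#'
#' @param mask [LabelMask-class] on the preprocessed (padded) frame.
#' @param transform the [PreprocessTransform-class] from [resizePad()].
#' @param targetPx side length the transform was built for (default 1024).
#' @return [LabelMask-class] at the original image shape.
#' @export
unmapMask <- function(mask, transform, targetPx = 1024L) {
  stopifnot(is(mask, "LabelMask"), is(transform, "PreprocessTransform"))
  m <- maskData(mask)
  if (!identical(dim(m), c(as.integer(targetPx), as.integer(targetPx))))
    stop(sprintf("mask is %d x %d but the transform expects %d x %d",
                 nrow(m), ncol(m), targetPx, targetPx))
  nh <- targetPx - transform@padRows
  nw <- targetPx - transform@padCols
  content <- m[seq_len(nh), seq_len(nw), drop = FALSE]
  os <- transform@originalShape
  if (!identical(c(nh, nw), os)) {
    content <- EBImage::resize(content, w = os[1], h = os[2], filter = "none")
    content <- matrix(as.integer(content), os[1], os[2])
  }
  LabelMask(content, pixelSizeUm = mask@pixelSizeUm * transform@scale)
}

# Shared foreground extraction: luminance -> optional smoothing -> Otsu
# threshold -> darker (or brighter) side -> hole filling. Returns binary
# matrix, or NULL for blank/constant images.
otsuForeground <- function(image, smoothSigma, darkForeground) {
  m <- imageData(image)
  if (diff(range(m)) < 1e-12) return(NULL)
  sm <- if (smoothSigma > 0) EBImage::gblur(m, sigma = smoothSigma) else m
  sm <- clamp01(sm)
  th <- EBImage::otsu(sm, range = c(0, 1))
  fg <- if (darkForeground) sm < th else sm > th
  if (!any(fg)) return(NULL)
  fg <- EBImage::fillHull(matrix(as.numeric(fg), nrow(fg), ncol(fg)))
  fg > 0
}

#' Otsu threshold segmentation
#'
#' Global Otsu threshold on the (optionally Gaussian-smoothed) image, keeping
#' the darker side as foreground (brightfield polarity; set
#' `darkForeground = FALSE` to invert), filling holes, labelling 8-connected
#' components and applying the object filters.
#'
#' @param image a [CalibratedImage-class] (grayscale; convert RGB with
#'   [readCalibratedImage()] which applies Rec.709 luminance).
#' @param filters an [ObjectFilterParams-class] (default permissive).
#' @param smoothSigma Gaussian pre-smoothing sigma in pixels (default 2;
#'   stabilizes the threshold under noise).
#' @param darkForeground if `TRUE` (default) objects are darker than
#'   background.
#' @return a [LabelMask-class]. Blank/constant images give an empty mask.
#' @examples
#' sc <- renderScene(SceneSpec(c(128, 128),
#'   objects = list(ObjectSpec(c(64, 64), 25)), seed = 1))
#' nObjects(segmentOtsu(sc$image))
#' @export
segmentOtsu <- function(image, filters = objectFilterParams(),
                        smoothSigma = 2, darkForeground = TRUE) {
  stopifnot(is(image, "CalibratedImage"))
  fg <- otsuForeground(image, smoothSigma, darkForeground)
  if (is.null(fg))
    return(LabelMask(matrix(0L, nrow(imageData(image)), ncol(imageData(image))),
                     pixelSizeUm = image@pixelSizeUm))
  lab <- label8(fg)
  applyObjectFilters(LabelMask(lab, pixelSizeUm = image@pixelSizeUm), filters)
}

#' Watershed segmentation
#'
#' Otsu foreground (as in [segmentOtsu()]) followed by a distance transform
#' and watershed splitting seeded at distance-map maxima, so touching
#' spheroids merged by thresholding are separated.
#'
#' @inheritParams segmentOtsu
#' @param minSeedSepPx neighbourhood radius (pixels) within which distance
#'   maxima are merged into one seed; larger values split less (default 10).
#' @param tolerance minimum distance-map depth between two objects (passed
#'   to [EBImage::watershed()]).
#' @return a [LabelMask-class].
#' @export
segmentWatershed <- function(image, filters = objectFilterParams(),
                             smoothSigma = 2, darkForeground = TRUE,
                             minSeedSepPx = 10, tolerance = 1) {
  stopifnot(is(image, "CalibratedImage"))
  fg <- otsuForeground(image, smoothSigma, darkForeground)
  if (is.null(fg))
    return(LabelMask(matrix(0L, nrow(imageData(image)), ncol(imageData(image))),
                     pixelSizeUm = image@pixelSizeUm))
  d <- EBImage::distmap(matrix(as.numeric(fg), nrow(fg), ncol(fg)))
  ws <- EBImage::watershed(d, tolerance = tolerance, ext = minSeedSepPx)
  lab <- matrix(as.integer(ws), nrow(ws), ncol(ws))
  # watershed output already labels objects; renumber consecutively
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) && !identical(u, seq_along(u)))
    lab[lab > 0L] <- match(lab[lab > 0L], u)
  applyObjectFilters(LabelMask(lab, pixelSizeUm = image@pixelSizeUm), filters)
}

#' Remove objects failing area or shape bounds
#'
#' Objects with pixel area outside `[minAreaPx, maxAreaPx]`, solidity below
#' `minSolidity` or circularity below `minCircularity` are removed; survivors
#' are relabelled `1..m` preserving their original order. Applying the same
#' filters twice is a no-op.
#'
#' @param mask a [LabelMask-class].
#' @param filters an [ObjectFilterParams-class].
#' @return filtered [LabelMask-class].
#' @examples
#' m <- matrix(0L, 40, 40); m[2:3, 2:3] <- 1L; m[10:30, 10:30] <- 2L
#' nObjects(applyObjectFilters(LabelMask(m),
#'   objectFilterParams(minAreaPx = 100, maxAreaPx = 1e5)))
#' @export
applyObjectFilters <- function(mask, filters = objectFilterParams()) {
  stopifnot(is(mask, "LabelMask"), is(filters, "ObjectFilterParams"))
  m <- maskData(mask)
  n <- nObjects(mask)
  if (n == 0L) return(mask)
  areas <- labelAreas(m)
  keep <- areas >= filters@minAreaPx & areas <= filters@maxAreaPx
  needShape <- filters@minSolidity > 0 || filters@minCircularity > 0
  for (i in seq_len(n)) {
    if (!keep[i]) next
    if (needShape) {
      obj <- m == i
      if (filters@minSolidity > 0 && objectSolidity(obj) < filters@minSolidity) {
        keep[i] <- FALSE
        next
      }
      if (filters@minCircularity > 0) {
        p <- croftonPerimeter(obj)
        circ <- if (p > 0) min(1, 4 * pi * areas[i] / p^2) else 1
        if (circ < filters@minCircularity) keep[i] <- FALSE
      }
    }
  }
  out <- m
  out[!(m %in% which(keep))] <- 0L
  if (any(keep)) out[out > 0L] <- match(out[out > 0L], which(keep))
  LabelMask(out, pixelSizeUm = mask@pixelSizeUm)
}

# Registry of named segmenter backends (e.g. learned models wrapped in R).
.segmenters <- new.env(parent = emptyenv())

#' Pluggable segmenter registry
#'
#' `registerSegmenter()` stores a backend under a name; `runSegmenter()`
#' delegates to it and validates that the output is a [LabelMask-class]
#' aligned to the input image. The classical pipelines are pre-registered as
#' `"otsu"` and `"watershed"`. This is the slot where an external learned
#' model (e.g. a served Mask R-CNN) plugs in; training is out of scope.
#'
#' @param name backend name.
#' @param fun function of signature `function(image, ...)` returning a
#'   [LabelMask-class] with the same dimensions as `image`.
#' @return `registerSegmenter()` returns `name` invisibly; `runSegmenter()`
#'   returns the backend's [LabelMask-class]; `listSegmenters()` the
#'   registered names.
#' @examples
#' registerSegmenter("inverted_otsu", function(image, ...)
#'   segmentOtsu(image, darkForeground = FALSE, ...))
#' "inverted_otsu" %in% listSegmenters()
#' @export
registerSegmenter <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.function(fun))
  assign(name, fun, envir = .segmenters)
  invisible(name)
}

#' @rdname registerSegmenter
#' @param image a [CalibratedImage-class].
#' @param ... passed through to the backend.
#' @export
runSegmenter <- function(name, image, ...) {
  if (!exists(name, envir = .segmenters, inherits = FALSE))
    stop(sprintf("unknown segmenter '%s'; registered: %s", name,
                 paste(listSegmenters(), collapse = ", ")))
  out <- get(name, envir = .segmenters)(image, ...)
  if (!is(out, "LabelMask"))
    stop(sprintf("segmenter '%s' did not return a LabelMask", name))
  if (!identical(dim(out), dim(image)))
    stop(sprintf("segmenter '%s' returned a %d x %d mask for a %d x %d image",
                 name, dim(out)[1], dim(out)[2], dim(image)[1], dim(image)[2]))
  out
}

#' @rdname registerSegmenter
#' @export
listSegmenters <- function() sort(ls(envir = .segmenters))

.onLoad <- function(libname, pkgname) {
  registerSegmenter("otsu", function(image, ...) segmentOtsu(image, ...))
  registerSegmenter("watershed", function(image, ...)
    segmentWatershed(image, ...))
}
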
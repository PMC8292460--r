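# Reading and writing images, label masks, annotations and configuration.
# Images: 8-bit PNG or 16-bit grayscale TIFF (via png/tiff). Masks: 16-bit
# label TIFF. Annotations: COCO-style JSON with uncompressed column-major
# run-length encoding. Scene specifications round-trip through JSON.

#' Read an image file as a CalibratedImage
#'
#' PNG and TIFF are supported; RGB input is converted to grayscale with
#' Rec.709 luminance (0.2126 R + 0.7152 G + 0.0722 B).
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @param pixelSizeUm micrometres per pixel to attach.
#' @param stageUm optional stage `(x, y)` of pixel (1,1), um.
#' @return a [CalibratedImage-class].
#' @export
readCalibratedImage <- function(path, pixelSizeUm = 1, stageUm = numeric()) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s'", ext)))
  m <- if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L)
      0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
    else arr[, , 1]
  } else arr
  m <- clamp01(if (is.null(dim(m))) matrix(m, nrow(arr), ncol(arr)) else m)
  CalibratedImage(m, pixelSizeUm = pixelSizeUm,
                  stageUm = stageUm)
}

#' Write a CalibratedImage to PNG (8-bit) or TIFF (16-bit grayscale)
#'
#' @param image a [CalibratedImage-class].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
writeCalibratedImage <- function(image, path) {
  stopifnot(is(image, "CalibratedImage"))
  ext <- tolower(tools::file_ext(path))
  m <- imageData(image)
  switch(ext,
    png = png::writePNG(m, path),
    tif = , tiff = tiff::writeTIFF(m, path, bits.per.sample = 16L),
    stop(sprintf("unsupported image format '.%s'", ext)))
  invisible(path)
}

#' Write / read a label mask as 16-bit TIFF
#'
#' Labels are stored as 16-bit gray values (supports up to 65535 objects).
#'
#' @param mask a [LabelMask-class].
#' @param path `.tif`/`.tiff` path.
#' @param pixelSizeUm pixel size to attach on read.
#' @return `writeLabelMask()` returns `path` invisibly; `readLabelMask()` a
#'   [LabelMask-class].
#' @export
writeLabelMask <- function(mask, path) {
  stopifnot(is(mask, "LabelMask"))
  m <- maskData(mask)
  if (max(m) > 65535L) stop("more than 65535 labels cannot be stored in 16 bit")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path, pixelSizeUm = 1) {
  arr <- tiff::readTIFF(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  LabelMask(matrix(as.integer(round(arr * 65535)), nrow(arr), ncol(arr)),
            pixelSizeUm = pixelSizeUm)
}

#' COCO-style annotation export / import
#'
#' `maskToCoco()` encodes every object of a label mask as an uncompressed
#' column-major run-length encoding (the `counts` convention of COCO
#' uncompressed RLE: alternating background/foreground run lengths);
#' `cocoToMask()` reconstructs the label mask. Round-trips exactly.
#'
#' @param mask a [LabelMask-class].
#' @param path optional JSON path; when given the annotation is written
#'   there.
#' @return `maskToCoco()`: the annotation list (invisibly if written);
#'   `cocoToMask()`: a [LabelMask-class].
#' @export
maskToCoco <- function(mask, path = NULL) {
  stopifnot(is(mask, "LabelMask"))
  m <- maskData(mask)
  shape <- dim(m)
  anns <- lapply(seq_len(nObjects(mask)), function(i) {
    v <- as.integer(m == i)  # column-major vector
    r <- rle(v)
    counts <- r$lengths
    if (r$values[1] == 1L) counts <- c(0L, counts)  # RLE starts with background
    list(id = i, segmentation = list(size = shape, counts = as.integer(counts)),
         area = sum(v))
  })
  out <- list(size = shape, pixel_size_um = mask@pixelSizeUm,
              annotations = anns)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

#' @rdname maskToCoco
#' @param ann annotation list from `maskToCoco()` or a JSON path.
#' @export
cocoToMask <- function(ann) {
  if (is.character(ann)) ann <- jsonlite::read_json(ann, simplifyVector = TRUE)
  shape <- as.integer(unlist(ann$size))
  m <- matrix(0L, shape[1], shape[2])
  anns <- ann$annotations
  getAnn <- function(i) if (is.data.frame(anns)) {
    list(id = anns$id[i], counts = unlist(anns$segmentation$counts[i]))
  } else list(id = anns[[i]]$id, counts = unlist(anns[[i]]$segmentation$counts))
  nAnn <- if (is.data.frame(anns)) nrow(anns) else length(anns)
  for (i in seq_len(nAnn)) {
    a <- getAnn(i)
    counts <- as.integer(a$counts)
    vals <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
    m[vals == 1L] <- as.integer(a$id)
  }
  LabelMask(m, pixelSizeUm = ann$pixel_size_um %||% 1)
}

#' Serialize / restore a SceneSpec as JSON
#'
#' @param spec a [SceneSpec-class].
#' @param path JSON path.
#' @return `writeSceneSpec()` returns `path` invisibly; `readSceneSpec()` a
#'   [SceneSpec-class] that renders bit-identically to the original.
#' @export
writeSceneSpec <- function(spec, path) {
  stopifnot(is(spec, "SceneSpec"))
  obj <- list(
    imageShapePx = spec@imageShapePx, pixelSizeUm = spec@pixelSizeUm,
    backgroundLevel = spec@backgroundLevel,
    illuminationGradient = spec@illuminationGradient,
    noiseSigma = spec@noiseSigma, seed = spec@seed,
    objects = lapply(spec@objects, function(o) list(
      centerPx = o@centerPx, radiusPx = o@radiusPx,
      irregularity = o@irregularity, interiorLevel = o@interiorLevel,
      haloGain = o@haloGain, defocusSigmaPx = o@defocusSigmaPx)),
    artifacts = spec@artifacts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSceneSpec
#' @export
readSceneSpec <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  objects <- if (length(o$objects)) {
    if (is.data.frame(o$objects)) {
      ctrs <- o$objects$centerPx  # matrix (n x 2) or list column
      lapply(seq_len(nrow(o$objects)), function(i) {
        irr <- o$objects$irregularity[[i]]
        if (is.null(irr) || !length(irr))
          irr <- data.frame(order = integer(), amplitude = numeric(),
                            phase = numeric())
        ctr <- if (is.matrix(ctrs)) ctrs[i, ] else unlist(ctrs[[i]])
        ObjectSpec(centerPx = as.numeric(ctr),
                   radiusPx = o$objects$radiusPx[i],
                   irregularity = as.data.frame(irr),
                   interiorLevel = o$objects$interiorLevel[i],
                   haloGain = o$objects$haloGain[i],
                   defocusSigmaPx = o$objects$defocusSigmaPx[i])
      })
    } else {
      lapply(o$objects, function(ob) {
        irr <- ob$irregularity
        if (is.null(irr) || !length(irr))
          irr <- data.frame(order = integer(), amplitude = numeric(),
                            phase = numeric())
        ObjectSpec(centerPx = unlist(ob$centerPx), radiusPx = ob$radiusPx,
                   irregularity = as.data.frame(irr),
                   interiorLevel = ob$interiorLevel, haloGain = ob$haloGain,
                   defocusSigmaPx = ob$defocusSigmaPx)
      })
    }
  } else list()
  artifacts <- if (length(o$artifacts)) {
    lapply(if (is.data.frame(o$artifacts)) seq_len(nrow(o$artifacts)) else
           seq_along(o$artifacts), function(i) {
      a <- if (is.data.frame(o$artifacts))
        lapply(o$artifacts, function(col) col[[i]]) else o$artifacts[[i]]
      a <- a[!vapply(a, function(x) is.null(x) || all(is.na(unlist(x))),
                     logical(1))]
      for (f in c("center", "points"))
        if (!is.null(a[[f]])) a[[f]] <- if (f == "points")
          matrix(unlist(a[[f]]), ncol = 2) else unlist(a[[f]])
      a
    })
  } else list()
  SceneSpec(imageShapePx = unlist(o$imageShapePx),
            pixelSizeUm = o$pixelSizeUm,
            backgroundLevel = o$backgroundLevel,
            illuminationGradient = unlist(o$illuminationGradient),
            noiseSigma = o$noiseSigma, objects = objects,
            artifacts = artifacts, seed = o$seed)
}

#' Read selection criteria from JSON
#'
#' Expected shape:
#' `{"area_um2": {"min": 21000, "max": 29000}, "circularity": {"min": 0.815}}`
#' with optional top-level `preferred` (`{"feature":.., "value":..}`) and
#' `max_count`.
#'
#' @param path JSON path.
#' @return a [SelectionCriteria-class].
#' @export
readSelectionCriteria <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  preferred <- o$preferred
  maxCount <- o$max_count
  o$preferred <- NULL; o$max_count <- NULL
  args <- lapply(o, function(iv) c(
    if (is.null(iv$min)) NA_real_ else as.numeric(iv$min),
    if (is.null(iv$max)) NA_real_ else as.numeric(iv$max)))
  do.call(selectionCriteria,
          c(args, list(preferred = preferred, maxCount = maxCount)))
}
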
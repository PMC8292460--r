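# Per-object morphometric features in physical units.
#
# Area comes from pixel counting (area_um2 = n_px * pixel_size^2), perimeter
# from a Crofton 4-direction estimate (near-unbiased for smooth boundaries,
# unlike boundary-pixel counting which would push the circularity of true
# circles far below 1), circularity is the ISO-style roundness 4*pi*A/P^2,
# solidity is pixel area over rasterized convex-hull area, and volume is the
# sphere of equal equivalent diameter.

#' Circularity (ISO roundness) from area and perimeter
#'
#' `4 * pi * area / perimeter^2`, clamped to 1. Equals 1 for a perfect
#' circle and decreases with boundary irregularity; a minimum-circularity
#' selection criterion (e.g. 0.815) therefore demands a rounded shape.
#' Area and perimeter must be in consistent units (both pixel-based or both
#' physical).
#'
#' @param area object area (> 0).
#' @param perimeter object perimeter (> 0).
#' @return circularity in `(0, 1]`.
#' @examples
#' circularity(pi * 10^2, 2 * pi * 10)  # circle: 1
#' circularity(4, 8)                    # unit square: pi/4
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("'area' and 'perimeter' must be positive")
  pmin(1, 4 * pi * area / perimeter^2)
}

#' Equivalent diameter of the circle with the same area
#'
#' `2 * sqrt(area / pi)`; e.g. an area of 25,000 um^2 corresponds to a
#' 178.41 um diameter.
#'
#' @param areaUm2 area in square micrometres (> 0).
#' @return diameter in micrometres.
#' @examples
#' equivalentDiameter(25000)
#' @export
equivalentDiameter <- function(areaUm2) {
  if (any(areaUm2 <= 0)) stop("'areaUm2' must be positive")
  2 * sqrt(areaUm2 / pi)
}

#' Sphere-equivalent volume estimate from 2D area
#'
#' Volume of the sphere whose diameter equals the object's equivalent
#' diameter: `(pi / 6) * d_eq^3`. This is a single-view estimate; it assumes
#' the spheroid is approximately spherical (method recorded as
#' `"sphere_equivalent"` in feature tables).
#'
#' @param areaUm2 area in square micrometres (> 0).
#' @return volume in cubic micrometres.
#' @examples
#' volumeEstimate(25000)
#' @export
volumeEstimate <- function(areaUm2) {
  if (any(areaUm2 <= 0)) stop("'areaUm2' must be positive")
  (pi / 6) * equivalentDiameter(areaUm2)^3
}

#' Solidity of a binary object
#'
#' Pixel area divided by the rasterized convex-hull area. Near 1 for convex
#' shapes (disks, ellipses); low for ring- or streak-shaped structures such
#' as air-bubble arcs, which is what makes it an effective artifact filter.
#'
#' @param object logical or 0/1 matrix of a single object.
#' @return solidity in `(0, 1]`.
#' @examples
#' m <- outer(-20:20, -20:20, function(i, j) i^2 + j^2 <= 15^2)
#' solidity(m)
#' @export
solidity <- function(object) objectSolidity(object)

#' Extract per-object morphometric features from a label mask
#'
#' Computes, for every label in ascending order: pixel and physical area,
#' Crofton perimeter, circularity, equivalent diameter, solidity,
#' sphere-equivalent volume, centroid, bounding box and (when a stage origin
#' is supplied) absolute stage coordinates of the centroid.
#'
#' Stage convention: x runs along image columns, y along rows, both in
#' micrometres; `stage_x_um = origin_x + (centroid_col - 1) * pixelSizeUm`.
#'
#' @param mask a [LabelMask-class].
#' @param pixelSizeUm micrometres per pixel (defaults to the mask's own).
#' @param stageOrigin optional `(x, y)` stage position of pixel (1,1), um.
#' @return data.frame with one row per object: `label`, `area_px`,
#'   `area_um2`, `perimeter_um`, `circularity`, `equivalent_diameter_um`,
#'   `solidity`, `volume_um3`, `centroid_row`, `centroid_col`, `bbox_min_row`,
#'   `bbox_min_col`, `bbox_max_row`, `bbox_max_col`, `stage_x_um`,
#'   `stage_y_um`. Attribute `volume_method` is `"sphere_equivalent"`.
#' @examples
#' m <- matrix(0L, 30, 30); m[10:19, 10:19] <- 1L
#' extractFeatures(LabelMask(m), pixelSizeUm = 2)$area_um2  # 400
#' @export
extractFeatures <- function(mask, pixelSizeUm = pixelSize(mask),
                            stageOrigin = NULL) {
  stopifnot(is(mask, "LabelMask"))
  if (length(pixelSizeUm) != 1L || !is.finite(pixelSizeUm) || pixelSizeUm <= 0)
    stop("'pixelSizeUm' must be a single positive number")
  m <- maskData(mask)
  n <- nObjects(mask)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    obj <- m == i
    idx <- which(obj, arr.ind = TRUE)
    npx <- nrow(idx)
    areaUm2 <- npx * pixelSizeUm^2
    perimUm <- croftonPerimeter(obj) * pixelSizeUm
    circ <- if (perimUm > 0) circularity(areaUm2, perimUm) else 1
    ctr <- colMeans(idx)
    rows[[i]] <- data.frame(
      label = i, area_px = npx, area_um2 = areaUm2, perimeter_um = perimUm,
      circularity = circ,
      equivalent_diameter_um = equivalentDiameter(areaUm2),
      solidity = objectSolidity(obj),
      volume_um3 = volumeEstimate(areaUm2),
      centroid_row = ctr[1], centroid_col = ctr[2],
      bbox_min_row = min(idx[, 1]), bbox_min_col = min(idx[, 2]),
      bbox_max_row = max(idx[, 1]), bbox_max_col = max(idx[, 2]),
      stage_x_um = if (is.null(stageOrigin)) NA_real_ else
        stageOrigin[1] + (ctr[2] - 1) * pixelSizeUm,
      stage_y_um = if (is.null(stageOrigin)) NA_real_ else
        stageOrigin[2] + (ctr[1] - 1) * pixelSizeUm,
      row.names = NULL)
  }
  out <- if (n) do.call(rbind, rows) else data.frame(
    label = integer(), area_px = integer(), area_um2 = numeric(),
    perimeter_um = numeric(), circularity = numeric(),
    equivalent_diameter_um = numeric(), solidity = numeric(),
    volume_um3 = numeric(), centroid_row = numeric(),
    centroid_col = numeric(), bbox_min_row = integer(),
    bbox_min_col = integer(), bbox_max_row = integer(),
    bbox_max_col = integer(), stage_x_um = numeric(), stage_y_um = numeric())
  attr(out, "volume_method") <- "sphere_equivalent"
  attr(out, "pixel_size_um") <- pixelSizeUm
  out
}

#' Write / read a feature table as CSV
#'
#' @param features data.frame from [extractFeatures()].
#' @param path CSV path.
#' @return `writeFeatures()` returns `path` invisibly; `readFeatures()` the
#'   data.frame.
#' @export
writeFeatures <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
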
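# Synthetic brightfield spheroid scenes with exact ground-truth masks.
#
# The generator emulates stereomicroscope brightfield wells: a bright,
# possibly unevenly illuminated background; darker, roughly circular
# spheroids with a thin bright halo rim; optional per-object defocus;
# additive sensor noise drawn after blurring; and dark artifact structures
# (air bubbles, plate borders, plastic defects) that perturb the image but
# never the ground-truth mask.

# r(theta) for a Fourier-perturbed boundary
radialProfile <- function(spec, theta) {
  r <- rep(spec@radiusPx, length(theta))
  irr <- spec@irregularity
  if (nrow(irr))
    for (k in seq_len(nrow(irr)))
      r <- r + spec@radiusPx * irr$amplitude[k] *
        cos(irr$order[k] * theta + irr$phase[k])
  r
}

# Signed distance-like fields for one object over its bounding window:
# returns list(rows, cols, dist, rTheta) restricted to a window that surely
# contains boundary + halo.
objectWindow <- function(spec, imageShapePx, marginPx = 0) {
  rmax <- spec@radiusPx * (1 + sum(abs(spec@irregularity$amplitude))) +
    marginPx + 1
  r0 <- max(1L, floor(spec@centerPx[1] - rmax))
  r1 <- min(imageShapePx[1], ceiling(spec@centerPx[1] + rmax))
  c0 <- max(1L, floor(spec@centerPx[2] - rmax))
  c1 <- min(imageShapePx[2], ceiling(spec@centerPx[2] + rmax))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - spec@centerPx[1]
  dx <- cols - spec@centerPx[2]
  dist <- sqrt(outer(dy^2, dx^2, "+"))
  theta <- atan2(outer(dy, rep(1, length(dx))), outer(rep(1, length(dy)), dx))
  rT <- matrix(radialProfile(spec, as.vector(theta)), nrow = length(rows))
  list(rows = rows, cols = cols, dist = dist, rTheta = rT)
}

#' Render the exact pixel mask of one synthetic spheroid
#'
#' The object boundary is the radial curve
#' `r(theta) = R (1 + sum_k a_k cos(k theta + phi_k))`; a pixel belongs to
#' the object iff its centre lies inside (or on) the curve.
#'
#' @param spec an [ObjectSpec-class].
#' @param imageShapePx integer `(height, width)` of the target image.
#' @return A [LabelMask-class] with the single object labelled 1.
#' @examples
#' m <- renderObjectMask(ObjectSpec(c(64, 64), 20), c(128, 128))
#' sum(maskData(m) == 1L)  # close to pi * 20^2
#' @export
renderObjectMask <- function(spec, imageShapePx) {
  validObject(spec)
  imageShapePx <- as.integer(imageShapePx)
  w <- objectWindow(spec, imageShapePx)
  inside <- w$dist <= w$rTheta
  # bounds check: the curve must fit inside the image
  thetaGrid <- seq(0, 2 * pi, length.out = 720)
  rG <- radialProfile(spec, thetaGrid)
  rr <- spec@centerPx[1] + rG * sin(thetaGrid)
  cc <- spec@centerPx[2] + rG * cos(thetaGrid)
  if (min(rr) < 0.5 || max(rr) > imageShapePx[1] + 0.5 ||
      min(cc) < 0.5 || max(cc) > imageShapePx[2] + 0.5)
    stop(sprintf(
      "object at (%.1f, %.1f) with radius %.1f px extends beyond image bounds %d x %d",
      spec@centerPx[1], spec@centerPx[2], spec@radiusPx,
      imageShapePx[1], imageShapePx[2]))
  m <- matrix(0L, imageShapePx[1], imageShapePx[2])
  m[w$rows, w$cols][inside] <- 1L
  LabelMask(m)
}

# Additive intensity contribution of one object (interior + halo) relative
# to the local background field B, over the full image. haloWidthPx is the
# rim thickness outside the boundary.
objectContribution <- function(spec, B, haloWidthPx = 3) {
  shp <- dim(B)
  w <- objectWindow(spec, shp, marginPx = haloWidthPx + 4 * spec@defocusSigmaPx)
  Bl <- B[w$rows, w$cols]
  inside <- w$dist <= w$rTheta
  halo <- !inside & w$dist <= (w$rTheta + haloWidthPx)
  contrib <- matrix(0, length(w$rows), length(w$cols))
  contrib[inside] <- (spec@interiorLevel - 1) * Bl[inside]
  contrib[halo] <- spec@haloGain * Bl[halo]
  if (spec@defocusSigmaPx > 0)
    contrib <- EBImage::gblur(contrib, sigma = spec@defocusSigmaPx,
                              boundary = 0)
  out <- matrix(0, shp[1], shp[2])
  out[w$rows, w$cols] <- contrib
  out
}

# Stamp a dark annular arc (air bubble or curved plate border) onto `img`.
# a: list(center = c(row, col), radius, thickness, arcStart, arcSpan, level)
# where level is the intensity multiplier applied to the covered pixels.
stampArc <- function(img, a) {
  shp <- dim(img)
  rmax <- a$radius + a$thickness
  r0 <- max(1L, floor(a$center[1] - rmax)); r1 <- min(shp[1], ceiling(a$center[1] + rmax))
  c0 <- max(1L, floor(a$center[2] - rmax)); c1 <- min(shp[2], ceiling(a$center[2] + rmax))
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - a$center[1]; dx <- cols - a$center[2]
  dist <- sqrt(outer(dy^2, dx^2, "+"))
  ang <- atan2(outer(dy, rep(1, length(dx))), outer(rep(1, length(dy)), dx))
  rel <- (ang - a$arcStart) %% (2 * pi)
  inArc <- dist >= a$radius - a$thickness / 2 &
    dist <= a$radius + a$thickness / 2 & rel <= a$arcSpan
  patch <- img[rows, cols]
  patch[inArc] <- patch[inArc] * a$level
  img[rows, cols] <- patch
  img
}

# Stamp a thin dark zig-zag streak (plastic defect): polyline through
# a$points (n x 2 matrix, row/col), half-width a$thickness / 2.
stampStreak <- function(img, a) {
  shp <- dim(img)
  pts <- a$points
  r0 <- max(1L, floor(min(pts[, 1]) - a$thickness))
  r1 <- min(shp[1], ceiling(max(pts[, 1]) + a$thickness))
  c0 <- max(1L, floor(min(pts[, 2]) - a$thickness))
  c1 <- min(shp[2], ceiling(max(pts[, 2]) + a$thickness))
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  g <- expand.grid(row = rows, col = cols)
  d2min <- rep(Inf, nrow(g))
  for (i in seq_len(nrow(pts) - 1L)) {
    p <- pts[i, ]; q <- pts[i + 1L, ]
    v <- q - p; len2 <- sum(v^2)
    t <- if (len2 > 0)
      pmin(1, pmax(0, ((g$row - p[1]) * v[1] + (g$col - p[2]) * v[2]) / len2))
    else 0
    d2 <- (g$row - (p[1] + t * v[1]))^2 + (g$col - (p[2] + t * v[2]))^2
    d2min <- pmin(d2min, d2)
  }
  hit <- matrix(d2min <= (a$thickness / 2)^2, length(rows))
  patch <- img[rows, cols]
  patch[hit] <- patch[hit] * a$level
  img[rows, cols] <- patch
  img
}

#' Render a synthetic brightfield scene and its ground-truth mask
#'
#' Composes, in order: background with linear illumination gradient; per
#' object a darker interior and bright halo rim (Gaussian-defocused when
#' `defocusSigmaPx > 0`); artifacts (image only, never the mask); additive
#' Gaussian noise from the scene's seeded generator; clamp to `[0, 1]`.
#' Objects are labelled `1..n` in list order. Identical SceneSpecs render
#' bit-identical output.
#'
#' Artifact descriptors are lists with a `kind` field:
#' \describe{
#'   \item{air_bubble / plate_border}{dark annular arc: `center` (row, col),
#'     `radius`, `thickness`, `arcStart`, `arcSpan` (radians), `level`
#'     (intensity multiplier < 1). Bubbles are small open rings; borders are
#'     large-radius arcs sweeping through the field.}
#'   \item{plastic_defect}{thin dark zig-zag streak: `points` (n x 2 matrix
#'     of row/col vertices), `thickness`, `level`.}
#' }
#'
#' @param spec a [SceneSpec-class].
#' @return list with elements `image` ([CalibratedImage-class]) and `mask`
#'   ([LabelMask-class]).
#' @examples
#' sc <- SceneSpec(c(128, 128), objects = list(ObjectSpec(c(64, 64), 25)),
#'                 noiseSigma = 0.01, seed = 7)
#' out <- renderScene(sc)
#' nObjects(out$mask)
#' @export
renderScene <- function(spec) {
  validObject(spec)
  shp <- spec@imageShapePx
  h <- shp[1]; w <- shp[2]
  # background with centred linear gradient
  fr <- if (h > 1) (seq_len(h) - 1) / (h - 1) - 0.5 else 0
  fc <- if (w > 1) (seq_len(w) - 1) / (w - 1) - 0.5 else 0
  B <- spec@backgroundLevel *
    (1 + matrix(fr * spec@illuminationGradient[1], h, w) +
       matrix(fc * spec@illuminationGradient[2], h, w, byrow = TRUE))
  img <- B
  mask <- matrix(0L, h, w)
  for (i in seq_along(spec@objects)) {
    o <- spec@objects[[i]]
    om <- tryCatch(maskData(renderObjectMask(o, shp)), error = function(e)
      stop(sprintf("object %d: %s", i, conditionMessage(e)), call. = FALSE))
    if (any(mask[om == 1L] != 0L))
      stop(sprintf("object %d overlaps object %d; spheroids must not overlap",
                   i, max(mask[om == 1L])))
    mask[om == 1L] <- i
    img <- img + objectContribution(o, B)
  }
  for (a in spec@artifacts) {
    img <- switch(a$kind,
      air_bubble = stampArc(img, a),
      plate_border = stampArc(img, a),
      plastic_defect = stampStreak(img, a),
      stop(sprintf("unknown artifact kind '%s'", a$kind)))
  }
  if (spec@noiseSigma > 0)
    img <- withSeed(spec@seed,
                    img + matrix(stats::rnorm(h * w, 0, spec@noiseSigma), h, w))
  img <- clamp01(img)
  list(image = CalibratedImage(img, pixelSizeUm = spec@pixelSizeUm),
       mask = LabelMask(mask, pixelSizeUm = spec@pixelSizeUm))
}

#' Difficulty profiles for benchmark generation
#'
#' Named parameter bundles controlling how [makeBenchmarkSet()] samples
#' scenes:
#' \describe{
#'   \item{round}{perfect in-focus disks, no artifacts, minimal noise —
#'     morphometric ground truth conditions.}
#'   \item{clean}{in-focus, mildly irregular spheroids, no artifacts, light
#'     noise and illumination gradient.}
#'   \item{default}{irregular spheroids, occasional defocus, moderate noise,
#'     artifacts in about half the images.}
#'   \item{artifact}{as default but with 1-3 artifacts guaranteed per image.}
#' }
#'
#' @param name profile name.
#' @return list of sampling parameters (ranges are uniform unless noted):
#'   `nObjects`, `diameterUm`, `maxAmplitude`, `nHarmonics`,
#'   `defocusSigmaPx`, `noiseSigma`, `gradientMax`, `artifactCount`.
#' @export
difficultyProfile <- function(name = c("clean", "round", "default", "artifact")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    imageShapePx = c(512L, 512L),
    pixelSizeUm = 2.0,
    backgroundLevel = 0.75,
    interiorLevel = c(0.45, 0.6),
    haloGain = c(0.05, 0.12),
    nObjects = c(1L, 5L),
    diameterUm = c(200, 250),
    nHarmonics = c(0L, 0L),
    maxAmplitude = 0,
    defocusSigmaPx = c(0, 0),
    noiseSigma = 0.01,
    gradientMax = 0.05,
    artifactCount = c(0L, 0L))
  switch(name,
    round = base,
    clean = utils::modifyList(base, list(
      nHarmonics = c(1L, 2L), maxAmplitude = 0.05)),
    default = utils::modifyList(base, list(
      nHarmonics = c(1L, 3L), maxAmplitude = 0.12,
      defocusSigmaPx = c(0, 3), noiseSigma = 0.02, gradientMax = 0.10,
      artifactCount = c(0L, 1L))),
    artifact = utils::modifyList(base, list(
      nHarmonics = c(1L, 3L), maxAmplitude = 0.12,
      defocusSigmaPx = c(0, 2), noiseSigma = 0.02, gradientMax = 0.10,
      artifactCount = c(1L, 3L))))
}

sampleInt <- function(lohi) if (lohi[1] >= lohi[2]) lohi[1] else
  sample(lohi[1]:lohi[2], 1L)
sampleUnif <- function(lohi) if (lohi[1] >= lohi[2]) lohi[1] else
  stats::runif(1, lohi[1], lohi[2])

# Sample one artifact descriptor inside the image.
sampleArtifact <- function(shp) {
  kind <- sample(c("air_bubble", "plate_border", "plastic_defect"), 1L)
  if (kind == "air_bubble") {
    r <- stats::runif(1, 15, 35)
    list(kind = kind,
         center = c(stats::runif(1, r + 5, shp[1] - r - 5),
                    stats::runif(1, r + 5, shp[2] - r - 5)),
         radius = r, thickness = stats::runif(1, 4, 8),
         arcStart = stats::runif(1, 0, 2 * pi),
         arcSpan = stats::runif(1, 3.5, 5.5),  # open ring, 200-315 degrees
         level = stats::runif(1, 0.45, 0.6))
  } else if (kind == "plate_border") {
    # large-radius arc whose rim sweeps through the field (well edge)
    r <- stats::runif(1, 1.2, 2.0) * max(shp)
    corner <- matrix(c(1, 1, 1, shp[2], shp[1], 1, shp[1], shp[2]),
                     ncol = 2, byrow = TRUE)[sample(4L, 1L), ]
    dir <- stats::runif(1, 0, 2 * pi)
    center <- corner + r * c(sin(dir), cos(dir))
    list(kind = kind, center = center, radius = r,
         thickness = stats::runif(1, 6, 12),
         arcStart = 0, arcSpan = 2 * pi,
         level = stats::runif(1, 0.5, 0.65))
  } else {
    n <- sample(3:5, 1L)
    start <- c(stats::runif(1, 20, shp[1] - 20), stats::runif(1, 20, shp[2] - 20))
    step <- stats::runif(1, 15, 30)
    ang <- stats::runif(1, 0, 2 * pi)
    pts <- matrix(NA_real_, n, 2)
    pts[1, ] <- start
    for (i in 2:n) {
      ang <- ang + stats::runif(1, 1.2, 2.2) * sample(c(-1, 1), 1L)  # sharp kinks
      pts[i, ] <- pts[i - 1, ] + step * c(sin(ang), cos(ang))
    }
    pts[, 1] <- pmin(pmax(pts[, 1], 3), shp[1] - 2)
    pts[, 2] <- pmin(pmax(pts[, 2], 3), shp[2] - 2)
    list(kind = kind, points = pts, thickness = stats::runif(1, 2, 4),
         level = stats::runif(1, 0.35, 0.55))
  }
}

# Sample a full SceneSpec from a profile (assumes RNG already seeded).
sampleSceneSpec <- function(profile, seed) {
  shp <- profile$imageShapePx
  px <- profile$pixelSizeUm
  nObj <- sampleInt(profile$nObjects)
  objects <- list()
  centers <- matrix(numeric(0), ncol = 3)  # row, col, radius
  attempts <- 0L
  while (length(objects) < nObj && attempts < 200L) {
    attempts <- attempts + 1L
    dUm <- sampleUnif(profile$diameterUm)
    R <- dUm / 2 / px
    margin <- R * 1.6 + 4
    if (2 * margin >= min(shp)) break
    ctr <- c(stats::runif(1, margin, shp[1] - margin),
             stats::runif(1, margin, shp[2] - margin))
    # enforce non-overlap with a touching margin
    if (nrow(centers) &&
        any(sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2) <
            (centers[, 3] + R) * 1.35 + 4)) next
    nh <- sampleInt(profile$nHarmonics)
    irr <- if (nh > 0L && profile$maxAmplitude > 0) {
      data.frame(order = sample(2:5, nh),
                 amplitude = stats::runif(nh, 0, profile$maxAmplitude),
                 phase = stats::runif(nh, 0, 2 * pi))
    } else data.frame(order = integer(), amplitude = numeric(),
                      phase = numeric())
    objects[[length(objects) + 1L]] <- ObjectSpec(
      centerPx = ctr, radiusPx = R, irregularity = irr,
      interiorLevel = sampleUnif(profile$interiorLevel),
      haloGain = sampleUnif(profile$haloGain),
      defocusSigmaPx = sampleUnif(profile$defocusSigmaPx))
    centers <- rbind(centers, c(ctr, R))
  }
  nArt <- sampleInt(profile$artifactCount)
  artifacts <- if (nArt > 0L) lapply(seq_len(nArt), function(i)
    sampleArtifact(shp)) else list()
  g <- profile$gradientMax
  SceneSpec(imageShapePx = shp, pixelSizeUm = px,
            backgroundLevel = profile$backgroundLevel,
            illuminationGradient = c(stats::runif(1, -g, g),
                                     stats::runif(1, -g, g)),
            noiseSigma = profile$noiseSigma,
            objects = objects, artifacts = artifacts, seed = seed)
}

#' Generate a seeded benchmark set of synthetic scenes
#'
#' Samples `nImages` scenes from a difficulty profile and renders each one.
#' Object count, diameter (default 200-250 um), boundary irregularity,
#' defocus and artifact presence are drawn from the profile's seeded
#' generator; the result is fully deterministic given `seed`.
#'
#' @param nImages number of scenes (>= 1).
#' @param profile a profile name (see [difficultyProfile()]) or a profile
#'   list.
#' @param seed integer seed driving all sampling and rendering noise.
#' @return list of length `nImages`; each element has `image`
#'   ([CalibratedImage-class]), `mask` ([LabelMask-class]) and `scene`
#'   ([SceneSpec-class], the ground-truth generating parameters).
#' @examples
#' set <- makeBenchmarkSet(2, profile = "clean", seed = 1)
#' nObjects(set[[1]]$mask)
#' @export
makeBenchmarkSet <- function(nImages, profile = "default", seed = 1L) {
  stopifnot(nImages >= 1)
  if (is.character(profile)) profile <- difficultyProfile(profile)
  specs <- withSeed(seed, lapply(seq_len(nImages), function(i)
    sampleSceneSpec(profile, seed = as.integer(seed) * 1000L + i)))
  lapply(specs, function(s) {
    out <- renderScene(s)
    list(image = out$image, mask = out$mask, scene = s)
  })
}
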
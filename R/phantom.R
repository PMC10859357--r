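## Synthetic wrap phantoms: label volumes with analytically known
## tumor-vessel contact angles, used to validate the quantifier and the
## staging rules end to end without clinical data.
##
## Geometry defaults emulate the superior mesenteric artery at CT-like
## resolution: a 5 mm radius tube in a 96^3 grid at 0.5 mm isotropic
## spacing, wrapped by a 3 mm tumor shell over 10 slices (5 mm).
##
## The wrap must be short relative to the tube. The quantifier maximizes
## over all grid-axis planes; a longitudinal plane grazing the wrapped arc
## sees contact ~ L_w against perimeter ~ 2 L_v (L_w wrap length, L_v tube
## length), i.e. about 360 L_w / (2 L_v) degrees irrespective of theta. For
## the measured maximum to equal the cross-sectional wrap angle down to
## theta_min, the geometry must satisfy L_w < L_v * theta_min / 180. The
## 5 mm default against the ~44 mm tube keeps this floor near 22 degrees.

.axisCoords <- function(n, sp) (seq_len(n) - 0.5) * sp

.inPlaneGrids <- function(shape, spacing, axis) {
  uv <- setdiff(1:3, axis)
  u <- uv[1]; v <- uv[2]
  uu <- .axisCoords(shape[u], spacing[u])
  vv <- .axisCoords(shape[v], spacing[v])
  list(u = u, v = v,
       U = matrix(uu, shape[u], shape[v]),
       V = matrix(vv, shape[u], shape[v], byrow = TRUE))
}

.putSlice <- function(vox, axis, s, pl) {
  switch(axis,
    vox[s, , ] <- pl, vox[, s, ] <- pl, vox[, , s] <- pl)
  vox
}

.setSlice <- function(vox, axis, s, mask, value) {
  pl <- switch(axis,
    vox[s, , , drop = TRUE], vox[, s, , drop = TRUE],
    vox[, , s, drop = TRUE])
  pl[mask] <- value
  .putSlice(vox, axis, s, pl)
}

.getSlice <- function(vox, axis, s) {
  switch(axis, vox[s, , , drop = TRUE], vox[, s, , drop = TRUE],
         vox[, , s, drop = TRUE])
}

## Annular tumor sector: shell radii (radius, radius + shell], angular
## positions within theta degrees of wrapStart (counter-clockwise). The
## sector is grown outward from the vessel's analytic surface, so at every
## wrapped angular position the tumor abuts the vessel boundary in-plane.
.sectorMask <- function(grids, center, radius, shell, theta, wrapStart) {
  dU <- grids$U - center[1]; dV <- grids$V - center[2]
  rr <- sqrt(dU^2 + dV^2)
  if (theta <= 0) return(rr < 0)  # empty
  ang <- (atan2(dV, dU) * 180 / pi - wrapStart) %% 360
  rr > radius & rr <= radius + shell & (ang <= theta | theta >= 360)
}

.erode8 <- function(mask) !.dilate8(!mask)

## Seeded boundary jitter: every voxel on the in-plane 8-boundary of the
## tumor shell (either side, never inside a vessel) toggles membership with
## probability jitterProb. Emulates segmentation noise.
.jitterTumor <- function(vox, tumorLabel, vesselLabels, axis, jitterProb) {
  d <- dim(vox)
  for (s in seq_len(d[axis])) {
    pl <- .getSlice(vox, axis, s)
    tm <- pl == tumorLabel
    if (!any(tm)) next
    inBoundary <- tm & !.erode8(tm)
    outBoundary <- !tm & .dilate8(tm) & !(pl %in% vesselLabels)
    cand <- which(inBoundary | outBoundary)
    flip <- cand[stats::runif(length(cand)) < jitterProb]
    if (length(flip)) {
      pl[flip] <- ifelse(tm[flip], 0L, tumorLabel)
      vox <- .putSlice(vox, axis, s, pl)
    }
  }
  vox
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.wrapSliceWindow <- function(shape, axis, wrapExtent) {
  s0 <- (shape[axis] - wrapExtent) %/% 2L + 1L
  s0:(s0 + wrapExtent - 1L)
}

## Axial slice range for the tube: inset 2 mm from the volume faces so the
## vessel never touches the image border.
.tubeSlices <- function(shape, spacing, axis) {
  zc <- .axisCoords(shape[axis], spacing[axis])
  which(zc >= 2 & zc <= shape[axis] * spacing[axis] - 2)
}

.checkInPlaneFit <- function(center, radius, shell, grids, shape, spacing) {
  extU <- shape[grids$u] * spacing[grids$u]
  extV <- shape[grids$v] * spacing[grids$v]
  r <- radius + shell
  if (center[1] - r < 0 || center[1] + r > extU ||
      center[2] - r < 0 || center[2] + r > extV)
    stop("vessel/tumor would exit the volume: reduce radius or recenter")
}

.phantomTruth <- function(angles, rules) {
  full <- structure(rep(0, length(.VESSELS)), names = .VESSELS)
  full[names(angles)] <- angles
  new("PhantomTruth", angles = full, categories = binDegree(full),
      stage = caseStage(classifyStage(full, rules)))
}

#' Straight-cylinder wrap phantom
#'
#' Rasterizes a straight vessel tube of given radius along a grid axis and a
#' tumor shell subtending exactly `theta` degrees around the vessel axis,
#' abutting the vessel surface, over `wrapExtent` central slices. For
#' `theta = 0` a detached tumor ball is placed 2 mm clear of the vessel
#' instead, so planes contain both structures but no contact exists. With
#' `jitter = TRUE` and a seed, boundary voxels of the tumor shell toggle
#' membership with probability `jitterProb`, reproducibly.
#'
#' @param theta wrap angle in degrees, 0 to 360 (the analytic ground truth).
#' @param vessel vessel name receiving the wrap (default `"SMA"`).
#' @param shape integer(3) volume dimensions in voxels.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param axis tube axis (1, 2 or 3).
#' @param radius tube radius in mm.
#' @param shellThickness tumor shell thickness in mm.
#' @param wrapExtent longitudinal extent of the wrap, in slices. Keep the
#'   physical wrap length below `tube length * theta/180` for the smallest
#'   wrap angle of interest, or near-tangent longitudinal planes dominate
#'   the plane-sweep maximum (see the package vignette).
#' @param wrapStart angular position (degrees) where the wrap begins.
#' @param center in-plane tube center in mm (default: volume center).
#' @param jitter,jitterProb,seed boundary jitter controls.
#' @param rules rule set used for the truth's expected stage.
#' @return List with `volume` (a [LabelVolume-class]) and `truth`
#'   (a [PhantomTruth-class]).
#' @examples
#' ph <- makeWrapPhantom(90, shape = c(48, 48, 48))
#' truthAngles(ph$truth)[["SMA"]]
#' @export
makeWrapPhantom <- function(theta, vessel = "SMA",
                            shape = c(96L, 96L, 96L),
                            spacing = c(0.5, 0.5, 0.5), axis = 3L,
                            radius = 5, shellThickness = 3,
                            wrapExtent = 10L, wrapStart = 15,
                            center = NULL, jitter = FALSE, jitterProb = 0.1,
                            seed = NULL, rules = defaultRuleSet()) {
  stopifnot(length(theta) == 1L, theta >= 0, theta <= 360,
            radius > 0, shellThickness > 0, vessel %in% .VESSELS)
  shape <- as.integer(shape); axis <- as.integer(axis)
  lm <- defaultLabelMap()
  grids <- .inPlaneGrids(shape, spacing, axis)
  if (is.null(center))
    center <- c(shape[grids$u] * spacing[grids$u],
                shape[grids$v] * spacing[grids$v]) / 2
  .checkInPlaneFit(center, radius, shellThickness, grids, shape, spacing)

  vox <- array(0L, shape)
  rr <- sqrt((grids$U - center[1])^2 + (grids$V - center[2])^2)
  vesselMask <- rr <= radius
  for (s in .tubeSlices(shape, spacing, axis))
    vox <- .setSlice(vox, axis, s, vesselMask, unname(lm[vessel]))

  wrapSlices <- .wrapSliceWindow(shape, axis, as.integer(wrapExtent))
  if (theta > 0) {
    sector <- .sectorMask(grids, center, radius, shellThickness, theta,
                          wrapStart)
    for (s in wrapSlices)
      vox <- .setSlice(vox, axis, s, sector & .getSlice(vox, axis, s) == 0L,
                       unname(lm["tumor"]))
  } else {
    ## detached ball: 2 mm clearance guarantees no in-plane 8-adjacency
    ballR <- shellThickness
    dist <- radius + 2 + ballR
    bc <- center + dist * c(cos(wrapStart * pi / 180),
                            sin(wrapStart * pi / 180))
    zc <- .axisCoords(shape[axis], spacing[axis])
    zmid <- zc[wrapSlices[ceiling(length(wrapSlices) / 2)]]
    for (s in which(abs(zc - zmid) <= ballR)) {
      r2 <- ballR^2 - (zc[s] - zmid)^2
      ball <- (grids$U - bc[1])^2 + (grids$V - bc[2])^2 <= r2
      vox <- .setSlice(vox, axis, s, ball & .getSlice(vox, axis, s) == 0L,
                       unname(lm["tumor"]))
    }
  }

  if (jitter)
    vox <- .withSeed(seed, .jitterTumor(vox, unname(lm["tumor"]),
                                        unname(lm[.VESSELS]), axis,
                                        jitterProb))
  list(volume = LabelVolume(vox, spacing, lm),
       truth = .phantomTruth(structure(theta, names = vessel), rules))
}

#' Multi-vessel wrap phantom
#'
#' One volume containing all five staging-relevant vessels as parallel
#' tubes at disjoint in-plane positions, each with its own wrap angle.
#' The truth records the expected case stage implied by the exact angles.
#'
#' @param wraps named numeric: wrap angle per vessel; must cover CeTr, HA,
#'   SMA, SMV, PV, each in [0, 360]. Vessels at 0 receive no tumor.
#' @inheritParams makeWrapPhantom
#' @return List with `volume` and `truth`, as [makeWrapPhantom()].
#' @examples
#' ph <- makeMultiVesselPhantom(c(CeTr = 0, HA = 0, SMA = 120, SMV = 0,
#'                                PV = 0))
#' truthStage(ph$truth)
#' @export
makeMultiVesselPhantom <- function(wraps, shape = c(96L, 96L, 96L),
                                   spacing = c(0.5, 0.5, 0.5), axis = 3L,
                                   radius = 5, shellThickness = 3,
                                   wrapExtent = 10L, jitter = FALSE,
                                   jitterProb = 0.1, seed = NULL,
                                   rules = defaultRuleSet()) {
  missing <- setdiff(.VESSELS, names(wraps))
  if (length(missing))
    stop("wrap angle missing for: ", paste(missing, collapse = ", "))
  if (any(wraps < 0 | wraps > 360)) stop("wrap angles must lie in [0, 360]")
  shape <- as.integer(shape); axis <- as.integer(axis)
  lm <- defaultLabelMap()
  grids <- .inPlaneGrids(shape, spacing, axis)
  extU <- shape[grids$u] * spacing[grids$u]
  extV <- shape[grids$v] * spacing[grids$v]
  frac <- list(CeTr = c(0.25, 0.25), HA = c(0.75, 0.25),
               SMA = c(0.25, 0.75), SMV = c(0.75, 0.75), PV = c(0.5, 0.5))
  centers <- lapply(frac, function(f) c(f[1] * extU, f[2] * extV))
  cm <- do.call(rbind, centers)
  minSep <- min(stats::dist(cm))
  if (minSep <= 2 * (radius + shellThickness))
    stop("vessels would intersect: tubes too close for this radius/shell")

  vox <- array(0L, shape)
  tubeSl <- .tubeSlices(shape, spacing, axis)
  wrapSl <- .wrapSliceWindow(shape, axis, as.integer(wrapExtent))
  for (i in seq_along(.VESSELS)) {
    v <- .VESSELS[i]
    ctr <- centers[[v]]
    .checkInPlaneFit(ctr, radius, shellThickness, grids, shape, spacing)
    rr <- sqrt((grids$U - ctr[1])^2 + (grids$V - ctr[2])^2)
    vm <- rr <= radius
    for (s in tubeSl)
      vox <- .setSlice(vox, axis, s, vm & .getSlice(vox, axis, s) == 0L,
                       unname(lm[v]))
    th <- wraps[[v]]
    if (th > 0) {
      sector <- .sectorMask(grids, ctr, radius, shellThickness, th,
                            15 + 72 * (i - 1))
      for (s in wrapSl)
        vox <- .setSlice(vox, axis, s,
                         sector & .getSlice(vox, axis, s) == 0L,
                         unname(lm["tumor"]))
    }
  }
  if (jitter)
    vox <- .withSeed(seed, .jitterTumor(vox, unname(lm["tumor"]),
                                        unname(lm[.VESSELS]), axis,
                                        jitterProb))
  list(volume = LabelVolume(vox, spacing, lm),
       truth = .phantomTruth(wraps[.VESSELS], rules))
}

#' Curved (helical) vessel phantom
#'
#' The vessel follows a helical centerline whose amplitude ramps smoothly to
#' zero around the wrap window, so the wrapped sub-segment is straight and
#' the ground-truth angle stays analytic there. Stress-tests the
#' circumference-based measure under vascular curvature.
#'
#' @param amplitude helix amplitude in mm.
#' @param period helix period in slices.
#' @inheritParams makeWrapPhantom
#' @return List with `volume` and `truth`, as [makeWrapPhantom()].
#' @export
makeCurvedVesselPhantom <- function(theta, vessel = "SMA",
                                    shape = c(96L, 96L, 96L),
                                    spacing = c(0.5, 0.5, 0.5), axis = 3L,
                                    radius = 5, shellThickness = 3,
                                    wrapExtent = 10L, wrapStart = 15,
                                    amplitude = 4, period = 48,
                                    jitter = FALSE, jitterProb = 0.1,
                                    seed = NULL, rules = defaultRuleSet()) {
  stopifnot(theta >= 0, theta <= 360, amplitude >= 0, period > 0,
            vessel %in% .VESSELS)
  shape <- as.integer(shape); axis <- as.integer(axis)
  lm <- defaultLabelMap()
  grids <- .inPlaneGrids(shape, spacing, axis)
  base <- c(shape[grids$u] * spacing[grids$u],
            shape[grids$v] * spacing[grids$v]) / 2
  wrapSl <- .wrapSliceWindow(shape, axis, as.integer(wrapExtent))
  straight <- range(wrapSl) + c(-6L, 6L)
  rampLen <- 8
  n <- shape[axis]
  distOut <- pmax(0, pmax(straight[1] - seq_len(n), seq_len(n) - straight[2]))
  w <- pmin(1, distOut / rampLen)
  ramp <- w^2 * (3 - 2 * w)  # smoothstep
  phase <- 2 * pi * seq_len(n) / period
  off <- cbind(amplitude * ramp * cos(phase), amplitude * ramp * sin(phase))
  stepMm <- sqrt(rowSums(diff(off)^2))
  if (any(stepMm > radius / 2))
    stop("helix too sharp: tube would self-intersect ",
         "(reduce amplitude or increase period)")
  centers <- cbind(base[1] + off[, 1], base[2] + off[, 2])
  for (s in seq_len(n))
    .checkInPlaneFit(centers[s, ], radius, shellThickness, grids, shape,
                     spacing)

  vox <- array(0L, shape)
  tubeSl <- .tubeSlices(shape, spacing, axis)
  for (s in tubeSl) {
    rr <- sqrt((grids$U - centers[s, 1])^2 + (grids$V - centers[s, 2])^2)
    vox <- .setSlice(vox, axis, s, rr <= radius, unname(lm[vessel]))
  }
  if (theta > 0) {
    sector <- .sectorMask(grids, base, radius, shellThickness, theta,
                          wrapStart)
    for (s in wrapSl)
      vox <- .setSlice(vox, axis, s, sector & .getSlice(vox, axis, s) == 0L,
                       unname(lm["tumor"]))
  }
  if (jitter)
    vox <- .withSeed(seed, .jitterTumor(vox, unname(lm["tumor"]),
                                        unname(lm[.VESSELS]), axis,
                                        jitterProb))
  list(volume = LabelVolume(vox, spacing, lm),
       truth = .phantomTruth(structure(theta, names = vessel), rules))
}

#' Write a phantom to disk
#'
#' Writes the NIfTI label volume, a JSON truth sidecar (angles, categories,
#' expected stage) and the matching label-map YAML.
#'
#' @param phantom list with `volume` and `truth` as returned by the phantom
#'   generators.
#' @param dir output directory (created if needed).
#' @param basename file stem.
#' @return Named character vector of written paths, invisibly.
#' @export
writePhantom <- function(phantom, dir, basename = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nii <- file.path(dir, paste0(basename, ".nii.gz"))
  writeLabelVolume(phantom$volume, nii)
  lmp <- file.path(dir, paste0(basename, "_labels.yaml"))
  writeLabelMap(labelMap(phantom$volume), lmp)
  tr <- phantom$truth
  trp <- file.path(dir, paste0(basename, "_truth.json"))
  jsonlite::write_json(
    list(angles = as.list(truthAngles(tr)),
         categories = as.list(truthCategories(tr)),
         stage = truthStage(tr)),
    trp, auto_unbox = TRUE, digits = NA)
  invisible(c(volume = nii, labels = lmp, truth = trp))
}
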
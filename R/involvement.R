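#' Find connected vessel components within a plane
#'
#' Returns the connected regions (8-connectivity) of the vessel label in a
#' plane, excluding regions below the minimum pixel count. A curved vessel
#' crosses a plane more than once; involvement is computed per crossing and
#' never pooled, so unrelated arcs are not summed.
#'
#' @param plane a [LabelPlane-class].
#' @param vesselLabel structure name or label value.
#' @param minPixels minimum component size in pixels; smaller specks have
#'   meaningless perimeters and are ignored (default 4).
#' @return List of [VesselComponent-class] objects (empty when the vessel is
#'   absent from the plane).
#' @export
findVesselComponents <- function(plane, vesselLabel, minPixels = 4L) {
  stopifnot(is(plane, "LabelPlane"))
  if (is.character(vesselLabel)) stop("pass a label value, or use ",
                                      "quantifyVessel() for name resolution")
  mask <- plane@pixels == as.integer(vesselLabel)
  if (!any(mask)) return(list())
  lab <- .labelComponents8(mask * 1L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minPixels)
  lapply(keep, function(k) {
    new("VesselComponent", coords = which(lab == k, arr.ind = TRUE),
        axis = plane@axis, index = plane@index)
  })
}

.componentMask <- function(coords, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  m[coords] <- TRUE
  m
}

#' Perimeter of a vessel cross-section component
#'
#' The physical length (mm) of the component's outer boundary, measured as
#' the 0.5 iso-level contour of the hole-filled binary mask (marching
#' squares), smoothed with a circular moving average of the contour vertices
#' (window 5) to remove the half-pixel staircase. Segment lengths use the
#' physical in-plane pixel dimensions, so anisotropic spacing is respected.
#' On digital disks of radius 5-50 px this estimator is within ~1% of
#' \eqn{2\pi r}.
#'
#' @param component a [VesselComponent-class].
#' @param spacing numeric(2), in-plane pixel spacing in mm.
#' @return Perimeter in mm.
#' @examples
#' pl <- new("LabelPlane",
#'   pixels = {m <- matrix(0L, 30, 30); m[8:23, 8:23] <- 4L; m},
#'   spacing = c(1, 1), axis = 3L, index = 1L)
#' comp <- findVesselComponents(pl, 4L)[[1]]
#' componentPerimeter(comp, c(1, 1))
#' @export
componentPerimeter <- function(component, spacing) {
  stopifnot(is(component, "VesselComponent"), length(spacing) == 2L,
            all(spacing > 0))
  co <- component@coords
  nr <- max(co[, 1]) + 1L
  nc <- max(co[, 2]) + 1L
  .componentMeasure(NULL, .componentMask(co, nr, nc), NULL, spacing)$V
}

#' Tumor-contact length of a vessel cross-section component
#'
#' The physical length (mm) of the portion of the component's outer boundary
#' adjacent to tumor pixels. Each boundary segment of the contour separates
#' one vessel pixel from one outside pixel; under the default `"face"`
#' adjacency a segment is in contact when that outside pixel carries the
#' tumor label. The `"diagonal"` rule additionally accepts segments whose
#' outside pixel is background while the underlying vessel boundary pixel
#' has a tumor pixel in its 8-neighbourhood (tolerates single-pixel
#' stair-stepping, at the cost of extending measured arcs by about one
#' boundary pixel per end). Segments on the image border count toward the
#' perimeter but can never be in contact. The result never exceeds
#' [componentPerimeter()] of the same component.
#'
#' @param component a [VesselComponent-class].
#' @param plane the [LabelPlane-class] the component belongs to.
#' @param tumorLabel tumor label value.
#' @param adjacency `"face"` (default) or `"diagonal"`.
#' @return Contact length in mm (0 when no adjacency).
#' @export
componentContactLength <- function(component, plane, tumorLabel,
                                   adjacency = c("face", "diagonal")) {
  stopifnot(is(component, "VesselComponent"), is(plane, "LabelPlane"))
  adjacency <- match.arg(adjacency)
  pix <- plane@pixels
  mask <- .componentMask(component@coords, nrow(pix), ncol(pix))
  .componentMeasure(pix, mask, as.integer(tumorLabel), plane@spacing,
                    adjacency)$TV
}

#' Circumferential involvement in degrees
#'
#' Converts a cross-section's tumor-contact length TV and circumference V
#' into a contact angle. The default `"fraction"` mode computes
#' \eqn{(TV / V) \times 360}, clipped to [0, 360]: 0 for no contact, 360 for
#' full encasement. The `"literal"` mode evaluates
#' \eqn{TV / (TV + (TV - V)) \times 360} exactly as printed in the source
#' method description; that expression is degenerate (zero denominator) at
#' TV = V/2 and negative below, and is retained for transparency only — it
#' agrees with the fraction mode at the anchors TV = 0 and TV = V.
#'
#' @param contactTV contact length, mm (0 <= TV <= V).
#' @param circumferenceV circumference, mm (> 0).
#' @param mode `"fraction"` (default) or `"literal"`.
#' @return Degrees. Fraction mode is always in [0, 360]; literal mode is
#'   unrestricted and raises an error at its degenerate point.
#' @examples
#' involvementDegree(c(0, 2.5, 7.5, 10), 10)        # 0, 90, 270, 360
#' @export
involvementDegree <- function(contactTV, circumferenceV,
                              mode = c("fraction", "literal")) {
  mode <- match.arg(mode)
  if (any(circumferenceV <= 0))
    stop("circumference V must be > 0")
  tol <- 1e-9 * pmax(circumferenceV, 1)
  if (any(contactTV < -tol) || any(contactTV > circumferenceV + tol))
    stop("contact TV must satisfy 0 <= TV <= V")
  contactTV <- pmin(pmax(contactTV, 0), circumferenceV)
  if (mode == "fraction")
    return(pmin(pmax(contactTV / circumferenceV * 360, 0), 360))
  denom <- 2 * contactTV - circumferenceV
  if (any(abs(denom) < 1e-12 * pmax(circumferenceV, 1)))
    stop("literal formula degenerate: denominator TV + (TV - V) is zero ",
         "(at TV = V/2); use mode = \"fraction\"")
  contactTV / denom * 360
}

#' Bin a contact angle into the five radiological categories
#'
#' Exact zero maps to the dedicated "0" group (the rater scale
#' distinguishes no contact); positive angles fall into right-closed
#' intervals (0, 90] -> "0-90", (90, 180] -> "90-180", (180, 270] ->
#' "180-270", (270, 360] -> "270-360". An angle of 89 therefore maps to
#' "0-90" and exactly 270 to "180-270".
#'
#' @param degrees numeric vector in [0, 360].
#' @return Character vector of categories (see [involvementCategories()]).
#' @examples
#' binDegree(c(0, 89, 90, 90.001, 360))
#' @export
binDegree <- function(degrees) {
  if (any(is.na(degrees)) || any(degrees < 0) || any(degrees > 360))
    stop("degrees must lie in [0, 360]")
  out <- as.character(cut(degrees, breaks = c(0, 90, 180, 270, 360),
                          labels = .CATEGORIES[-1], right = TRUE))
  out[degrees == 0] <- "0"
  names(out) <- names(degrees)
  out
}

## Internal fast slice access (raw matrix + in-plane spacing).
.slicePix <- function(volume, axis, index) {
  switch(axis,
    volume@voxels[index, , , drop = TRUE],
    volume@voxels[, index, , drop = TRUE],
    volume@voxels[, , index, drop = TRUE])
}

## Measure every qualifying vessel component in one (cropped) plane.
## Returns a data.frame of V, TV, degrees, border per component (0 rows when
## no component passes the size filter).
.measurePlane <- function(pix, vesselLabel, tumorLabel, spacing, minPixels,
                          adjacency, mode) {
  vmask <- pix == vesselLabel
  tmask <- pix == tumorLabel
  if (!any(vmask) || !any(tmask))
    return(NULL)
  ## crop to the joint bounding box + 2 px so contour neighbourhoods stay in
  ## range except at true image borders
  rr <- range(which(rowSums(vmask | tmask) > 0))
  cc <- range(which(colSums(vmask | tmask) > 0))
  r0 <- max(1L, rr[1] - 2L); r1 <- min(nrow(pix), rr[2] + 2L)
  c0 <- max(1L, cc[1] - 2L); c1 <- min(ncol(pix), cc[2] + 2L)
  sub <- pix[r0:r1, c0:c1, drop = FALSE]
  lab <- .labelComponents8((sub == vesselLabel) * 1L)
  nlab <- max(lab)
  if (nlab == 0L) return(NULL)
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(sizes >= minPixels)
  if (!length(keep)) return(NULL)
  res <- lapply(keep, function(k) {
    m <- .componentMeasure(sub, lab == k, tumorLabel, spacing, adjacency)
    deg <- if (m$V > 0) involvementDegree(m$TV, m$V, mode) else 0
    data.frame(V = m$V, TV = m$TV, degrees = deg, border = m$border)
  })
  do.call(rbind, res)
}

#' Maximum circumferential involvement of one vessel
#'
#' Sweeps every plane, across all three grid axes, that contains both the
#' tumor and the vessel; within each plane measures the contact angle of
#' each connected vessel component (8-connectivity, components under
#' `minComponentPixels` ignored) and takes the plane's maximum over
#' components; returns the maximum over all planes together with the plane
#' attaining it. A vessel with no voxels, or with no plane co-occurring with
#' the tumor, yields 0 degrees and category "0".
#'
#' @param volume a [LabelVolume-class] whose label map declares `"tumor"`
#'   and the requested vessel.
#' @param vessel structure name (e.g. `"SMA"`).
#' @param mode degree formula mode, see [involvementDegree()].
#' @param minComponentPixels minimum vessel component size (default 4).
#' @param adjacency contact rule, see [componentContactLength()].
#' @return A [VesselInvolvement-class].
#' @examples
#' ph <- makeWrapPhantom(90)
#' quantifyVessel(ph$volume, "SMA")
#' @export
quantifyVessel <- function(volume, vessel, mode = c("fraction", "literal"),
                           minComponentPixels = 4L,
                           adjacency = c("face", "diagonal")) {
  stopifnot(is(volume, "LabelVolume"))
  mode <- match.arg(mode)
  adjacency <- match.arg(adjacency)
  if (!is.character(vessel) || length(vessel) != 1L)
    stop("vessel must be a single structure name")
  vl <- .resolveLabel(volume, vessel)
  tl <- .resolveLabel(volume, "tumor")
  warnings <- character()
  absent <- !any(volume@voxels == vl)
  if (absent)
    warnings <- c(warnings, "vessel absent: no voxels in the volume")
  planes <- planesContaining(volume, tl, vl)
  best <- list(deg = -1, V = NA_real_, TV = NA_real_,
               axis = integer(), index = integer())
  borderSeen <- FALSE
  clipped <- FALSE
  if (nrow(planes)) {
    for (i in seq_len(nrow(planes))) {
      ax <- planes$axis[i]; idx <- planes$index[i]
      pix <- .slicePix(volume, ax, idx)
      meas <- .measurePlane(pix, vl, tl, volume@spacing[-ax],
                            minComponentPixels, adjacency, mode)
      if (is.null(meas)) next
      if (any(meas$border)) borderSeen <- TRUE
      j <- which.max(meas$degrees)
      if (meas$degrees[j] > best$deg)
        best <- list(deg = meas$degrees[j], V = meas$V[j], TV = meas$TV[j],
                     axis = ax, index = idx)
    }
  }
  if (best$deg < 0) {
    maxDeg <- 0
    best$V <- numeric(); best$TV <- numeric()
  } else {
    maxDeg <- best$deg
    if (maxDeg > 360 || maxDeg < 0) {  # only reachable in literal mode
      maxDeg <- min(max(maxDeg, 0), 360)
      clipped <- TRUE
    }
  }
  if (borderSeen)
    warnings <- c(warnings,
      "vessel touches the image border in measured planes; border length counts toward the perimeter but never contact")
  if (clipped)
    warnings <- c(warnings, "literal-mode degrees clipped into [0, 360]")
  new("VesselInvolvement", vessel = vessel, maxDegrees = maxDeg,
      category = binDegree(maxDeg), axis = best$axis, index = best$index,
      circumferenceV = if (length(best$V)) best$V else numeric(),
      contactTV = if (length(best$TV)) best$TV else numeric(),
      absent = absent, warnings = warnings)
}

#' Involvement report for all five staging-relevant vessels
#'
#' Runs [quantifyVessel()] for CeTr, HA, SMA, SMV and PV. Vessels without
#' voxels are flagged absent and reported at 0 degrees.
#'
#' @inheritParams quantifyVessel
#' @return An [InvolvementReport-class].
#' @examples
#' ph <- makeMultiVesselPhantom(c(CeTr = 0, HA = 0, SMA = 90, SMV = 225,
#'                                PV = 0))
#' rep <- quantifyVolume(ph$volume)
#' involvementTable(rep)
#' @export
quantifyVolume <- function(volume, mode = c("fraction", "literal"),
                           minComponentPixels = 4L,
                           adjacency = c("face", "diagonal")) {
  stopifnot(is(volume, "LabelVolume"))
  mode <- match.arg(mode)
  adjacency <- match.arg(adjacency)
  .resolveLabel(volume, "tumor")  # tumor must be declared
  res <- lapply(.VESSELS, function(v)
    quantifyVessel(volume, v, mode = mode,
                   minComponentPixels = minComponentPixels,
                   adjacency = adjacency))
  names(res) <- .VESSELS
  new("InvolvementReport", vessels = res)
}

#' Write an involvement report to JSON and CSV
#'
#' One row/entry per vessel: maximum degrees (1 decimal in the CSV),
#' category, argmax plane, V and TV at the argmax plane (mm), absence flag
#' and warnings.
#'
#' @param report an [InvolvementReport-class].
#' @param jsonPath,csvPath output paths (either may be `NULL` to skip).
#' @return The written paths, invisibly.
#' @export
writeInvolvementReport <- function(report, jsonPath = NULL, csvPath = NULL) {
  stopifnot(is(report, "InvolvementReport"))
  tab <- involvementTable(report)
  if (!is.null(csvPath)) {
    out <- tab
    out$max_degrees <- round(out$max_degrees, 1)
    utils::write.csv(out, csvPath, row.names = FALSE)
  }
  if (!is.null(jsonPath))
    jsonlite::write_json(tab, jsonPath, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(c(json = jsonPath, csv = csvPath))
}
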
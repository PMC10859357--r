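#' @import methods
NULL

## Structure vocabulary used throughout the package. The six required names
## are the primary tumor plus the five vessels that determine pancreatic-tumor
## resectability: celiac trunk (CeTr), hepatic artery (HA), superior mesenteric
## artery (SMA), superior mesenteric vein (SMV) and portal vein (PV).
.REQUIRED_STRUCTURES <- c("tumor", "CeTr", "HA", "SMA", "SMV", "PV")
.VESSELS <- c("CeTr", "HA", "SMA", "SMV", "PV")
.CATEGORIES <- c("0", "0-90", "90-180", "180-270", "270-360")
.STAGES <- c("resectable", "borderline_resectable", "locally_advanced")

#' Structure and category vocabularies
#'
#' Constants shared across the package: the five staging-relevant vessels,
#' the six structure names every label map must declare, the five
#' radiological involvement categories, and the three resectability stages
#' in increasing order of severity.
#'
#' @return A character vector.
#' @examples
#' vesselNames()
#' involvementCategories()
#' @export
vesselNames <- function() .VESSELS

#' @rdname vesselNames
#' @export
requiredStructures <- function() .REQUIRED_STRUCTURES

#' @rdname vesselNames
#' @export
involvementCategories <- function() .CATEGORIES

#' @rdname vesselNames
#' @export
resectabilityStages <- function() .STAGES

## ---------------------------------------------------------------------------
## LabelVolume
## ---------------------------------------------------------------------------

#' LabelVolume: a 3D multi-label segmentation grid
#'
#' Holds a 3D integer voxel grid (0 = background), the physical voxel
#' spacing in mm along each grid axis, and a label map assigning a positive
#' integer label value to each structure name. The grid is used exactly as
#' stored; no reorientation to anatomical axes is performed (the involvement
#' measure sweeps all three grid axes, so orientation does not change the
#' maximum).
#'
#' @slot voxels 3D integer array of label values.
#' @slot spacing numeric(3), mm per voxel along each axis (all > 0).
#' @slot labelMap named integer vector mapping structure names to label
#'   values; must contain the six required names (see
#'   [requiredStructures()]) with unique positive values.
#'
#' @aliases LabelVolume
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(voxels = "array", spacing = "numeric", labelMap = "integer"))

.validLabelMap <- function(labelMap) {
  msg <- character()
  if (is.null(names(labelMap)) || any(!nzchar(names(labelMap))))
    msg <- c(msg, "labelMap must be a fully named integer vector")
  missing <- setdiff(.REQUIRED_STRUCTURES, names(labelMap))
  if (length(missing))
    msg <- c(msg, paste0("labelMap missing required structure(s): ",
                         paste(missing, collapse = ", ")))
  if (anyDuplicated(names(labelMap)))
    msg <- c(msg, "labelMap names must be unique")
  if (anyDuplicated(labelMap))
    msg <- c(msg, "labelMap values must be unique")
  if (any(is.na(labelMap)) || any(labelMap <= 0L))
    msg <- c(msg, "labelMap values must be positive integers")
  msg
}

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  msg <- c(msg, .validLabelMap(object@labelMap))
  if (!length(msg)) {
    vals <- unique(as.integer(object@voxels))
    vals <- vals[vals != 0L]
    unknown <- setdiff(vals, unname(object@labelMap))
    if (length(unknown))
      msg <- c(msg, paste0("voxel value(s) not declared in labelMap: ",
                           paste(sort(unknown), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LabelVolume
#'
#' @param voxels 3D array of integer (or exactly integer-valued) labels.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param labelMap named vector mapping structure names to positive integer
#'   label values; must declare all of [requiredStructures()].
#' @return A [LabelVolume-class] object.
#' @examples
#' vox <- array(0L, c(8, 8, 8))
#' vox[4:5, 4:5, ] <- 4L  # SMA
#' vol <- LabelVolume(vox, c(0.5, 0.5, 1), defaultLabelMap())
#' dim(vol)
#' @export
LabelVolume <- function(voxels, spacing, labelMap) {
  if (is.double(voxels)) {
    if (any(voxels != round(voxels)))
      stop("voxel values must be integers (label masks are categorical)")
    storage.mode(voxels) <- "integer"
  }
  lm <- labelMap
  storage.mode(lm) <- "integer"
  new("LabelVolume", voxels = voxels, spacing = as.numeric(spacing),
      labelMap = lm)
}

#' Default label map for the six required structures
#'
#' @return Named integer vector (tumor = 1, CeTr = 2, HA = 3, SMA = 4,
#'   SMV = 5, PV = 6), the convention used by the phantom generator.
#' @export
defaultLabelMap <- function() {
  structure(1:6, names = .REQUIRED_STRUCTURES)
}

## ---------------------------------------------------------------------------
## LabelPlane
## ---------------------------------------------------------------------------

#' LabelPlane: one 2D slice of a LabelVolume
#'
#' A 2D label grid extracted orthogonally to one of the three grid axes,
#' together with its in-plane pixel spacing. Axes and slice indices are
#' 1-based. The in-plane spacing is the pair of volume spacings for the two
#' remaining axes, in ascending axis order (axis 1 drops spacing 1, leaving
#' (spacing 2, spacing 3), and so on); the first matrix dimension
#' corresponds to the lower remaining axis.
#'
#' @slot pixels 2D integer matrix of label values.
#' @slot spacing numeric(2), mm per pixel for the two matrix dimensions.
#' @slot axis integer, the volume axis (1, 2 or 3) the plane is orthogonal to.
#' @slot index integer, 1-based slice position along `axis`.
#' @exportClass LabelPlane
setClass("LabelPlane",
  representation(pixels = "matrix", spacing = "numeric",
                 axis = "integer", index = "integer"))

setValidity("LabelPlane", function(object) {
  msg <- character()
  if (length(object@spacing) != 2L || any(object@spacing <= 0))
    msg <- c(msg, "in-plane spacing must be 2 positive values (mm)")
  if (length(object@axis) != 1L || !(object@axis %in% 1:3))
    msg <- c(msg, "axis must be 1, 2 or 3")
  if (length(object@index) != 1L || object@index < 1L)
    msg <- c(msg, "index must be a positive slice position")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## VesselComponent
## ---------------------------------------------------------------------------

#' VesselComponent: one connected vessel region within a plane
#'
#' A vessel may cross a plane more than once; each crossing is one connected
#' component (8-connectivity) of the vessel label. Involvement degrees are
#' computed per component, never by pooling unrelated crossings.
#'
#' @slot coords integer matrix (n x 2) of pixel coordinates (row, col) in the
#'   parent plane.
#' @slot axis,index plane reference (same convention as [LabelPlane-class]).
#' @exportClass VesselComponent
setClass("VesselComponent",
  representation(coords = "matrix", axis = "integer", index = "integer"))

setValidity("VesselComponent", function(object) {
  if (nrow(object@coords) < 1L) "component must be non-empty"
  else if (ncol(object@coords) != 2L) "coords must be an n x 2 matrix"
  else TRUE
})

## ---------------------------------------------------------------------------
## VesselInvolvement / InvolvementReport
## ---------------------------------------------------------------------------

#' VesselInvolvement: one vessel's maximum circumferential involvement
#'
#' The maximum degree of tumor contact over all planes (all three grid axes)
#' that contain both the vessel and the tumor, with the plane attaining the
#' maximum, the five-group category, and the cross-section measurements at
#' the argmax plane: `circumferenceV` (the vessel segment's outer-contour
#' perimeter, mm) and `contactTV` (the portion of that contour adjacent to
#' tumor, mm).
#'
#' @slot vessel character, vessel name.
#' @slot maxDegrees numeric in [0, 360]; 0 when no co-occurring plane exists.
#' @slot category one of [involvementCategories()].
#' @slot axis,index argmax plane (length 0 when no co-occurring plane).
#' @slot circumferenceV,contactTV mm at the argmax plane (length 0 if none).
#' @slot absent logical, TRUE when the vessel has no voxels in the volume.
#' @slot warnings character vector of measurement caveats (e.g. the vessel
#'   touching the image border, where boundary counts toward the perimeter
#'   but can never be in contact).
#' @exportClass VesselInvolvement
setClass("VesselInvolvement",
  representation(vessel = "character", maxDegrees = "numeric",
                 category = "character", axis = "integer", index = "integer",
                 circumferenceV = "numeric", contactTV = "numeric",
                 absent = "logical", warnings = "character"))

setValidity("VesselInvolvement", function(object) {
  msg <- character()
  if (object@maxDegrees < 0 || object@maxDegrees > 360)
    msg <- c(msg, "maxDegrees must lie in [0, 360]")
  if (!(object@category %in% .CATEGORIES))
    msg <- c(msg, "unknown involvement category")
  if (length(object@contactTV) && length(object@circumferenceV) &&
      object@contactTV > object@circumferenceV + 1e-9)
    msg <- c(msg, "contactTV must not exceed circumferenceV")
  if (length(msg)) msg else TRUE
})

#' InvolvementReport: per-vessel involvement for one volume
#'
#' Exactly one [VesselInvolvement-class] per required vessel (CeTr, HA, SMA,
#' SMV, PV). Use [involvementTable()] for a data.frame view.
#'
#' @slot vessels named list of [VesselInvolvement-class] objects.
#' @exportClass InvolvementReport
setClass("InvolvementReport", representation(vessels = "list"))

setValidity("InvolvementReport", function(object) {
  if (!identical(sort(names(object@vessels)), sort(.VESSELS)))
    return("report must contain exactly the five required vessels")
  ok <- vapply(object@vessels, is, logical(1), class2 = "VesselInvolvement")
  if (!all(ok)) return("all entries must be VesselInvolvement objects")
  TRUE
})

## ---------------------------------------------------------------------------
## RuleSet / StagingResult
## ---------------------------------------------------------------------------

#' RuleSet: degree thresholds mapping involvement to resectability stages
#'
#' Each vessel belongs to a class (arterial or venous); each class has an
#' ordered table of degree intervals, one per stage, jointly covering
#' [0, 360] without gaps or overlap. Interval semantics mirror the binning
#' convention: an interval `[lower, upper]` matches degrees d with
#' `lower < d <= upper`, except that a lower bound of 0 also matches d = 0
#' (so a zero-width `[0, 0]` interval is the exact-zero singleton).
#'
#' The bundled default (`defaultRuleSet()`) encodes the Dutch Pancreatic
#' Cancer Group scheme: arterial contact 0 is compatible with resectable,
#' (0, 90] borderline resectable, > 90 locally advanced; venous contact
#' <= 90 resectable, (90, 270] borderline, > 270 locally advanced.
#' Occlusion/stenosis modifiers carry no signal in a label mask and are not
#' evaluated; the `caveat` slot states this on every staging result.
#'
#' @slot vesselClasses named character, vessel name -> "arterial"/"venous".
#' @slot arterialStages,venousStages data.frame with columns `stage`,
#'   `lower`, `upper` (degrees), ordered, contiguous, covering [0, 360].
#' @slot caveat character, fixed caveat carried into results.
#' @exportClass RuleSet
setClass("RuleSet",
  representation(vesselClasses = "character", arterialStages = "data.frame",
                 venousStages = "data.frame", caveat = "character"))

.validStageTable <- function(df, what) {
  msg <- character()
  need <- c("stage", "lower", "upper")
  if (!all(need %in% names(df)))
    return(paste0(what, ": stage table needs columns stage, lower, upper"))
  if (!all(df$stage %in% .STAGES))
    msg <- c(msg, paste0(what, ": unknown stage name(s): ",
                         paste(setdiff(df$stage, .STAGES), collapse = ", ")))
  if (anyDuplicated(df$stage))
    msg <- c(msg, paste0(what, ": duplicated stage"))
  if (nrow(df) < 1L) return(paste0(what, ": empty stage table"))
  if (df$lower[1] != 0)
    msg <- c(msg, paste0(what, ": thresholds must start at 0"))
  if (df$upper[nrow(df)] != 360)
    msg <- c(msg, paste0(what, ": thresholds must reach 360 (gap at the top)"))
  if (any(df$upper < df$lower))
    msg <- c(msg, paste0(what, ": interval with upper < lower"))
  if (nrow(df) > 1L) {
    gaps <- df$lower[-1] != df$upper[-nrow(df)]
    if (any(gaps))
      msg <- c(msg, paste0(what, ": gap/overlap between intervals ",
                           paste(which(gaps), collapse = ", "),
                           " and the next"))
  }
  if (any(df$upper == df$lower & df$lower != 0))
    msg <- c(msg, paste0(what, ": zero-width interval only allowed at 0"))
  msg
}

setValidity("RuleSet", function(object) {
  msg <- character()
  missing <- setdiff(.VESSELS, names(object@vesselClasses))
  if (length(missing))
    msg <- c(msg, paste0("vessel(s) without a class: ",
                         paste(missing, collapse = ", ")))
  if (!all(object@vesselClasses %in% c("arterial", "venous")))
    msg <- c(msg, "vessel classes must be 'arterial' or 'venous'")
  msg <- c(msg, .validStageTable(object@arterialStages, "arterial"))
  msg <- c(msg, .validStageTable(object@venousStages, "venous"))
  if (length(msg)) msg else TRUE
})

#' StagingResult: the case-level resectability decision
#'
#' @slot stage one of [resectabilityStages()].
#' @slot perVessel data.frame with columns `vessel`, `class`, `degrees`,
#'   `stage`: the stage each vessel individually implies.
#' @slot drivingVessels vessels whose individual stage equals the case stage.
#' @slot caveat character, carried over from the [RuleSet-class].
#' @exportClass StagingResult
setClass("StagingResult",
  representation(stage = "character", perVessel = "data.frame",
                 drivingVessels = "character", caveat = "character"))

setValidity("StagingResult", function(object) {
  if (!(object@stage %in% .STAGES)) return("unknown stage")
  if (!length(object@drivingVessels))
    return("decision trace must name at least one vessel")
  TRUE
})

## ---------------------------------------------------------------------------
## PhantomTruth
## ---------------------------------------------------------------------------

#' PhantomTruth: analytic ground truth of a generated phantom
#'
#' Records the exact wrap angle per vessel, the category each angle falls in,
#' and the case stage the exact angles imply under the supplied rule set.
#' Categories and stage are always recomputed from the angles through the
#' public [binDegree()] and [classifyStage()] operations, never stored
#' independently.
#'
#' @slot angles named numeric, exact wrap angle (degrees) per vessel.
#' @slot categories named character, `binDegree` of each angle.
#' @slot stage character, `classifyStage` of the exact angles.
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(angles = "numeric", categories = "character",
                 stage = "character"))

## ---------------------------------------------------------------------------
## Evaluation results
## ---------------------------------------------------------------------------

#' AgreementResult: categorical agreement between model and rater
#'
#' @slot nAgree,nTotal integer counts of exact category matches / records.
#' @slot fraction nAgree / nTotal.
#' @slot strata data.frame with per-stratum `stratum`, `nAgree`, `nTotal`,
#'   `fraction` (zero rows when unstratified).
#' @exportClass AgreementResult
setClass("AgreementResult",
  representation(nAgree = "integer", nTotal = "integer",
                 fraction = "numeric", strata = "data.frame"))

setValidity("AgreementResult", function(object) {
  msg <- character()
  if (object@nTotal < 1L) msg <- c(msg, "empty agreement result")
  if (abs(object@fraction - object@nAgree / object@nTotal) > 1e-12)
    msg <- c(msg, "fraction must equal nAgree / nTotal")
  if (nrow(object@strata) &&
      (sum(object@strata$nTotal) != object@nTotal ||
       sum(object@strata$nAgree) != object@nAgree))
    msg <- c(msg, "strata counts must sum to the totals")
  if (length(msg)) msg else TRUE
})

#' AnovaResult: classical one-way analysis of variance
#'
#' @slot F F statistic (between-group MS / within-group MS); `Inf` for the
#'   degenerate zero-within-variance, unequal-means case.
#' @slot p p-value from the F distribution (0 in the degenerate case).
#' @slot dfBetween,dfWithin degrees of freedom.
#' @slot nGroups,nTotal group count and total observations.
#' @exportClass AnovaResult
setClass("AnovaResult",
  representation(F = "numeric", p = "numeric", dfBetween = "integer",
                 dfWithin = "integer", nGroups = "integer",
                 nTotal = "integer"))
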
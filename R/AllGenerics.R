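#' Accessors for VesselContact classes
#'
#' Slot access goes through these accessors, never through `@`.
#'
#' @param object,x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))

#' @rdname accessors
#' @export
setGeneric("planePixels", function(object) standardGeneric("planePixels"))

#' @rdname accessors
#' @export
setGeneric("planeAxis", function(object) standardGeneric("planeAxis"))

#' @rdname accessors
#' @export
setGeneric("planeIndex", function(object) standardGeneric("planeIndex"))

#' @rdname accessors
#' @export
setGeneric("componentCoords",
           function(object) standardGeneric("componentCoords"))

#' @rdname accessors
#' @export
setGeneric("maxDegrees", function(object) standardGeneric("maxDegrees"))

#' @rdname accessors
#' @export
setGeneric("involvementCategory",
           function(object) standardGeneric("involvementCategory"))

#' Tabular view of an involvement report
#'
#' @param object an [InvolvementReport-class] or [VesselInvolvement-class].
#' @return data.frame with one row per vessel: `vessel`, `max_degrees`,
#'   `category`, `axis`, `index`, `circumference_V_mm`, `contact_TV_mm`,
#'   `absent`, `warnings`.
#' @export
setGeneric("involvementTable",
           function(object) standardGeneric("involvementTable"))

#' @rdname accessors
#' @export
setGeneric("vesselClasses", function(object) standardGeneric("vesselClasses"))

#' @rdname accessors
#' @export
setGeneric("stageTable", function(object, class) standardGeneric("stageTable"))

#' @rdname accessors
#' @export
setGeneric("caseStage", function(object) standardGeneric("caseStage"))

#' @rdname accessors
#' @export
setGeneric("drivingVessels",
           function(object) standardGeneric("drivingVessels"))

#' @rdname accessors
#' @export
setGeneric("truthAngles", function(object) standardGeneric("truthAngles"))

#' @rdname accessors
#' @export
setGeneric("truthCategories",
           function(object) standardGeneric("truthCategories"))

#' @rdname accessors
#' @export
setGeneric("truthStage", function(object) standardGeneric("truthStage"))

#' Classify case resectability from per-vessel involvement
#'
#' @param report an [InvolvementReport-class], or a named numeric vector of
#'   per-vessel degrees covering all five required vessels.
#' @param rules a [RuleSet-class]; defaults to the bundled DPCG encoding.
#' @return A [StagingResult-class]: the case stage is the maximum severity
#'   over vessels (resectable < borderline_resectable < locally_advanced),
#'   with the vessels that drove the decision.
#' @examples
#' classifyStage(c(CeTr = 0, HA = 0, SMA = 120, SMV = 0, PV = 0))
#' @export
setGeneric("classifyStage",
           function(report, rules = defaultRuleSet())
             standardGeneric("classifyStage"))
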
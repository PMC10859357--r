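#' @rdname accessors
setMethod("voxels", "LabelVolume", function(object) object@voxels)

#' @rdname accessors
setMethod("spacing", "LabelVolume", function(object) object@spacing)

#' @rdname accessors
setMethod("spacing", "LabelPlane", function(object) object@spacing)

#' @rdname accessors
setMethod("labelMap", "LabelVolume", function(object) object@labelMap)

#' @rdname accessors
#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@voxels))

#' @rdname accessors
setMethod("planePixels", "LabelPlane", function(object) object@pixels)

#' @rdname accessors
setMethod("planeAxis", "LabelPlane", function(object) object@axis)

#' @rdname accessors
setMethod("planeIndex", "LabelPlane", function(object) object@index)

#' @rdname accessors
setMethod("componentCoords", "VesselComponent",
          function(object) object@coords)

#' @rdname accessors
setMethod("maxDegrees", "VesselInvolvement", function(object) object@maxDegrees)

#' @rdname accessors
setMethod("involvementCategory", "VesselInvolvement",
          function(object) object@category)

.involvementRow <- function(vi) {
  data.frame(
    vessel = vi@vessel,
    max_degrees = vi@maxDegrees,
    category = vi@category,
    axis = if (length(vi@axis)) vi@axis else NA_integer_,
    index = if (length(vi@index)) vi@index else NA_integer_,
    circumference_V_mm = if (length(vi@circumferenceV)) vi@circumferenceV
                         else NA_real_,
    contact_TV_mm = if (length(vi@contactTV)) vi@contactTV else NA_real_,
    absent = vi@absent,
    warnings = paste(vi@warnings, collapse = "; "),
    stringsAsFactors = FALSE)
}

#' @rdname involvementTable
setMethod("involvementTable", "VesselInvolvement",
          function(object) .involvementRow(object))

#' @rdname involvementTable
setMethod("involvementTable", "InvolvementReport", function(object) {
  out <- do.call(rbind, lapply(object@vessels[.VESSELS], .involvementRow))
  rownames(out) <- NULL
  out
})

#' @rdname accessors
setMethod("vesselClasses", "RuleSet", function(object) object@vesselClasses)

#' @rdname accessors
setMethod("stageTable", "RuleSet", function(object, class) {
  class <- match.arg(class, c("arterial", "venous"))
  if (class == "arterial") object@arterialStages else object@venousStages
})

#' @rdname accessors
setMethod("caseStage", "StagingResult", function(object) object@stage)

#' @rdname accessors
setMethod("drivingVessels", "StagingResult",
          function(object) object@drivingVessels)

#' @rdname accessors
setMethod("truthAngles", "PhantomTruth", function(object) object@angles)

#' @rdname accessors
setMethod("truthCategories", "PhantomTruth", function(object) object@categories)

#' @rdname accessors
setMethod("truthStage", "PhantomTruth", function(object) object@stage)

## show methods -------------------------------------------------------------

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("LabelVolume %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
  present <- names(object@labelMap)[object@labelMap %in%
                                    unique(as.integer(object@voxels))]
  cat("  structures present:",
      if (length(present)) paste(present, collapse = ", ") else "(none)",
      "\n")
})

setMethod("show", "LabelPlane", function(object) {
  cat(sprintf("LabelPlane axis %d, index %d (%d x %d px, %s mm)\n",
              object@axis, object@index, nrow(object@pixels),
              ncol(object@pixels),
              paste(format(object@spacing), collapse = " x ")))
})

setMethod("show", "VesselInvolvement", function(object) {
  cat(sprintf("%s: %.1f degrees [%s]%s\n", object@vessel, object@maxDegrees,
              object@category, if (object@absent) " (absent)" else ""))
  if (length(object@axis))
    cat(sprintf("  argmax plane axis %d index %d: V = %.2f mm, TV = %.2f mm\n",
                object@axis, object@index, object@circumferenceV,
                object@contactTV))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "InvolvementReport", function(object) {
  cat("InvolvementReport (maximum circumferential involvement per vessel)\n")
  print(involvementTable(object), digits = 4)
})

setMethod("show", "RuleSet", function(object) {
  cat("RuleSet (degrees -> resectability stage)\n")
  cl <- object@vesselClasses
  cat("  arterial:", paste(names(cl)[cl == "arterial"], collapse = ", "), "\n")
  cat("  venous:  ", paste(names(cl)[cl == "venous"], collapse = ", "), "\n")
  for (k in c("arterial", "venous")) {
    df <- stageTable(object, k)
    cat(" ", k, "stages:\n")
    for (i in seq_len(nrow(df)))
      cat(sprintf("    %-22s (%g, %g]%s\n", df$stage[i], df$lower[i],
                  df$upper[i],
                  if (df$lower[i] == 0) " (lower bound includes 0)" else ""))
  }
})

setMethod("show", "StagingResult", function(object) {
  cat("Resectability stage:", object@stage, "\n")
  cat("  driven by:", paste(object@drivingVessels, collapse = ", "), "\n")
  print(object@perVessel, digits = 4)
  cat("  caveat:", object@caveat, "\n")
})

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth\n")
  df <- data.frame(vessel = names(object@angles),
                   wrap_degrees = unname(object@angles),
                   category = unname(object@categories))
  print(df)
  cat("  expected stage:", object@stage, "\n")
})

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf("Agreement: %d/%d (%.1f%%)\n", object@nAgree, object@nTotal,
              100 * object@fraction))
  if (nrow(object@strata)) print(object@strata, digits = 3)
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.4g, p = %.3g (%d groups, n = %d)\n",
    object@dfBetween, object@dfWithin, object@F, object@p, object@nGroups,
    object@nTotal))
})
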
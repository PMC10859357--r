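.makeStageDf <- function(lst, what) {
  if (is.null(lst) || !length(lst))
    stop("ruleset: missing ", what, " stage table")
  df <- data.frame(stage = names(lst),
                   lower = vapply(lst, function(x) as.numeric(x[[1]]),
                                  numeric(1)),
                   upper = vapply(lst, function(x) as.numeric(x[[2]]),
                                  numeric(1)),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df[order(df$lower, df$upper), , drop = FALSE]
}

#' Read a resectability rule set from YAML or JSON
#'
#' The configuration has three keys: `vessel_classes` (vessel name ->
#' `arterial`/`venous`), `arterial_stages` and `venous_stages` (stage name ->
#' `[lower, upper]` degree interval). Intervals are right-closed and must
#' jointly cover [0, 360] per class without gaps or overlap; a `[0, 0]`
#' interval is the exact-zero singleton. Validation errors name the
#' offending class.
#'
#' @param path path to the configuration file.
#' @return A [RuleSet-class].
#' @seealso [defaultRuleSet()] for the bundled DPCG encoding.
#' @export
readRuleSet <- function(path) {
  if (!file.exists(path)) stop("ruleset file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported ruleset format: .", ext))
  if (is.null(raw$vessel_classes))
    stop("ruleset: missing vessel_classes")
  classes <- vapply(raw$vessel_classes, as.character, character(1))
  new("RuleSet",
      vesselClasses = classes,
      arterialStages = .makeStageDf(raw$arterial_stages, "arterial"),
      venousStages = .makeStageDf(raw$venous_stages, "venous"),
      caveat = .STAGING_CAVEAT)
}

.STAGING_CAVEAT <- paste(
  "vessel occlusion/stenosis modifiers are not evaluated:",
  "label masks carry no such signal")

#' The bundled DPCG rule set
#'
#' Degree thresholds encoding the Dutch Pancreatic Cancer Group resectability
#' scheme: arterial vessels (CeTr, HA, SMA) — contact 0 compatible with
#' resectable, (0, 90] borderline resectable, over 90 locally advanced;
#' venous vessels (SMV, PV) — up to 90 resectable, (90, 270] borderline,
#' over 270 locally advanced. Loaded from the package's
#' `extdata/dpcg_default.yaml`, which users may copy and override.
#'
#' @return A [RuleSet-class].
#' @examples
#' defaultRuleSet()
#' @export
defaultRuleSet <- function() {
  readRuleSet(system.file("extdata", "dpcg_default.yaml",
                          package = "VesselContact", mustWork = TRUE))
}

## Stage implied by a single degree value under one class's table.
## Right-closed: lower < d <= upper; a lower bound of 0 also admits d == 0.
.stageForDegrees <- function(degrees, stageDf) {
  hit <- (degrees > stageDf$lower & degrees <= stageDf$upper) |
         (degrees == 0 & stageDf$lower == 0)
  stageDf$stage[which(hit)[1]]
}

.classifyAngles <- function(angles, rules) {
  missing <- setdiff(.VESSELS, names(angles))
  if (length(missing))
    stop("degrees missing for vessel(s): ", paste(missing, collapse = ", "))
  if (any(is.na(angles[.VESSELS])) || any(angles[.VESSELS] < 0) ||
      any(angles[.VESSELS] > 360))
    stop("degrees must lie in [0, 360]")
  per <- do.call(rbind, lapply(.VESSELS, function(v) {
    cls <- rules@vesselClasses[[v]]
    tab <- if (cls == "arterial") rules@arterialStages else rules@venousStages
    data.frame(vessel = v, class = cls, degrees = unname(angles[[v]]),
               stage = .stageForDegrees(unname(angles[[v]]), tab),
               stringsAsFactors = FALSE)
  }))
  sev <- match(per$stage, .STAGES)
  top <- max(sev)
  new("StagingResult", stage = .STAGES[top], perVessel = per,
      drivingVessels = per$vessel[sev == top], caveat = rules@caveat)
}

#' @rdname classifyStage
setMethod("classifyStage", "InvolvementReport", function(report, rules) {
  stopifnot(is(rules, "RuleSet"))
  tab <- involvementTable(report)
  angles <- structure(tab$max_degrees, names = tab$vessel)
  .classifyAngles(angles, rules)
})

#' @rdname classifyStage
setMethod("classifyStage", "numeric", function(report, rules) {
  stopifnot(is(rules, "RuleSet"))
  .classifyAngles(report, rules)
})
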
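#' Read rater involvement categories from CSV
#'
#' Expects columns `case_id`, `vessel`, `rater_category`; categories are
#' validated against the five-group vocabulary
#' ([involvementCategories()]) and vessels against the five required
#' vessels.
#'
#' @param path CSV path.
#' @return data.frame with the three validated columns.
#' @export
readRaterCategories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "vessel", "rater_category")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("rater CSV missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$rater_category), .CATEGORIES)
  if (length(bad))
    stop("unknown rater categories: ", paste(bad, collapse = ", "),
         " (expected ", paste(.CATEGORIES, collapse = ", "), ")")
  badv <- setdiff(unique(df$vessel), .VESSELS)
  if (length(badv))
    stop("unknown vessels in rater CSV: ", paste(badv, collapse = ", "))
  df[need]
}

.checkPairs <- function(pairs) {
  need <- c("model_category", "rater_category")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop("paired assessments missing column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(pairs)) stop("paired assessments are empty")
  if (any(is.na(pairs$model_category)) || any(is.na(pairs$rater_category)))
    stop("paired assessments contain missing categories")
  if ("model_degrees" %in% names(pairs)) {
    expected <- binDegree(pairs$model_degrees)
    off <- which(expected != pairs$model_category)
    if (length(off))
      stop("model_category inconsistent with binDegree(model_degrees) ",
           "for record(s): ", paste(utils::head(off, 5), collapse = ", "))
  }
  invisible(pairs)
}

#' Categorical agreement between model and rater
#'
#' Counts exact category matches, overall and optionally per stratum (e.g.
#' arteries vs veins, or resectability classes). The same operation serves
#' vessel-level involvement agreement and case-level stage agreement;
#' category vocabularies are not restricted here.
#'
#' @param pairs data.frame with columns `model_category` and
#'   `rater_category` (and, optionally, `model_degrees`, which is checked
#'   for consistency with [binDegree()]).
#' @param stratifyBy optional name of a column in `pairs` to break the
#'   counts down by.
#' @return An [AgreementResult-class].
#' @examples
#' pairs <- data.frame(model_category = c("0", "0-90", "0-90", "90-180"),
#'                     rater_category = c("0", "0-90", "90-180", "90-180"))
#' categoricalAgreement(pairs)
#' @export
categoricalAgreement <- function(pairs, stratifyBy = NULL) {
  .checkPairs(pairs)
  agree <- pairs$model_category == pairs$rater_category
  strata <- data.frame(stratum = character(), nAgree = integer(),
                       nTotal = integer(), fraction = numeric())
  if (!is.null(stratifyBy)) {
    if (!(stratifyBy %in% names(pairs)))
      stop("no such stratifier column: ", stratifyBy)
    byStr <- split(agree, pairs[[stratifyBy]])
    strata <- data.frame(
      stratum = names(byStr),
      nAgree = vapply(byStr, function(x) sum(x), integer(1)),
      nTotal = vapply(byStr, length, integer(1)),
      stringsAsFactors = FALSE)
    strata$fraction <- strata$nAgree / strata$nTotal
    rownames(strata) <- NULL
  }
  new("AgreementResult", nAgree = sum(agree), nTotal = length(agree),
      fraction = mean(agree), strata = strata)
}

#' Per-rater-group summary of the model's continuous degrees
#'
#' For each of the five rater categories present in the data, the median and
#' interquartile bounds (Q1, Q3; linear interpolation between order
#' statistics, `stats::quantile` type 7) of the model's continuous degree
#' output. Groups absent from the data are omitted and listed in the
#' `missing_groups` attribute.
#'
#' @param pairs data.frame with columns `rater_category` and
#'   `model_degrees`.
#' @return data.frame with columns `rater_category`, `n`, `median`, `q1`,
#'   `q3`, ordered by category severity.
#' @export
summarizeByRaterGroup <- function(pairs) {
  need <- c("rater_category", "model_degrees")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(pairs)) stop("paired assessments are empty")
  present <- .CATEGORIES[.CATEGORIES %in% unique(pairs$rater_category)]
  out <- do.call(rbind, lapply(present, function(g) {
    x <- pairs$model_degrees[pairs$rater_category == g]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(rater_category = g, n = length(x), median = q[2],
               q1 = q[1], q3 = q[3], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  missingGroups <- setdiff(.CATEGORIES, present)
  if (length(missingGroups))
    message("groups absent from the data: ",
            paste(missingGroups, collapse = ", "))
  attr(out, "missing_groups") <- missingGroups
  out
}

#' Classical one-way analysis of variance
#'
#' Between/within sums-of-squares decomposition via `stats::lm`/`anova`,
#' testing whether any group means differ. The degenerate case of zero
#' within-group variance with unequal means is reported as `F = Inf`,
#' `p = 0`.
#'
#' @param groups list of numeric vectors, one per group; at least two
#'   groups, each non-empty, and at least one group with two or more values.
#' @return An [AnovaResult-class].
#' @examples
#' oneWayAnova(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
oneWayAnova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 1L)) stop("every group must contain at least one value")
  if (!any(n >= 2L)) stop("at least one group needs two or more values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n))
  ## perfect-fit warnings are expected here: the zero-within-variance case
  ## is handled explicitly below
  at <- suppressWarnings(stats::anova(stats::lm(values ~ g)))
  ssb <- at[["Sum Sq"]][1]
  ssw <- at[["Sum Sq"]][2]
  dfb <- at[["Df"]][1]
  dfw <- at[["Df"]][2]
  if (ssw <= 1e-12 * max(ssb, 1)) {
    if (ssb <= 1e-12) {                       # all values identical
      F <- 0; p <- 1
    } else {                                  # unequal means, no noise
      F <- Inf; p <- 0
    }
  } else {
    F <- (ssb / dfb) / (ssw / dfw)
    p <- stats::pf(F, dfb, dfw, lower.tail = FALSE)
  }
  new("AnovaResult", F = F, p = p, dfBetween = as.integer(dfb),
      dfWithin = as.integer(dfw), nGroups = length(groups),
      nTotal = length(values))
}

#' Pair measured phantom reports with their ground truth
#'
#' Convenience builder for evaluation fixtures: given measured involvement
#' reports and the matching phantom truths, emits the long-format paired
#' table [categoricalAgreement()] and [summarizeByRaterGroup()] consume,
#' with the truth category playing the rater role.
#'
#' @param reports list of [InvolvementReport-class].
#' @param truths list of [PhantomTruth-class], same length/order.
#' @return data.frame with columns `case_id`, `vessel`, `model_degrees`,
#'   `model_category`, `rater_category`.
#' @export
pairWithTruth <- function(reports, truths) {
  stopifnot(length(reports) == length(truths))
  out <- lapply(seq_along(reports), function(i) {
    tab <- involvementTable(reports[[i]])
    data.frame(case_id = i, vessel = tab$vessel,
               model_degrees = tab$max_degrees,
               model_category = tab$category,
               rater_category = unname(
                 truthCategories(truths[[i]])[tab$vessel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
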
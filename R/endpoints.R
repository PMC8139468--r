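## Graft-survival end-points: fixed horizons at which the outcome is
## dichotomised, and the censoring/exclusion rule that labels each transplant.

.endpointInfo <- function() {
  if (is.null(.lmCache$endpoints)) {
    raw <- jsonlite::read_json(fixturePath("endpoint_classes.json"))
    .lmCache$endpoints <- raw$endpoints
  }
  .lmCache$endpoints
}

#' Construct an end-point
#'
#' The four standard horizons are 3 months (91 days), 1 year (365), 2 years
#' (730) and 5 years (1825). The day counts follow the calendar-year
#' convention and are overridable, since "3 months" admits 90-92 days.
#'
#' @param label one of `"3M"`, `"1Y"`, `"2Y"`, `"5Y"`.
#' @param horizon optional override of the horizon in days.
#' @return an [EndPoint-class] object.
#' @examples
#' endPoint("5Y")
#' @export
endPoint <- function(label = c("3M", "1Y", "2Y", "5Y"), horizon = NULL) {
  label <- match.arg(label)
  if (is.null(horizon)) horizon <- .endpointInfo()[[label]]$horizon_days
  new("EndPoint", label = label, horizon = as.numeric(horizon))
}

#' Registry class distribution per end-point
#'
#' Returns the packaged cohort size and class split per end-point, and the
#' graft-survival share used as the calibration target of the synthetic
#' generator (e.g. 11570/20456 at five years).
#'
#' @return data frame with columns `endpoint`, `horizon`, `nonSurvival`,
#'   `survival`, `total`, `survivalShare`.
#' @export
endpointClassTable <- function() {
  info <- .endpointInfo()
  do.call(rbind, lapply(names(info), function(ep) {
    e <- info[[ep]]
    data.frame(endpoint = ep, horizon = e$horizon_days,
               nonSurvival = e$non_survival, survival = e$survival,
               total = e$total,
               survivalShare = e$survival / e$total)
  }))
}

#' @rdname endpointClassTable
#' @param label end-point label.
#' @return `survivalPrevalence()`: the graft-survival share for one end-point.
#' @export
survivalPrevalence <- function(label) {
  e <- .endpointInfo()[[label]]
  if (is.null(e)) stop("unknown end-point '", label, "'")
  e$survival / e$total
}

#' Label transplants at an end-point
#'
#' Dichotomises each outcome record at the end-point horizon. Graft survival
#' runs from transplantation until a re-transplant is required or the
#' recipient dies of transplant-related causes:
#' * `non-survival` if graft failure occurs at or before the horizon;
#' * `survival` if follow-up reaches the horizon without failure;
#' * `excluded` if follow-up ends before the horizon without failure
#'   (censored), or if the death was unrelated to the transplantation
#'   procedure.
#'
#' @param failureDay day of graft failure, `NA` if none observed.
#' @param followupDay last follow-up day (must be >= `failureDay` when both
#'   are present).
#' @param unrelatedDeath 0/1 flag: death unrelated to the transplant.
#' @param ep an [EndPoint-class].
#' @return factor with levels `survival`, `non-survival`, `excluded`.
#' @examples
#' ep <- endPoint("3M")
#' labelEndpoint(60, 60, 0, ep)             # failure inside horizon
#' labelEndpoint(NA, 200, 0, endPoint("1Y")) # censored -> excluded
#' @export
labelEndpoint <- function(failureDay, followupDay, unrelatedDeath, ep) {
  stopifnot(is(ep, "EndPoint"))
  n <- max(length(failureDay), length(followupDay), length(unrelatedDeath))
  failureDay <- rep_len(failureDay, n)
  followupDay <- rep_len(followupDay, n)
  unrelatedDeath <- rep_len(unrelatedDeath, n)
  if (any(stats::na.omit(c(failureDay, followupDay)) < 0))
    stop("negative event times are invalid", call. = FALSE)
  bad <- !is.na(failureDay) & !is.na(followupDay) & failureDay > followupDay
  if (any(bad))
    stop("failure time after last follow-up in record ", which(bad)[1],
         call. = FALSE)
  out <- rep("excluded", n)
  failed <- !is.na(failureDay) & failureDay <= ep@horizon
  survived <- !failed & !is.na(followupDay) & followupDay >= ep@horizon
  out[failed] <- "non-survival"
  out[survived] <- "survival"
  out[unrelatedDeath == 1] <- "excluded"
  factor(out, levels = c("survival", "non-survival", "excluded"))
}

#' @describeIn EndPoint-class display label and horizon.
#' @param object an `EndPoint`.
#' @export
setMethod("show", "EndPoint", function(object) {
  cat("EndPoint ", object@label, " (horizon ", object@horizon, " days)\n",
      sep = "")
})
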
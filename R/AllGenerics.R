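#' Predict graft-survival probability
#'
#' Applies a logistic model to encoded feature vectors (or to a raw cohort
#' data frame, which is encoded with the model's own scaling first) and
#' returns the Bernoulli parameter p: the probability that the graft survives
#' past the model's end-point horizon.
#'
#' @param model a [LogisticModel-class].
#' @param newdata an encoded numeric vector, an encoded matrix with one row
#'   per pair, or a complete (imputed) cohort data frame.
#' @return numeric vector of probabilities in (0, 1).
#' @examples
#' m <- new("LogisticModel", weights = c(a = 1, b = -1), intercept = 0,
#'          scaling = identityScaling(character(0)))
#' predictProbability(m, c(a = 2, b = 1))   # plogis(1)
#' @export
setGeneric("predictProbability", function(model, newdata)
  standardGeneric("predictProbability"))

#' @rdname minimumSensitivity
#' @export
setGeneric("minimumSensitivity", function(x) standardGeneric("minimumSensitivity"))

#' @rdname accuracy
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname allocationAccessors
#' @export
setGeneric("chosenRecipients", function(x) standardGeneric("chosenRecipients"))

#' @rdname allocationAccessors
#' @export
setGeneric("decisionStages", function(x) standardGeneric("decisionStages"))

#' @rdname allocationAccessors
#' @export
setGeneric("candidateSets", function(x) standardGeneric("candidateSets"))

#' @rdname scenarioAccessors
#' @export
setGeneric("scenarioProbs", function(x) standardGeneric("scenarioProbs"))

#' @rdname scenarioAccessors
#' @export
setGeneric("recipientMELD", function(x) standardGeneric("recipientMELD"))

#' @rdname scenarioAccessors
#' @export
setGeneric("waitingDays", function(x) standardGeneric("waitingDays"))
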
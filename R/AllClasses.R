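#' @import methods
NULL

#' ScalingStats: per-variable location/scale for numeric features
#'
#' Holds the location and scale applied to each continuous donor/recipient
#' variable before it enters a linear predictor. Binary and one-hot components
#' are never rescaled, so the statistics cover only the numeric fields of the
#' cohort schema.
#'
#' @slot location named numeric, one entry per numeric field.
#' @slot scale named numeric, strictly positive, same names as `location`.
#' @seealso [fitScaling()], [identityScaling()], [syntheticScaling()]
#' @export
setClass("ScalingStats",
  representation(location = "numeric", scale = "numeric"),
  validity = function(object) {
    if (!identical(names(object@location), names(object@scale)))
      return("location and scale must cover the same fields, in the same order")
    if (is.null(names(object@location)) && length(object@location) > 0)
      return("scaling statistics must be named by field")
    if (any(!is.finite(object@scale)) || any(object@scale <= 0))
      return("all scale values must be finite and > 0")
    TRUE
  }
)

#' ImputerStats: train-set fill values for missing D-R fields
#'
#' One fill value per schema field: the training-set mean for continuous
#' variables and the training-set mode for binary and nominal variables.
#' Fitting is restricted to training records so that no test-fold value can
#' leak into the statistics.
#'
#' @slot fills named list, one fill value per field.
#' @seealso [fitImputer()], [applyImputer()]
#' @export
setClass("ImputerStats",
  representation(fills = "list"),
  validity = function(object) {
    if (is.null(names(object@fills)) || any(!nzchar(names(object@fills))))
      return("fills must be a named list")
    TRUE
  }
)

#' LogisticModel: logistic graft-survival model
#'
#' A logistic regression model over encoded donor-recipient feature vectors:
#' weights, an intercept (independent term) and the [ScalingStats-class]
#' applied to numeric fields during encoding. The packaged published model
#' carries 49 weights, one per component of the canonical feature order.
#'
#' @slot weights named numeric coefficient vector.
#' @slot intercept numeric scalar independent term.
#' @slot scaling a [ScalingStats-class] object.
#' @seealso [loadPublishedModel()], [fitL1Logistic()], [predictProbability()]
#' @export
setClass("LogisticModel",
  representation(weights = "numeric", intercept = "numeric",
                 scaling = "ScalingStats"),
  validity = function(object) {
    if (length(object@intercept) != 1L || !is.finite(object@intercept))
      return("intercept must be a single finite number")
    if (length(object@weights) == 0L)
      return("weights must be non-empty")
    if (any(!is.finite(object@weights)))
      return("weights must be finite")
    TRUE
  }
)

#' EndPoint: fixed horizon at which graft survival is dichotomised
#'
#' @slot label one of `"3M"`, `"1Y"`, `"2Y"`, `"5Y"`.
#' @slot horizon horizon in days after transplantation.
#' @seealso [endPoint()], [labelEndpoint()]
#' @export
setClass("EndPoint",
  representation(label = "character", horizon = "numeric"),
  validity = function(object) {
    if (length(object@label) != 1L) return("label must be a single string")
    if (length(object@horizon) != 1L || object@horizon <= 0)
      return("horizon must be a single positive number of days")
    TRUE
  }
)

#' CohortConfig: configuration of the synthetic D-R cohort generator
#'
#' @slot n number of donor-recipient pairs to generate.
#' @slot seed integer seed; split internally into independent substreams for
#'   values, missingness, labels and outcome times.
#' @slot missingRate per-field probability that a generated value is masked as
#'   missing; either one shared rate or a named vector. Capped at 0.10, the
#'   screening threshold above which variables were dropped from the schema.
#' @slot marginals named list of overrides: `function(n)` drawing values for a
#'   field, replacing the default marginal (uniform over the admissible range
#'   for numerics, uniform over levels for nominals, Bernoulli(1/2) for
#'   binaries).
#' @slot prevalence named numeric: target graft-survival share per end-point
#'   used to calibrate the ground-truth intercept.
#' @seealso [cohortConfig()], [generatePairs()], [generateCohort()]
#' @export
setClass("CohortConfig",
  representation(n = "integer", seed = "integer", missingRate = "numeric",
                 marginals = "list", prevalence = "numeric"),
  validity = function(object) {
    if (object@n < 1L) return("n must be >= 1")
    if (any(object@missingRate < 0 | object@missingRate > 0.10))
      return("missing rates must lie in [0, 0.10]")
    if (any(object@prevalence <= 0 | object@prevalence >= 1))
      return("target prevalences must lie in (0, 1)")
    TRUE
  }
)

#' ClassifierSpec: a survival-prediction method and its selection grid
#'
#' Names one of the benchmarked classification methods together with its
#' hyperparameter grid for nested model selection. The packaged default grids
#' are the published ones; the naive Bayes grid is empty because the method
#' has no tunable parameters.
#'
#' @slot method one of `"LR"`, `"MLP"`, `"RF"`, `"SVM"`, `"C4.5"`, `"NB"`,
#'   `"kNN"`, `"GB"`.
#' @slot grid named list of candidate values per hyperparameter.
#' @seealso [classifierSpec()], [enumerateGrid()], [trainWithSpec()]
#' @export
setClass("ClassifierSpec",
  representation(method = "character", grid = "list"),
  validity = function(object) {
    if (length(object@method) != 1L) return("method must be a single string")
    if (!object@method %in% .classifierMethods)
      return(paste0("unknown method '", object@method, "'; valid methods: ",
                    paste(.classifierMethods, collapse = ", ")))
    TRUE
  }
)

#' CVPlan: nested cross-validation plan
#'
#' Describes the benchmark protocol: stratified outer folds for evaluation and,
#' within each outer training set, an independent inner cross-validation that
#' selects the hyperparameter configuration maximising mean Minimum
#' Sensitivity. Outer test folds are never touched during selection.
#'
#' @slot outerFolds number of outer evaluation folds.
#' @slot innerFolds number of inner selection folds.
#' @slot metric selection metric; `"MS"` (Minimum Sensitivity).
#' @slot seed integer seed controlling fold assignment and learner seeds.
#' @slot spec the [ClassifierSpec-class] to benchmark.
#' @slot stratified stratify folds by class (recommended; the rarer class can
#'   otherwise vanish from a fold at strongly imbalanced end-points).
#' @slot threshold probability cut-off converting scores into class labels.
#' @seealso [cvPlan()], [runNestedCV()]
#' @export
setClass("CVPlan",
  representation(outerFolds = "integer", innerFolds = "integer",
                 metric = "character", seed = "integer",
                 spec = "ClassifierSpec", stratified = "logical",
                 threshold = "numeric"),
  validity = function(object) {
    if (object@outerFolds < 2L || object@innerFolds < 2L)
      return("outer and inner fold counts must be >= 2")
    if (!object@metric %in% c("MS", "AUC", "Acc"))
      return("selection metric must be one of MS, AUC, Acc")
    if (object@threshold <= 0 || object@threshold >= 1)
      return("threshold must lie in (0, 1)")
    TRUE
  }
)

#' ConfusionMatrix: binary confusion counts
#'
#' Counts with graft survival as the positive class: `tp` survivors predicted
#' to survive, `fn` survivors predicted to fail, `fp` failures predicted to
#' survive, `tn` failures predicted to fail.
#'
#' @slot tp,fn,fp,tn non-negative counts.
#' @seealso [confusionMatrix()], [minimumSensitivity()], [accuracy()]
#' @export
setClass("ConfusionMatrix",
  representation(tp = "numeric", fn = "numeric", fp = "numeric",
                 tn = "numeric"),
  validity = function(object) {
    counts <- c(object@tp, object@fn, object@fp, object@tn)
    if (length(counts) != 4L || any(!is.finite(counts)) || any(counts < 0))
      return("tp, fn, fp, tn must be single non-negative finite counts")
    TRUE
  }
)

#' EvalResult: one model's evaluation on one end-point
#'
#' @slot cm the [ConfusionMatrix-class].
#' @slot acc accuracy in \[0, 1\].
#' @slot ms Minimum Sensitivity, the smaller of the two per-class recalls.
#' @slot auc area under the ROC curve.
#' @slot wallTime elapsed seconds (informational only).
#' @seealso [evaluateScores()]
#' @export
setClass("EvalResult",
  representation(cm = "ConfusionMatrix", acc = "numeric", ms = "numeric",
                 auc = "numeric", wallTime = "numeric"),
  validity = function(object) {
    for (m in c("acc", "ms", "auc"))
      if (slot(object, m) < 0 || slot(object, m) > 1)
        return(paste(m, "must lie in [0, 1]"))
    TRUE
  }
)

#' AllocationScenario: recipients-by-donors graft-survival probabilities
#'
#' A waiting-list snapshot: each column holds the predicted graft-survival
#' probability of every listed recipient with one offered donor organ,
#' together with recipient MELD scores and accumulated waiting-list days.
#'
#' @slot probs numeric matrix, recipients in rows, donors in columns,
#'   entries in \[0, 1\].
#' @slot meld recipient MELD scores (6-75 points), one per row.
#' @slot waitDays recipient waiting-list days, one per row, non-negative.
#' @seealso [allocationScenario()], [fixtureScenario()], [allocateMatrix()]
#' @export
setClass("AllocationScenario",
  representation(probs = "matrix", meld = "numeric", waitDays = "numeric"),
  validity = function(object) {
    p <- object@probs
    if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
      return("probs must be a numeric matrix with entries in [0, 1]")
    if (length(object@meld) != nrow(p))
      return("one MELD score per recipient row is required")
    if (any(object@meld < 6 | object@meld > 75))
      return("MELD scores must lie in [6, 75]")
    if (length(object@waitDays) != nrow(p) || any(object@waitDays < 0))
      return("one non-negative waiting-day count per recipient is required")
    TRUE
  }
)

#' AllocationConfig: parameters of the rule-based allocator
#'
#' @slot tau significance threshold on probability differences: recipients
#'   within `tau` of the column maximum are clinically indistinguishable and
#'   fall through to the MELD rule. Default 0.14, the published threshold
#'   (one standard deviation of the model's predicted probabilities).
#' @slot sequential if `TRUE`, a matched recipient is removed before the next
#'   donor column is allocated; off by default (the published simulations
#'   allocate every donor against the full recipient list).
#' @slot populationSD use the population (divide-by-n) convention in
#'   [sigmaThreshold()].
#' @seealso [allocationConfig()], [allocate()], [allocateMatrix()]
#' @export
setClass("AllocationConfig",
  representation(tau = "numeric", sequential = "logical",
                 populationSD = "logical"),
  validity = function(object) {
    if (length(object@tau) != 1L || object@tau < 0 || object@tau > 1)
      return("tau must be a single value in [0, 1]")
    TRUE
  }
)

#' AllocationResult: per-donor allocation decisions
#'
#' @slot chosen integer vector, 1-based index of the recipient allocated to
#'   each donor, named by donor id.
#' @slot candidates list of integer vectors: the candidate set (recipients
#'   within `tau` of the column maximum) per donor.
#' @slot stage character per donor: `"probability-dominance"` when the model
#'   alone decided, `"MELD"`, `"waiting-time"`, or `"index-fallback"` when an
#'   exact tie survived every rule and the lowest index was taken.
#' @slot recipientIds,donorIds row and column identifiers.
#' @seealso [allocateMatrix()], [chosenRecipients()], [decisionStages()]
#' @export
setClass("AllocationResult",
  representation(chosen = "integer", candidates = "list", stage = "character",
                 recipientIds = "character", donorIds = "character"),
  validity = function(object) {
    k <- length(object@chosen)
    if (length(object@candidates) != k || length(object@stage) != k)
      return("chosen, candidates and stage must have one entry per donor")
    for (j in seq_len(k)) {
      if (length(object@candidates[[j]]) == 0L)
        return("candidate sets must be non-empty")
      if (!object@chosen[j] %in% object@candidates[[j]])
        return("each chosen recipient must belong to its candidate set")
    }
    TRUE
  }
)

.classifierMethods <- c("LR", "MLP", "RF", "SVM", "C4.5", "NB", "kNN", "GB")
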
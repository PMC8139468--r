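## Synthetic D-R cohort generator.
##
## The generator emulates the registry schema (admissible ranges and category
## codes), its per-end-point class prevalences, and a logistic ground-truth
## labelling mechanism, so that encoding, imputation, the benchmark and the
## allocator are all testable without the access-restricted registry extract.
## Default marginals are uniform over each admissible range (ranges are the
## only published distributional facts); each field is drawn independently.

#' Configure a synthetic cohort
#'
#' @param n number of D-R pairs.
#' @param seed integer master seed; internally split into independent
#'   substreams for values, missingness, labels and outcome times, so that
#'   e.g. changing the missing rate never perturbs the generated values.
#' @param missingRate shared or per-field (named) missingness probability in
#'   \[0, 0.10\].
#' @param marginals named list of per-field overrides, each a `function(n)`
#'   returning draws; defaults are uniform over the admissible range
#'   (numeric), uniform over category codes (nominal) and Bernoulli(1/2)
#'   (binary).
#' @param prevalence named target graft-survival share per end-point;
#'   defaults to the registry shares of [endpointClassTable()].
#' @return a [CohortConfig-class] object.
#' @examples
#' cohortConfig(n = 100, seed = 7)
#' @export
cohortConfig <- function(n, seed = 1L, missingRate = 0.02,
                         marginals = list(), prevalence = NULL) {
  if (is.null(prevalence)) {
    tab <- endpointClassTable()
    prevalence <- stats::setNames(tab$survivalShare, tab$endpoint)
  }
  new("CohortConfig", n = as.integer(n), seed = as.integer(seed),
      missingRate = missingRate, marginals = marginals,
      prevalence = prevalence)
}

## Independent substream seeds derived from the master seed.
.substreams <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(2147483646L, 4L),
                  c("values", "missing", "labels", "outcomes"))
}

.missingRateFor <- function(config, fname) {
  mr <- config@missingRate
  if (!is.null(names(mr))) {
    if (fname %in% names(mr)) unname(mr[[fname]]) else 0
  } else mr[1]
}

## Draw complete field values (no missingness applied).
.generateValues <- function(config) {
  sch <- loadSchema()
  seeds <- .substreams(config@seed)
  set.seed(seeds[["values"]])
  n <- config@n
  out <- list()
  for (fname in names(sch)) {
    f <- sch[[fname]]
    v <- if (!is.null(config@marginals[[fname]])) {
      as.numeric(config@marginals[[fname]](n))
    } else if (f$type == "numeric") {
      stats::runif(n, f$range[1], f$range[2])
    } else if (f$type == "binary") {
      as.numeric(stats::rbinom(n, 1L, 0.5))
    } else {
      as.numeric(sample(f$levels, n, replace = TRUE))
    }
    out[[fname]] <- v
  }
  df <- as.data.frame(out, check.names = FALSE, optional = TRUE)
  names(df) <- names(sch)
  validatePairs(df, allowMissing = FALSE)
  df
}

.applyMissingness <- function(pairs, config) {
  seeds <- .substreams(config@seed)
  set.seed(seeds[["missing"]])
  for (fname in schemaFields()) {
    rate <- .missingRateFor(config, fname)
    mask <- stats::runif(config@n) < rate
    if (any(mask)) pairs[[fname]][mask] <- NA_real_
  }
  pairs
}

#' Generate synthetic D-R pairs
#'
#' Draws a schema-valid cohort: every generated value respects the admissible
#' range or category codes, identical seeds give identical cohorts, and a
#' missing rate of zero yields a complete cohort.
#'
#' @param config a [CohortConfig-class].
#' @return data frame with the 28 schema columns, `NA` marking missing.
#' @examples
#' pairs <- syntheticPairs(cohortConfig(n = 50, seed = 7))
#' range(pairs[["A-R"]], na.rm = TRUE)   # inside [18, 83]
#' @export
syntheticPairs <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  .applyMissingness(.generateValues(config), config)
}

#' Linear predictor and ground-truth survival probabilities
#'
#' Computes the ground-truth graft-survival probability of each pair under a
#' logistic model. Features are z-scored against the cohort's own statistics
#' before the weights are applied, so that coefficient magnitudes are
#' comparable across variables of very different raw scales (waiting days up
#' to 3516 vs binary flags).
#'
#' @param pairs complete cohort data frame.
#' @param model a [LogisticModel-class]; defaults to the published model.
#' @param intercept overriding independent term (e.g. a calibrated one).
#' @return numeric vector of probabilities.
#' @export
groundTruthProbabilities <- function(pairs, model = loadPublishedModel(),
                                     intercept = model@intercept) {
  eta <- .groundTruthEta(pairs, model)
  stats::plogis(intercept + eta)
}

.groundTruthEta <- function(pairs, model) {
  x <- encodeCohort(pairs, fitScaling(pairs))
  drop(x[, names(model@weights), drop = FALSE] %*% model@weights)
}

#' Calibrate the ground-truth intercept to a target prevalence
#'
#' Solves for the independent term at which the cohort-mean predicted
#' survival probability equals the target share (the mean sigmoid is strictly
#' increasing in the intercept, so a monotone one-dimensional root search
#' suffices).
#'
#' @inheritParams groundTruthProbabilities
#' @param target survival share in (0, 1), e.g. `survivalPrevalence("5Y")`.
#' @param tol acceptable |mean probability - target| (default 0.005).
#' @param maxIter iteration cap for the root search.
#' @return the calibrated intercept (numeric scalar).
#' @examples
#' pairs <- syntheticPairs(cohortConfig(n = 500, seed = 3, missingRate = 0))
#' b <- calibrateIntercept(pairs, target = 0.9)
#' mean(groundTruthProbabilities(pairs, intercept = b))   # ~0.9
#' @export
calibrateIntercept <- function(pairs, model = loadPublishedModel(),
                               target, tol = 0.005, maxIter = 200L) {
  stopifnot(target > 0, target < 1)
  eta <- .groundTruthEta(pairs, model)
  f <- function(b) mean(stats::plogis(b + eta)) - target
  sol <- stats::uniroot(f, interval = c(-50, 50), tol = 1e-10,
                        maxiter = maxIter)
  if (abs(f(sol$root)) > tol)
    stop("intercept calibration did not converge to within ", tol,
         call. = FALSE)
  sol$root
}

#' Draw Bernoulli survival labels from ground-truth probabilities
#'
#' @param probs per-pair survival probabilities.
#' @param seed integer seed for the label draws.
#' @return integer vector, 1 = graft survival (positive class), 0 otherwise.
#' @export
generateLabels <- function(probs, seed) {
  stopifnot(all(probs >= 0 & probs <= 1))
  set.seed(seed)
  stats::rbinom(length(probs), 1L, probs)
}

## Outcome times consistent with the per-end-point binary labels: failures
## occur uniformly inside the horizon; survivors are followed past it.
.generateOutcomes <- function(labels, ep, seed) {
  set.seed(seed)
  n <- length(labels)
  failure <- rep(NA_real_, n)
  idx <- labels == 0L
  failure[idx] <- ceiling(stats::runif(sum(idx), 0, ep@horizon))
  followup <- ifelse(idx, failure,
                     ep@horizon + floor(stats::runif(n, 0, 365)))
  data.frame(failure_day = failure, followup_day = followup,
             unrelated_death = rep(0, n))
}

#' Generate a complete labelled synthetic cohort
#'
#' End-to-end generator: draws schema-valid pairs, calibrates the ground-truth
#' intercept to the end-point's survival share, draws Bernoulli labels and
#' matching outcome times, then masks values as missing. Ground truth is
#' computed from the complete values; missingness acts as measurement dropout
#' afterwards.
#'
#' @param config a [CohortConfig-class].
#' @param endpoint end-point label (`"3M"`, `"1Y"`, `"2Y"`, `"5Y"`).
#' @param model ground-truth [LogisticModel-class]; defaults to the published
#'   weights.
#' @return a list of class `syntheticCohort`: `pairs` (with missingness),
#'   `complete` (pre-missingness values), `labels` (1 = survival), `probs`,
#'   `outcomes` (failure/follow-up days), `intercept`, `endpoint`, `config`.
#' @examples
#' co <- generateCohort(cohortConfig(n = 200, seed = 11), endpoint = "5Y")
#' mean(co$probs)    # close to the 5Y survival share
#' @export
generateCohort <- function(config, endpoint = "5Y",
                           model = loadPublishedModel()) {
  stopifnot(is(config, "CohortConfig"))
  ep <- endPoint(endpoint)
  seeds <- .substreams(config@seed)
  complete <- .generateValues(config)
  b <- calibrateIntercept(complete, model,
                          target = config@prevalence[[endpoint]])
  probs <- groundTruthProbabilities(complete, model, intercept = b)
  labels <- generateLabels(probs, seeds[["labels"]])
  outcomes <- .generateOutcomes(labels, ep, seeds[["outcomes"]])
  pairs <- .applyMissingness(complete, config)
  structure(list(pairs = pairs, complete = complete, labels = labels,
                 probs = probs, outcomes = outcomes, intercept = b,
                 endpoint = endpoint, config = config),
            class = "syntheticCohort")
}

#' Write / read the cohort CSV dialect
#'
#' One row per D-R pair; header names are the short schema codes plus the
#' outcome columns `failure_day`, `followup_day`, `unrelated_death`; an empty
#' cell is a missing value. Numerics are written with full precision so a
#' written cohort re-reads identically. A sidecar `<path>.provenance.json`
#' records the seed and configuration hash.
#'
#' @param pairs cohort data frame.
#' @param path output CSV path.
#' @param outcomes optional outcome data frame (same row count).
#' @param provenance named list echoed into the sidecar (e.g. seed).
#' @return `path`, invisibly.
#' @export
writeCohortCSV <- function(pairs, path, outcomes = NULL, provenance = list()) {
  df <- pairs
  if (!is.null(outcomes)) {
    stopifnot(nrow(outcomes) == nrow(pairs))
    df <- cbind(df, outcomes)
  }
  fmt <- vapply(df, function(col) {
    ifelse(is.na(col), "", sprintf("%.17g", col))
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1, dimnames = list(NULL, names(df)))
  utils::write.table(fmt, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  meta <- c(list(written = format(Sys.time(), tz = "UTC"),
                 rows = nrow(df), configHash = configHash(provenance)),
            provenance)
  jsonlite::write_json(meta, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCohortCSV
#' @return `readCohortCSV()`: the cohort data frame (all columns numeric,
#'   empty cells as `NA`), schema-validated.
#' @export
readCohortCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("", "NA"),
                        colClasses = "numeric")
  validatePairs(df)
  df
}

#' Deterministic hash of a configuration object
#'
#' md5 of the canonical JSON serialisation; embedded in artifact provenance so
#' runs can be traced to the exact configuration that produced them.
#'
#' @param x any jsonlite-serialisable object.
#' @return hex string.
#' @export
configHash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' @describeIn CohortConfig-class compact display.
#' @param object a `CohortConfig`.
#' @export
setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig: n =", object@n, ", seed =", object@seed,
      ", missing rate =", paste(signif(object@missingRate, 3), collapse = "/"),
      "\n  target survival share:",
      paste(names(object@prevalence), signif(object@prevalence, 4),
            sep = "=", collapse = ", "), "\n")
})
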
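## Nested 10-fold cross-validation benchmark.
##
## Outer folds estimate generalisation; an independent inner cross-validation
## over each outer training set selects the hyperparameter configuration with
## the maximum mean Minimum Sensitivity. Outer test folds are never used for
## selection, and imputation/scaling statistics are re-fitted inside every
## training split so no held-out value leaks into preprocessing.

#' Construct a cross-validation plan
#'
#' @param spec the [ClassifierSpec-class] to benchmark.
#' @param outerFolds,innerFolds fold counts (default 10/10).
#' @param metric inner selection metric (default `"MS"`).
#' @param seed integer seed for fold assignment and learner seeds.
#' @param stratified stratify folds by class (default `TRUE`; at the
#'   strongly imbalanced 3-month end-point unstratified folds can lose the
#'   minority class entirely, leaving MS undefined).
#' @param threshold probability cut-off for confusion matrices (default 0.5).
#' @return a [CVPlan-class].
#' @export
cvPlan <- function(spec, outerFolds = 10L, innerFolds = 10L, metric = "MS",
                   seed = 1L, stratified = TRUE, threshold = 0.5) {
  new("CVPlan", outerFolds = as.integer(outerFolds),
      innerFolds = as.integer(innerFolds), metric = metric,
      seed = as.integer(seed), spec = spec, stratified = stratified,
      threshold = threshold)
}

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds. With stratification, each
#' class is shuffled and dealt round-robin so per-fold class prevalence
#' matches the cohort's within rounding. Errors if any fold ends up with a
#' single class.
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @param stratified deal classes separately (default `TRUE`).
#' @return integer vector of fold ids in `1:k`.
#' @export
stratifiedFolds <- function(y, k, seed = 1L, stratified = TRUE) {
  n <- length(y)
  if (k < 2L || k > n) stop("fold count must lie in [2, n]", call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  for (j in seq_len(k))
    if (length(unique(y[fold == j])) < 2L)
      stop("fold ", j, " contains a single class; use stratified folds or ",
           "fewer folds", call. = FALSE)
  fold
}

## Impute, scale and encode a train/test split; statistics from train only.
.prepareSplit <- function(pairs, trainIdx, testIdx) {
  imp <- fitImputer(pairs[trainIdx, , drop = FALSE])
  tr <- applyImputer(pairs[trainIdx, , drop = FALSE], imp)
  te <- applyImputer(pairs[testIdx, , drop = FALSE], imp)
  sc <- fitScaling(tr)
  list(xtr = encodeCohort(tr, sc), xte = encodeCohort(te, sc))
}

## Inner model selection: mean inner MS, ties by mean inner AUC, then first
## in grid order.
.selectConfig <- function(pairs, y, plan, seed) {
  grid <- enumerateGrid(plan@spec)
  if (nrow(grid) == 1L)
    return(list(params = as.list(grid[1, , drop = FALSE]), index = 1L,
                meanMS = NA_real_))
  fold <- stratifiedFolds(y, plan@innerFolds, seed = seed,
                          stratified = plan@stratified)
  ms <- matrix(NA_real_, nrow(grid), plan@innerFolds)
  auc <- matrix(NA_real_, nrow(grid), plan@innerFolds)
  for (j in seq_len(plan@innerFolds)) {
    trainIdx <- which(fold != j)
    valIdx <- which(fold == j)
    enc <- .prepareSplit(pairs, trainIdx, valIdx)
    for (g in seq_len(nrow(grid))) {
      fit <- trainWithSpec(plan@spec, enc$xtr, y[trainIdx],
                           params = as.list(grid[g, , drop = FALSE]),
                           seed = seed + g)
      scores <- predictProb(fit, enc$xte)
      ms[g, j] <- minimumSensitivity(
        confusionFromScores(y[valIdx], scores, plan@threshold))
      auc[g, j] <- aucScore(scores, y[valIdx])
    }
  }
  meanMS <- rowMeans(ms)
  meanAUC <- rowMeans(auc)
  best <- which(meanMS == max(meanMS))
  if (length(best) > 1L) best <- best[meanAUC[best] == max(meanAUC[best])]
  best <- best[1L]
  list(params = as.list(grid[best, , drop = FALSE]), index = best,
       meanMS = meanMS[best])
}

#' Run the nested cross-validation benchmark
#'
#' For each outer fold: fit imputation and scaling statistics on the outer
#' training set only, select hyperparameters by inner cross-validation
#' (maximum mean Minimum Sensitivity; ties broken by mean inner AUC, then
#' grid order), refit on the full outer training set, and evaluate on the
#' held-out fold. The pooled confusion matrix is the sum of the outer test
#' confusion matrices; Acc/MS/AUC are summarised as mean and SD over folds.
#'
#' @param pairs cohort data frame (missing values allowed; imputed per fold).
#' @param labels binary labels, 1 = graft survival.
#' @param plan a [CVPlan-class].
#' @return a list of class `nestedCV`: `perFold` ([EvalResult-class] list),
#'   `pooled` (summed [ConfusionMatrix-class]), `summary` (mean/SD data
#'   frame), `selected` (chosen hyperparameters per fold), `foldAssign`
#'   (outer fold id per observation), `plan`.
#' @examples
#' \donttest{
#' co <- generateCohort(cohortConfig(n = 300, seed = 5, missingRate = 0))
#' plan <- cvPlan(classifierSpec("LR", grid = list(C = c(0.1, 1))),
#'                outerFolds = 3, innerFolds = 3)
#' res <- runNestedCV(co$pairs, co$labels, plan)
#' res$summary
#' }
#' @export
runNestedCV <- function(pairs, labels, plan) {
  stopifnot(is(plan, "CVPlan"), nrow(pairs) == length(labels))
  labels <- as.integer(labels)
  outer <- stratifiedFolds(labels, plan@outerFolds, seed = plan@seed,
                           stratified = plan@stratified)
  perFold <- vector("list", plan@outerFolds)
  selected <- vector("list", plan@outerFolds)
  for (j in seq_len(plan@outerFolds)) {
    t0 <- proc.time()[["elapsed"]]
    trainIdx <- which(outer != j)
    testIdx <- which(outer == j)
    sel <- .selectConfig(pairs[trainIdx, , drop = FALSE], labels[trainIdx],
                         plan, seed = plan@seed + 1000L + j)
    enc <- .prepareSplit(pairs, trainIdx, testIdx)
    fit <- trainWithSpec(plan@spec, enc$xtr, labels[trainIdx],
                         params = sel$params, seed = plan@seed + j)
    scores <- predictProb(fit, enc$xte)
    perFold[[j]] <- evaluateScores(labels[testIdx], scores, plan@threshold,
                                   wallTime = proc.time()[["elapsed"]] - t0)
    selected[[j]] <- sel$params
  }
  pooled <- poolConfusion(lapply(perFold, function(r) r@cm))
  met <- function(f) vapply(perFold, f, numeric(1))
  summary <- data.frame(
    metric = c("Acc", "MS", "AUC"),
    mean = c(mean(met(accuracy)), mean(met(minimumSensitivity)),
             mean(met(function(r) r@auc))),
    sd = c(stats::sd(met(accuracy)), stats::sd(met(minimumSensitivity)),
           stats::sd(met(function(r) r@auc)))
  )
  structure(list(perFold = perFold, pooled = pooled, summary = summary,
                 selected = selected, foldAssign = outer, plan = plan),
            class = "nestedCV")
}

#' @export
print.nestedCV <- function(x, ...) {
  cat("Nested", x$plan@outerFolds, "x", x$plan@innerFolds,
      "cross-validation of", x$plan@spec@method, "\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  cat("  pooled n =", length(x$pooled), "\n")
  invisible(x)
}

#' Rank methods by each metric
#'
#' Orders a set of benchmark summaries per metric, marking the best and
#' second-best method (the bold/italics convention of the benchmark report).
#' Exact ties are broken alphabetically by method name and flagged.
#'
#' @param results named list: per method either a `nestedCV` result or a
#'   numeric vector with entries `Acc`, `MS`, `AUC`.
#' @return data frame with one row per method, metric columns, and
#'   `rank_Acc`/`rank_MS`/`rank_AUC` marker columns (`"best"`, `"second"`,
#'   `""`); attribute `ties` lists tied metrics.
#' @export
rankSummary <- function(results) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  vals <- t(vapply(results, function(r) {
    if (inherits(r, "nestedCV"))
      stats::setNames(r$summary$mean, r$summary$metric)[c("Acc", "MS", "AUC")]
    else r[c("Acc", "MS", "AUC")]
  }, numeric(3)))
  out <- data.frame(method = names(results), vals, row.names = NULL,
                    check.names = FALSE)
  out <- out[order(out$method), , drop = FALSE]
  ties <- character(0)
  for (m in c("Acc", "MS", "AUC")) {
    ord <- order(-out[[m]], out$method)   # alphabetical tie-break
    marker <- character(nrow(out))
    marker[ord[1]] <- "best"
    if (nrow(out) >= 2) marker[ord[2]] <- "second"
    if (anyDuplicated(out[[m]])) ties <- c(ties, m)
    out[[paste0("rank_", m)]] <- marker
  }
  attr(out, "ties") <- ties
  out
}

#' @describeIn CVPlan-class plan display.
#' @param object a `CVPlan`.
#' @export
setMethod("show", "CVPlan", function(object) {
  cat("CVPlan:", object@outerFolds, "outer x", object@innerFolds,
      "inner folds, selection by", object@metric, "| method",
      object@spec@method, "| seed", object@seed, "\n")
})
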
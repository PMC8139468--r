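## Generic classifier harness.
##
## The benchmark's contribution is the protocol (nested selection by Minimum
## Sensitivity) and the interpretation of the logistic model; the individual
## learners are delegations to standard libraries behind a single contract:
## a fitted object exposing predictProb() on encoded matrices, seeded.

#' Default hyperparameter grid of a method
#'
#' @param method method name; see [ClassifierSpec-class].
#' @return named list of candidate values (empty for NB).
#' @export
defaultGrid <- function(method) {
  if (is.null(.lmCache$grids)) {
    raw <- jsonlite::read_json(fixturePath("selection_grids.json"))
    raw$comment <- NULL
    .lmCache$grids <- lapply(raw, function(g) lapply(g, unlist))
  }
  if (!method %in% names(.lmCache$grids))
    stop("unknown method '", method, "'; valid methods: ",
         paste(.classifierMethods, collapse = ", "), call. = FALSE)
  .lmCache$grids[[method]]
}

#' Construct a classifier specification
#'
#' @param method method name (`"LR"`, `"NB"`, `"kNN"`, ...).
#' @param grid hyperparameter grid; defaults to the packaged grid for the
#'   method.
#' @return a [ClassifierSpec-class].
#' @examples
#' classifierSpec("kNN")      # k in {2, 3, 4, 5}
#' @export
classifierSpec <- function(method, grid = defaultGrid(method)) {
  new("ClassifierSpec", method = method, grid = grid)
}

#' Enumerate all hyperparameter configurations of a grid
#'
#' Full Cartesian product of the grid, in row-major order with the first grid
#' dimension varying fastest; the inner selection scans configurations in
#' this order, so "first in grid" ties are deterministic.
#'
#' @param spec a [ClassifierSpec-class].
#' @return data frame, one row per configuration (a single all-default row
#'   for parameter-free methods).
#' @examples
#' nrow(enumerateGrid(classifierSpec("RF")))   # 3*2*5*8 = 240
#' @export
enumerateGrid <- function(spec) {
  stopifnot(is(spec, "ClassifierSpec"))
  if (length(spec@grid) == 0)
    return(data.frame(row.names = 1))
  expand.grid(spec@grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

#' Train a classifier under the harness contract
#'
#' Fits the method named by `spec` with one hyperparameter configuration and
#' returns an object usable with [predictProb()]. Hyperparameters outside the
#' spec's grid trigger a warning, not an error, so exploratory values remain
#' usable. Backends: glmnet (LR), `e1071` (NB, SVM), `randomForest` (RF;
#' split criterion is always Gini, an `"entropy"` request is honoured with a
#' warning), `rpart` (C4.5-style trees), `class` (kNN), `nnet` (MLP),
#' `xgboost` (GB).
#'
#' @param spec a [ClassifierSpec-class].
#' @param x encoded training matrix.
#' @param y binary labels, 1 = graft survival.
#' @param params named list (or one-row data frame) of hyperparameters drawn
#'   from the spec's grid.
#' @param seed integer seed applied before fitting.
#' @return an object of class `lmClassifier`.
#' @examples
#' co <- generateCohort(cohortConfig(n = 200, seed = 2, missingRate = 0))
#' x <- encodeCohort(co$complete, fitScaling(co$complete))
#' fit <- trainWithSpec(classifierSpec("LR"), x, co$labels, list(C = 1))
#' head(predictProb(fit, x))
#' @export
trainWithSpec <- function(spec, x, y, params = list(), seed = 1L) {
  stopifnot(is(spec, "ClassifierSpec"))
  if (is.data.frame(params)) params <- as.list(params)
  for (p in names(params)) {
    if (!p %in% names(spec@grid)) {
      warning("hyperparameter '", p, "' is not in the ", spec@method,
              " grid", call. = FALSE)
    } else if (!params[[p]] %in% spec@grid[[p]]) {
      warning(spec@method, " hyperparameter ", p, " = ", params[[p]],
              " lies outside the packaged grid", call. = FALSE)
    }
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("training data contain a single class; cannot fit", call. = FALSE)
  set.seed(seed)
  fit <- switch(spec@method,
    LR = fitL1Logistic(x, y, C = params$C %||% 1),
    NB = .needs("e1071", e1071::naiveBayes(
      as.data.frame(x, check.names = TRUE), factor(y, levels = 0:1))),
    kNN = list(x = x, y = factor(y, levels = 0:1), k = params$k %||% 3),
    RF = {
      if (identical(params$criterion, "entropy"))
        warning("randomForest splits on Gini impurity; 'entropy' request ",
                "is fitted with Gini", call. = FALSE)
      .needs("randomForest", randomForest::randomForest(
        x, factor(y, levels = 0:1),
        ntree = params$n_trees %||% 100,
        nodesize = params$min_samples %||% 2,
        maxnodes = 2^(params$max_depth %||% 6)))
    },
    SVM = .needs("e1071", e1071::svm(
      x, factor(y, levels = 0:1), kernel = "radial",
      cost = params$C %||% 1, gamma = params$gamma %||% (1 / ncol(x)),
      probability = TRUE)),
    `C4.5` = {
      df <- as.data.frame(x, check.names = TRUE)
      df$.y <- factor(y, levels = 0:1)
      .needs("rpart", rpart::rpart(
        .y ~ ., df, method = "class",
        control = rpart::rpart.control(
          maxdepth = min(params$max_depth %||% 5, 30),
          minsplit = params$min_samples %||% 20, cp = 0)))
    },
    MLP = .needs("nnet", nnet::nnet(
      x, y, size = params$n_neurons %||% 10,
      decay = params$alpha %||% 1e-4,
      maxit = params$max_iter %||% 500,
      entropy = TRUE, trace = FALSE, MaxNWts = 1e5)),
    GB = {
      .needs("xgboost", xgboost::xgboost(
        data = x, label = y, nrounds = params$n_trees %||% 100,
        eta = params$learning_rate %||% 0.1,
        max_depth = params$max_depth %||% 3,
        min_child_weight = params$min_samples %||% 2,
        objective = "binary:logistic", verbose = 0, nthread = 1))
    },
    stop("method '", spec@method, "' has no training backend")
  )
  structure(list(method = spec@method, fit = fit, params = params,
                 seed = seed),
            class = "lmClassifier")
}

.needs <- function(pkg, expr) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("package '", pkg, "' is required for this classifier backend",
         call. = FALSE)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict survival probabilities from a harness fit
#'
#' @param fit an `lmClassifier` from [trainWithSpec()].
#' @param x encoded matrix to score.
#' @return numeric vector: probability of the positive (graft-survival)
#'   class.
#' @export
predictProb <- function(fit, x) {
  stopifnot(inherits(fit, "lmClassifier"))
  switch(fit$method,
    LR = predictProbability(fit$fit, x),
    NB = {
      p <- stats::predict(fit$fit, as.data.frame(x, check.names = TRUE),
                          type = "raw")
      as.numeric(p[, "1"])
    },
    kNN = {
      set.seed(fit$seed)   # knn breaks vote ties at random
      pred <- class::knn(fit$fit$x, x, fit$fit$y, k = fit$fit$k,
                         prob = TRUE)
      pw <- attr(pred, "prob")
      ifelse(pred == "1", pw, 1 - pw)
    },
    RF = as.numeric(stats::predict(fit$fit, x, type = "prob")[, "1"]),
    SVM = {
      p <- attr(stats::predict(fit$fit, x, probability = TRUE),
                "probabilities")
      as.numeric(p[, "1"])
    },
    `C4.5` = as.numeric(stats::predict(
      fit$fit, as.data.frame(x, check.names = TRUE))[, "1"]),
    MLP = as.numeric(stats::predict(fit$fit, x)),
    GB = as.numeric(stats::predict(fit$fit, x)),
    stop("method '", fit$method, "' has no prediction backend")
  )
}

#' @describeIn ClassifierSpec-class method and grid size.
#' @param object a `ClassifierSpec`.
#' @export
setMethod("show", "ClassifierSpec", function(object) {
  k <- nrow(enumerateGrid(object))
  cat("ClassifierSpec ", object@method, ": ", k, " configuration",
      if (k != 1) "s", " (", paste(names(object@grid), collapse = ", "),
      ")\n", sep = "")
})
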
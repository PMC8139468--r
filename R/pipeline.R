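## End-to-end pipeline entry points and fixture reproduction.

#' Reproduce the published allocation simulations
#'
#' Runs the rule-based allocator on the three packaged simulation scenarios
#' and compares every donor column against the published allocation row.
#'
#' @param tau significance threshold (default 0.14).
#' @param config an [AllocationConfig-class]; overrides `tau` when given.
#' @return data frame of class `tableReport` with columns `table`, `donor`,
#'   `expected`, `chosen`, `stage`, `match`; attribute `ok` is `TRUE` when
#'   all 30 columns match.
#' @examples
#' rep <- reproduceTables()
#' attr(rep, "ok")          # TRUE: 30/30 columns
#' @export
reproduceTables <- function(tau = 0.14, config = allocationConfig(tau = tau)) {
  expected <- printedAllocations()
  rows <- list()
  for (tab in names(expected)) {
    sc <- fixtureScenario(tab)
    res <- allocateMatrix(sc, config)
    rows[[tab]] <- data.frame(
      table = tab, donor = res@donorIds,
      expected = expected[[tab]], chosen = unname(res@chosen),
      stage = unname(res@stage),
      match = unname(res@chosen) == expected[[tab]])
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "ok") <- all(out$match)
  class(out) <- c("tableReport", class(out))
  out
}

#' @export
print.tableReport <- function(x, ...) {
  cat(sprintf("Allocation reproduction: %d/%d donor columns match\n",
              sum(x$match), nrow(x)))
  bad <- x[!x$match, , drop = FALSE]
  if (nrow(bad) > 0) {
    cat("mismatches:\n")
    print.data.frame(bad, row.names = FALSE)
  }
  invisible(x)
}

#' Grid search for the significance threshold
#'
#' Scans candidate thresholds and counts, for each, how many of the 30
#' published donor columns the allocator reproduces. Exactly one grid value
#' reproduces all of them.
#'
#' @param taus candidate thresholds (default the 0.01 grid over
#'   \[0.10, 0.20\]).
#' @return data frame with columns `tau`, `matched` (of 30), `all`.
#' @examples
#' gs <- thresholdGridSearch()
#' gs$tau[gs$all]            # 0.14
#' @export
thresholdGridSearch <- function(taus = seq(0.10, 0.20, by = 0.01)) {
  res <- lapply(taus, function(tau) {
    rep <- reproduceTables(tau = tau)
    data.frame(tau = tau, matched = sum(rep$match), all = all(rep$match))
  })
  do.call(rbind, res)
}

#' Run one pipeline stage and write its artifacts
#'
#' Thin driver binding the stages into file-based runs. Every artifact is
#' accompanied by provenance (seed and configuration hash) so identical
#' seeds give identical result files.
#'
#' Commands:
#' * `generate`: synthetic labelled cohort -> `cohort.csv` (+ labels column).
#' * `benchmark`: nested cross-validation of one or more methods on a cohort
#'   -> per-fold CSV, summary JSON and selected-hyperparameter log.
#' * `predict`: published-model probabilities for a cohort -> `probs.csv`.
#' * `allocate`: rule-based allocation of a scenario CSV -> JSON decisions.
#' * `reproduce-tables`: fixture reproduction report -> JSON; an error is
#'   raised on any mismatch.
#'
#' @param command one of `generate`, `benchmark`, `predict`, `allocate`,
#'   `reproduce-tables`.
#' @param out output directory (created if needed).
#' @param seed integer seed.
#' @param n cohort size (`generate`).
#' @param endpoint end-point label.
#' @param cohort path to a cohort CSV (`benchmark`, `predict`); defaults to
#'   the file written by `generate` in `out`.
#' @param methods character vector of methods to benchmark.
#' @param scenario scenario CSV path or fixture name (`allocate`).
#' @param tau significance threshold (`allocate`, `reproduce-tables`).
#' @param outerFolds,innerFolds fold counts for `benchmark`.
#' @return named list of written artifact paths, invisibly.
#' @export
runPipeline <- function(command = c("generate", "benchmark", "predict",
                                    "allocate", "reproduce-tables"),
                        out = ".", seed = 1L, n = 1000L, endpoint = "5Y",
                        cohort = NULL, methods = "LR", scenario = "mediumMELD",
                        tau = 0.14, outerFolds = 10L, innerFolds = 10L) {
  command <- match.arg(command)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  prov <- list(seed = seed, command = command, endpoint = endpoint,
               package = as.character(utils::packageVersion("liverMatch")))
  artifacts <- list()
  if (command == "generate") {
    co <- generateCohort(cohortConfig(n = n, seed = seed), endpoint = endpoint)
    path <- file.path(out, "cohort.csv")
    writeCohortCSV(co$pairs, path, outcomes = co$outcomes,
                   provenance = c(prov, list(n = n,
                                             intercept = co$intercept)))
    labPath <- file.path(out, "labels.csv")
    utils::write.csv(data.frame(label = co$labels), labPath,
                     row.names = FALSE)
    artifacts <- list(cohort = path, labels = labPath)
  } else if (command == "benchmark") {
    bad <- setdiff(methods, .classifierMethods)
    if (length(bad) > 0)
      stop("unknown method(s) ", paste(bad, collapse = ", "),
           "; valid methods: ", paste(.classifierMethods, collapse = ", "),
           call. = FALSE)
    dat <- .loadCohortForRun(cohort, out, endpoint, seed, n)
    results <- list()
    for (m in methods) {
      plan <- cvPlan(classifierSpec(m), outerFolds = outerFolds,
                     innerFolds = innerFolds, seed = seed)
      results[[m]] <- runNestedCV(dat$pairs, dat$labels, plan)
    }
    perFold <- do.call(rbind, lapply(names(results), function(m) {
      r <- results[[m]]
      data.frame(method = m, fold = seq_along(r$perFold),
                 acc = vapply(r$perFold, accuracy, numeric(1)),
                 ms = vapply(r$perFold, minimumSensitivity, numeric(1)),
                 auc = vapply(r$perFold, function(e) e@auc, numeric(1)))
    }))
    foldPath <- file.path(out, "benchmark_folds.csv")
    utils::write.csv(perFold, foldPath, row.names = FALSE)
    sumPath <- file.path(out, "benchmark_summary.json")
    jsonlite::write_json(
      c(list(provenance = c(prov, list(configHash = configHash(prov)))),
        lapply(results, function(r) {
          list(summary = r$summary,
               pooled = c(tp = r$pooled@tp, fn = r$pooled@fn,
                          fp = r$pooled@fp, tn = r$pooled@tn),
               selected = r$selected)
        })),
      sumPath, auto_unbox = TRUE, digits = NA)
    artifacts <- list(folds = foldPath, summary = sumPath)
  } else if (command == "predict") {
    dat <- .loadCohortForRun(cohort, out, endpoint, seed, n)
    imp <- fitImputer(dat$pairs)
    complete <- applyImputer(dat$pairs, imp)
    probs <- predictProbability(loadPublishedModel(), complete)
    path <- file.path(out, "probs.csv")
    utils::write.csv(data.frame(pair = seq_along(probs), prob = probs),
                     path, row.names = FALSE)
    artifacts <- list(probs = path)
  } else if (command == "allocate") {
    sc <- if (scenario %in% c("mediumMELD", "highMELD", "ecd"))
      fixtureScenario(scenario) else readScenario(scenario)
    res <- allocateMatrix(sc, allocationConfig(tau = tau))
    path <- file.path(out, "allocation.json")
    jsonlite::write_json(
      list(provenance = c(prov, list(tau = tau,
                                     configHash = configHash(prov))),
           donors = res@donorIds,
           chosen = unname(res@chosen),
           chosenId = res@recipientIds[res@chosen],
           stage = unname(res@stage),
           candidates = unname(res@candidates)),
      path, auto_unbox = TRUE, digits = NA)
    artifacts <- list(allocation = path)
  } else {   # reproduce-tables
    rep <- reproduceTables(tau = tau)
    path <- file.path(out, "reproduction.json")
    jsonlite::write_json(
      list(provenance = c(prov, list(tau = tau,
                                     configHash = configHash(prov))),
           matched = sum(rep$match), total = nrow(rep),
           mismatches = rep[!rep$match, c("table", "donor", "expected",
                                          "chosen")]),
      path, auto_unbox = TRUE, digits = NA)
    artifacts <- list(reproduction = path)
    if (!attr(rep, "ok"))
      stop("allocation reproduction failed for ", sum(!rep$match),
           " donor column(s); see ", path, call. = FALSE)
  }
  invisible(artifacts)
}

.loadCohortForRun <- function(cohort, out, endpoint, seed, n) {
  if (is.null(cohort)) {
    generated <- file.path(out, "cohort.csv")
    if (file.exists(generated)) cohort <- generated
  }
  if (is.null(cohort)) {
    co <- generateCohort(cohortConfig(n = n, seed = seed), endpoint = endpoint)
    return(list(pairs = co$pairs, labels = co$labels))
  }
  df <- utils::read.csv(cohort, check.names = FALSE, na.strings = "")
  ep <- endPoint(endpoint)
  lab <- labelEndpoint(df$failure_day, df$followup_day, df$unrelated_death, ep)
  keep <- lab != "excluded"
  pairs <- df[keep, schemaFields(), drop = FALSE]
  list(pairs = pairs, labels = as.integer(lab[keep] == "survival"))
}
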
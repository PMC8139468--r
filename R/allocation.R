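## Rule-based donor-recipient allocation.
##
## For each offered organ the model's graft-survival probabilities decide
## alone only when one recipient is *significantly* better: all recipients
## within tau of the column maximum are clinically indistinguishable and the
## decision falls back to disease severity (highest MELD), then to longest
## waiting time. tau defaults to 0.14, one standard deviation of the model's
## predicted probabilities.

## comparisons on printed 3-decimal probabilities need a guard against
## binary-representation error (e.g. 0.675 - 0.535 != 0.14 exactly);
## far below the 0.01 resolution at which tau is ever varied.
.probTol <- 1e-9

#' Construct an allocation configuration
#'
#' @param tau significance threshold on probability differences, in \[0, 1\].
#'   Boundary inclusive: a difference of exactly `tau` keeps the recipient in
#'   the candidate set.
#' @param sequential remove each matched recipient before the next donor
#'   (default `FALSE`: every donor is allocated against the full list).
#' @param populationSD convention used by [sigmaThreshold()].
#' @return an [AllocationConfig-class].
#' @export
allocationConfig <- function(tau = 0.14, sequential = FALSE,
                             populationSD = TRUE) {
  new("AllocationConfig", tau = tau, sequential = sequential,
      populationSD = populationSD)
}

#' Candidate set of a donor column
#'
#' Recipients whose predicted graft-survival probability lies within `tau`
#' of the column maximum (boundary inclusive). Always contains the argmax.
#'
#' @param probs survival probabilities of all recipients with this donor.
#' @param tau significance threshold.
#' @return integer vector of recipient indices.
#' @examples
#' candidateSet(c(0.379, 0.293, 0.410, 0.411, 0.522), tau = 0.14)  # 3 4 5
#' @export
candidateSet <- function(probs, tau = 0.14) {
  if (length(probs) == 0) stop("empty probability column", call. = FALSE)
  if (any(!is.finite(probs))) stop("probabilities must be finite", call. = FALSE)
  which(max(probs) - probs <= tau + .probTol)
}

#' Allocate one donor organ
#'
#' Applies the decision chain within the candidate set: if a single recipient
#' dominates by probability the model decides; otherwise the highest MELD
#' wins; a MELD tie goes to the longest waiting time; an exact residual tie
#' (unresolved by the rule) falls back to the lowest recipient index and is
#' flagged as such in the decision stage.
#'
#' @param probs,meld,waitDays aligned per-recipient vectors.
#' @param config an [AllocationConfig-class].
#' @return list with `chosen` (1-based recipient index), `candidates`
#'   (integer vector) and `stage` (`"probability-dominance"`, `"MELD"`,
#'   `"waiting-time"` or `"index-fallback"`).
#' @examples
#' allocate(c(0.379, 0.293, 0.410, 0.411, 0.522),
#'          meld = c(27, 26, 25, 24, 23), waitDays = rep(0, 5))
#' @export
allocate <- function(probs, meld, waitDays, config = allocationConfig()) {
  stopifnot(is(config, "AllocationConfig"))
  if (length(meld) != length(probs) || length(waitDays) != length(probs))
    stop("probs, meld and waitDays must have one entry per recipient",
         call. = FALSE)
  cand <- candidateSet(probs, config@tau)
  if (length(cand) == 1L)
    return(list(chosen = cand, candidates = cand,
                stage = "probability-dominance"))
  byMeld <- cand[meld[cand] == max(meld[cand])]
  if (length(byMeld) == 1L)
    return(list(chosen = byMeld, candidates = cand, stage = "MELD"))
  byWait <- byMeld[waitDays[byMeld] == max(waitDays[byMeld])]
  if (length(byWait) == 1L)
    return(list(chosen = byWait, candidates = cand, stage = "waiting-time"))
  list(chosen = min(byWait), candidates = cand, stage = "index-fallback")
}

#' Allocate every donor of a scenario
#'
#' Runs [allocate()] on each donor column. By default columns are independent
#' (a recipient may receive several offers, as in the published simulations);
#' with `config@sequential` the matched recipient is removed from the pool
#' before the next donor.
#'
#' @param scenario an [AllocationScenario-class].
#' @param config an [AllocationConfig-class].
#' @return an [AllocationResult-class].
#' @examples
#' sc <- fixtureScenario("mediumMELD")
#' chosenRecipients(allocateMatrix(sc))
#' @export
allocateMatrix <- function(scenario, config = allocationConfig()) {
  stopifnot(is(scenario, "AllocationScenario"))
  nd <- ncol(scenario@probs)
  chosen <- integer(nd)
  cands <- vector("list", nd)
  stage <- character(nd)
  alive <- seq_len(nrow(scenario@probs))
  for (j in seq_len(nd)) {
    dec <- allocate(scenario@probs[alive, j], scenario@meld[alive],
                    scenario@waitDays[alive], config)
    chosen[j] <- alive[dec$chosen]
    cands[[j]] <- alive[dec$candidates]
    stage[j] <- dec$stage
    if (config@sequential) alive <- setdiff(alive, chosen[j])
    if (length(alive) == 0L && j < nd)
      stop("sequential allocation exhausted the recipient list", call. = FALSE)
  }
  new("AllocationResult", chosen = chosen, candidates = cands, stage = stage,
      recipientIds = rownames(scenario@probs) %||%
        paste0("R", seq_len(nrow(scenario@probs))),
      donorIds = colnames(scenario@probs) %||% paste0("D", seq_len(nd)))
}

#' Standard deviation of a probability collection
#'
#' The significance threshold of the allocator is defined as the standard
#' deviation of all probabilities predicted by the survival model; the
#' population convention (divide by n) is the default, the sample convention
#' is available.
#'
#' @param probs predicted probabilities, length >= 2.
#' @param population divide by n (default) rather than n - 1.
#' @return the standard deviation, usable as `tau`.
#' @examples
#' sigmaThreshold(c(0, 1))   # 0.5 under the population convention
#' @export
sigmaThreshold <- function(probs, population = TRUE) {
  n <- length(probs)
  if (n < 2L) stop("need at least 2 probabilities", call. = FALSE)
  mu <- mean(probs)
  v <- sum((probs - mu)^2) / if (population) n else n - 1L
  sqrt(v)
}

#' Construct an allocation scenario
#'
#' @param probs recipients-by-donors probability matrix.
#' @param meld recipient MELD scores.
#' @param waitDays recipient waiting-list days (default 0).
#' @return an [AllocationScenario-class].
#' @export
allocationScenario <- function(probs, meld,
                               waitDays = rep(0, nrow(probs))) {
  probs <- as.matrix(probs)
  if (is.null(rownames(probs))) rownames(probs) <- paste0("R", seq_len(nrow(probs)))
  if (is.null(colnames(probs))) colnames(probs) <- paste0("D", seq_len(ncol(probs)))
  new("AllocationScenario", probs = probs, meld = as.numeric(meld),
      waitDays = as.numeric(waitDays))
}

#' Read an allocation scenario CSV
#'
#' Expected dialect: recipients as rows with columns `id`, `meld`,
#' `wait_days`, then one probability column per donor.
#'
#' @param path CSV file path.
#' @return an [AllocationScenario-class].
#' @export
readScenario <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("id", "meld", "wait_days")
  if (!all(need %in% names(df)))
    stop("scenario CSV must have columns id, meld, wait_days plus donor ",
         "probability columns", call. = FALSE)
  donorCols <- setdiff(names(df), need)
  probs <- as.matrix(df[, donorCols, drop = FALSE])
  rownames(probs) <- df$id
  allocationScenario(probs, df$meld, df$wait_days)
}

#' Packaged simulation scenarios
#'
#' Loads one of the three published allocation-simulation fixtures:
#' `"mediumMELD"` (medium MELD, 23-27), `"highMELD"` (high MELD, 34-40, with a
#' synthetic strictly-increasing waiting-day vector 50/120/200/310/460 for
#' R1-R5 — the real values were not published, only that R5 waited longest)
#' or `"ecd"` (extended-criteria donors: age over 70 or BMI over 40).
#'
#' @param table `"mediumMELD"`, `"highMELD"` or `"ecd"`.
#' @return an [AllocationScenario-class].
#' @export
fixtureScenario <- function(table = c("mediumMELD", "highMELD", "ecd")) {
  table <- match.arg(table)
  file <- c(mediumMELD = "scenario_medium_meld.csv",
            highMELD = "scenario_high_meld.csv",
            ecd = "scenario_ecd.csv")[[table]]
  readScenario(fixturePath(file))
}

#' Published allocation rows of the simulation tables
#'
#' @return named list of integer vectors: the published 1-based recipient
#'   index per donor column for each simulation table.
#' @export
printedAllocations <- function() {
  raw <- jsonlite::read_json(fixturePath("published_allocations.json"))
  lapply(raw[c("mediumMELD", "highMELD", "ecd")], function(x) unlist(x))
}

#' @rdname allocationAccessors
#' @name allocationAccessors
#' @title Accessors for allocation objects
#' @param x an [AllocationResult-class] or [AllocationScenario-class].
#' @return `chosenRecipients()`: named integer vector of chosen recipient
#'   indices; `decisionStages()`: stage per donor; `candidateSets()`: list of
#'   candidate index vectors.
NULL

#' @rdname allocationAccessors
#' @export
setMethod("chosenRecipients", "AllocationResult", function(x)
  stats::setNames(x@chosen, x@donorIds))

#' @rdname allocationAccessors
#' @export
setMethod("decisionStages", "AllocationResult", function(x)
  stats::setNames(x@stage, x@donorIds))

#' @rdname allocationAccessors
#' @export
setMethod("candidateSets", "AllocationResult", function(x)
  stats::setNames(x@candidates, x@donorIds))

#' @rdname scenarioAccessors
#' @name scenarioAccessors
#' @title Accessors for allocation scenarios
#' @param x an [AllocationScenario-class].
#' @return the probability matrix, MELD vector or waiting-day vector.
NULL

#' @rdname scenarioAccessors
#' @export
setMethod("scenarioProbs", "AllocationScenario", function(x) x@probs)

#' @rdname scenarioAccessors
#' @export
setMethod("recipientMELD", "AllocationScenario", function(x)
  stats::setNames(x@meld, rownames(x@probs)))

#' @rdname scenarioAccessors
#' @export
setMethod("waitingDays", "AllocationScenario", function(x)
  stats::setNames(x@waitDays, rownames(x@probs)))

#' @describeIn AllocationScenario-class display dimensions and MELD range.
#' @param object an `AllocationScenario`.
#' @export
setMethod("show", "AllocationScenario", function(object) {
  cat("AllocationScenario:", nrow(object@probs), "recipients x",
      ncol(object@probs), "donors | MELD",
      paste(range(object@meld), collapse = "-"), "\n")
})

#' @describeIn AllocationResult-class display decisions per donor.
#' @param object an `AllocationResult`.
#' @export
setMethod("show", "AllocationResult", function(object) {
  cat("AllocationResult for", length(object@chosen), "donors\n")
  for (j in seq_along(object@chosen))
    cat(sprintf("  %-4s -> %-4s [%s; candidates %s]\n", object@donorIds[j],
                object@recipientIds[object@chosen[j]], object@stage[j],
                paste(object@recipientIds[object@candidates[[j]]],
                      collapse = ",")))
})

#' @describeIn AllocationConfig-class display threshold and modes.
#' @param object an `AllocationConfig`.
#' @export
setMethod("show", "AllocationConfig", function(object) {
  cat("AllocationConfig: tau =", object@tau,
      if (object@sequential) "| sequential" else "| independent columns", "\n")
})
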
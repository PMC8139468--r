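## Cohort schema: the 28 donor-recipient variables, their admissible values,
## and the canonical 49-component feature order shared by the encoder and the
## published model.

.lmCache <- new.env(parent = emptyenv())

## md5 checksums of the packaged fixtures; a mismatch means the installation
## is corrupt and every loader refuses to proceed.
.fixtureChecksums <- c(
  "dr_schema.json"             = "1d5f5b1f091783584e952a8bc9ca4552",
  "published_lr_weights.json"  = "39ac0a6db9ef855ab74b24cb97f41d28",
  "selection_grids.json"       = "44d687f5971b2379f53025fb3e6352b5",
  "endpoint_classes.json"      = "0121a8db02e0880c6be3015a67f9f54a",
  "scenario_medium_meld.csv"   = "26a4ac4eb4ff7ce0661572b8d276fb56",
  "scenario_high_meld.csv"     = "e0e873c2d321b2e9f2f41afe37260926",
  "scenario_ecd.csv"           = "ef0014e5bcf21928d2754eab0a178107",
  "published_allocations.json" = "4a4ab307f95e031cfe39eba485c99def"
)

#' Path to a packaged fixture, verified against its recorded checksum
#'
#' @param file fixture file name under `extdata/`.
#' @param checksum verify the md5 recorded at build time.
#' @return absolute path to the fixture.
#' @keywords internal
fixturePath <- function(file, checksum = TRUE) {
  path <- system.file("extdata", file, package = "liverMatch")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged fixture '", file, "' is missing", call. = FALSE)
  if (checksum && file %in% names(.fixtureChecksums)) {
    got <- unname(tools::md5sum(path))
    want <- unname(.fixtureChecksums[[file]])
    if (!identical(got, want))
      stop("fixture '", file, "' failed its checksum (", got,
           " != ", want, "); refusing to use a corrupted fixture",
           call. = FALSE)
  }
  path
}

#' Load the D-R variable schema
#'
#' Returns the manifest of the 28 donor, recipient and matching variables:
#' for each field its type (`numeric`, `binary`, `nominal`), its admissible
#' range or category codes, and a human-readable label. The manifest ships as
#' a JSON fixture and is cached after the first read.
#'
#' @return a list with one entry per field, named by the short field code.
#' @examples
#' sch <- loadSchema()
#' sch[["ME-R"]]$range     # admissible MELD points
#' @export
loadSchema <- function() {
  if (!is.null(.lmCache$schema)) return(.lmCache$schema)
  raw <- jsonlite::read_json(fixturePath("dr_schema.json"))
  fields <- list()
  for (f in raw$fields) {
    entry <- list(name = f$name, owner = f$owner, label = f$label,
                  type = f$type)
    if (!is.null(f$range)) entry$range <- unlist(f$range)
    entry$levels <- if (identical(f$type, "binary")) c(0, 1)
                    else if (!is.null(f$levels)) unlist(f$levels)
    fields[[f$name]] <- entry
  }
  .lmCache$schema <- fields
  fields
}

#' Field names of the cohort schema
#'
#' @param type optionally restrict to `"numeric"`, `"binary"` or `"nominal"`
#'   fields.
#' @return character vector of field codes in schema order.
#' @export
schemaFields <- function(type = NULL) {
  sch <- loadSchema()
  nm <- names(sch)
  if (is.null(type)) return(nm)
  nm[vapply(sch, function(f) f$type == type, logical(1))]
}

#' Validate a cohort data frame against the schema
#'
#' Checks that all 28 schema columns are present, that observed numeric
#' values lie within their admissible ranges, and that binary/nominal values
#' are admissible category codes. Missing values (`NA`) are allowed unless
#' `allowMissing = FALSE`.
#'
#' @param pairs data frame with one row per D-R pair, columns named by the
#'   schema field codes.
#' @param allowMissing whether `NA` entries are acceptable.
#' @return `pairs`, invisibly, if valid; otherwise an error naming the first
#'   offending field and value.
#' @export
validatePairs <- function(pairs, allowMissing = TRUE) {
  sch <- loadSchema()
  missingCols <- setdiff(names(sch), names(pairs))
  if (length(missingCols) > 0)
    stop("cohort is missing schema column(s): ",
         paste(missingCols, collapse = ", "), call. = FALSE)
  for (fname in names(sch)) {
    f <- sch[[fname]]
    v <- pairs[[fname]]
    if (!allowMissing && anyNA(v))
      stop("field '", fname, "' contains missing values; impute first",
           call. = FALSE)
    obs <- v[!is.na(v)]
    if (length(obs) == 0) next
    if (f$type == "numeric") {
      bad <- obs < f$range[1] | obs > f$range[2]
      if (any(bad))
        stop("field '", fname, "': value ", format(obs[which(bad)[1]]),
             " outside admissible range [", f$range[1], ", ", f$range[2], "]",
             call. = FALSE)
    } else {
      bad <- !obs %in% f$levels
      if (any(bad))
        stop("field '", fname, "': unknown category code '",
             obs[which(bad)[1]], "' (admissible: ",
             paste(f$levels, collapse = ", "), ")", call. = FALSE)
    }
  }
  invisible(pairs)
}

#' Canonical feature order of the encoded vector
#'
#' The 49 component names of the encoded feature vector, in the frozen
#' canonical order of the packaged published model (rank order by coefficient
#' magnitude). One-hot components are written `FIELD(level)`. Encoder output
#' and model weight vectors align by construction because both use this
#' manifest.
#'
#' @return character vector of length 49.
#' @examples
#' head(canonicalFeatureNames())
#' @export
canonicalFeatureNames <- function() {
  if (!is.null(.lmCache$canon)) return(.lmCache$canon)
  raw <- jsonlite::read_json(fixturePath("published_lr_weights.json"))
  w <- raw$weights
  ranks <- vapply(w, function(x) x$rank, numeric(1))
  nm <- vapply(w, function(x) x$name, character(1))[order(ranks)]
  .lmCache$canon <- nm
  nm
}

## Split a canonical component name into field and (optional) one-hot level.
.parseComponent <- function(component) {
  m <- regmatches(component, regexec("^(.*)\\(([0-9]+)\\)$", component))[[1]]
  if (length(m) == 3L)
    list(field = m[2], level = as.numeric(m[3]))
  else
    list(field = component, level = NA_real_)
}
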
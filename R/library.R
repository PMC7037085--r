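#' Expected library of metabolite alterations per disease
#'
#' The expected library is the knowledge base of the algorithm: one row
#' per (disease, metabolite, fluid) combination stating which metabolite
#' is expected increased or decreased in which body fluid, how specific
#' it is for the disease, and how important the alteration is for the
#' diagnosis. Diseases carry nosology metadata and an artefact
#' disclaimer; seven-odd non-IEM "conditions and interferences" (liver
#' failure, fasting, ...) are represented with `is_condition = TRUE` and
#' scored identically to IEM.
#'
#' @slot diseases data.frame with one row per disease/condition:
#'   `iem_id`, `name`, `category`, `gene`, `omim`, `incidence`,
#'   `artefact_disclaimer`, `is_condition`.
#' @slot entries data.frame with one row per metabolite entry:
#'   `iem_id`, `metabolite_name`, `hmdb_id`, `mz` (monoisotopic neutral
#'   mass, Da), `direction`, `fluid`, `role`, `only_biomarker`,
#'   `importance`, `has_endogenous_isomers`, `isomer_names`
#'   (semicolon-separated), `line` (source line, for diagnostics).
#' @slot weightConfig the [WeightConfig-class] used when scoring.
#'
#' @seealso [readExpectedLibrary()], [validateLibrary()]
#' @include weights.R
#' @export
setClass("ExpectedLibrary",
  representation(diseases = "data.frame", entries = "data.frame",
                 weightConfig = "WeightConfig"),
  validity = function(object) {
    d <- object@diseases; e <- object@entries
    msgs <- character()
    needD <- c("iem_id", "name", "is_condition")
    needE <- c("iem_id", "metabolite_name", "hmdb_id", "mz", "direction",
               "fluid", "role", "only_biomarker", "importance")
    if (!all(needD %in% names(d)))
      msgs <- c(msgs, "diseases is missing mandatory columns")
    if (!all(needE %in% names(e)))
      msgs <- c(msgs, "entries is missing mandatory columns")
    if (length(msgs)) return(msgs)
    if (anyDuplicated(d$iem_id))
      msgs <- c(msgs, "duplicate iem_id in diseases")
    if (any(!nzchar(d$name)))
      msgs <- c(msgs, "disease name must be non-empty")
    if (nrow(e)) {
      if (any(!is.finite(e$mz)) || any(e$mz <= 0))
        msgs <- c(msgs, "entry mz must be positive and finite")
      if (any(!nzchar(e$hmdb_id)))
        msgs <- c(msgs, "entry hmdb_id must be non-empty")
      if (!all(e$direction %in% DIRECTION_LEVELS))
        msgs <- c(msgs, "invalid direction value")
      if (!all(e$fluid %in% FLUID_LEVELS))
        msgs <- c(msgs, "invalid fluid value")
      if (!all(e$role %in% ROLE_LEVELS))
        msgs <- c(msgs, "invalid role value")
      if (!all(e$importance %in% IMPORTANCE_LEVELS))
        msgs <- c(msgs, "invalid importance value")
      orphan <- setdiff(e$iem_id, d$iem_id)
      if (length(orphan))
        msgs <- c(msgs, paste0("entries reference unknown iem_id: ",
                               paste(unique(orphan), collapse = ", ")))
    }
    if (length(msgs)) msgs else TRUE
  })

LIBRARY_COLUMNS <- c("iem_id", "disease_name", "category", "gene", "omim",
  "incidence", "artefact_disclaimer", "is_condition", "metabolite_name",
  "hmdb_id", "mz", "direction", "fluid", "role", "only_biomarker",
  "importance", "has_endogenous_isomers", "isomer_names")

MANDATORY_COLUMNS <- c("iem_id", "disease_name", "metabolite_name",
  "hmdb_id", "mz", "direction", "fluid", "role", "only_biomarker",
  "importance")

#' Construct an ExpectedLibrary from disease and entry tables
#'
#' @param diseases data.frame of diseases (see
#'   [ExpectedLibrary-class]); missing optional columns are filled with
#'   empty strings and `is_condition = FALSE`.
#' @param entries data.frame of metabolite entries.
#' @param weightConfig a [WeightConfig-class].
#' @return a validated [ExpectedLibrary-class].
#' @export
expectedLibrary <- function(diseases, entries,
                            weightConfig = new("WeightConfig")) {
  for (col in c("category", "gene", "omim", "incidence",
                "artefact_disclaimer"))
    if (is.null(diseases[[col]])) diseases[[col]] <- ""
  if (is.null(diseases$is_condition)) diseases$is_condition <- FALSE
  if (is.null(entries$has_endogenous_isomers))
    entries$has_endogenous_isomers <- FALSE
  if (is.null(entries$isomer_names)) entries$isomer_names <- ""
  if (is.null(entries$line)) entries$line <- seq_len(nrow(entries))
  rownames(diseases) <- rownames(entries) <- NULL
  new("ExpectedLibrary", diseases = diseases, entries = entries,
      weightConfig = weightConfig)
}

parseYesNo <- function(x, col, lines) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("yes", "true", "1")] <- TRUE
  out[lx %in% c("no", "false", "0", "")] <- FALSE
  if (anyNA(out))
    stop("column '", col, "' has unparseable boolean at line ",
         paste(lines[is.na(out)], collapse = ", "),
         " (allowed: yes/no)", call. = FALSE)
  out
}

checkEnum <- function(x, col, allowed, lines) {
  bad <- !(x %in% allowed)
  if (any(bad))
    stop("column '", col, "' has invalid value '", x[which(bad)[1]],
         "' at line ", lines[which(bad)[1]], "; allowed values: {",
         paste(allowed, collapse = ", "), "}", call. = FALSE)
  x
}

#' Read an expected library from a TSV file
#'
#' The file is UTF-8 tab-separated with one row per metabolite entry and
#' the disease metadata repeated on each of its rows. Mandatory columns:
#' `iem_id`, `disease_name`, `metabolite_name`, `hmdb_id`, `mz`,
#' `direction`, `fluid`, `role`, `only_biomarker`, `importance`.
#' Optional: `category`, `gene`, `omim`, `incidence`,
#' `artefact_disclaimer`, `is_condition`, `has_endogenous_isomers`,
#' `isomer_names`. Booleans are serialized yes/no. Unknown columns are
#' ignored with a warning. A `columnMap` (named character vector or YAML
#' file path, `ours = theirs`) renames foreign headers onto this schema
#' so externally curated spreadsheets can be loaded unchanged.
#'
#' On load the entry and disease counts are reported via `message()`.
#'
#' @param path path to the TSV file.
#' @param weightConfig a [WeightConfig-class] to attach.
#' @param columnMap optional named character vector, or path to a YAML
#'   file, mapping schema column names to the file's column names.
#' @return a validated [ExpectedLibrary-class]; row order is preserved.
#' @examples
#' toy <- system.file("extdata", "toy_library.tsv", package = "iemrank")
#' lib <- readExpectedLibrary(toy)
#' nrow(libraryEntries(lib))
#' @export
readExpectedLibrary <- function(path, weightConfig = new("WeightConfig"),
                                columnMap = NULL) {
  if (!file.exists(path)) stop("library file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, fileEncoding = "UTF-8")
  if (!is.null(columnMap)) {
    if (is.character(columnMap) && length(columnMap) == 1L &&
        file.exists(columnMap))
      columnMap <- unlist(yaml::read_yaml(columnMap))
    for (ours in names(columnMap)) {
      theirs <- columnMap[[ours]]
      if (theirs %in% names(raw))
        names(raw)[names(raw) == theirs] <- ours
    }
  }
  missing <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing))
    stop("library file is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(raw), LIBRARY_COLUMNS)
  if (length(extra))
    warning("ignoring unknown library column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)

  lines <- seq_len(nrow(raw)) + 1L  # 1-based file lines incl. header
  mz <- suppressWarnings(as.numeric(raw$mz))
  if (anyNA(mz))
    stop("column 'mz' is not numeric at line ",
         lines[which(is.na(mz))[1]], call. = FALSE)

  entries <- data.frame(
    iem_id = raw$iem_id,
    metabolite_name = raw$metabolite_name,
    hmdb_id = raw$hmdb_id,
    mz = mz,
    direction = checkEnum(trimws(raw$direction), "direction",
                          DIRECTION_LEVELS, lines),
    fluid = checkEnum(trimws(raw$fluid), "fluid", FLUID_LEVELS, lines),
    role = checkEnum(trimws(raw$role), "role", ROLE_LEVELS, lines),
    only_biomarker = parseYesNo(raw$only_biomarker, "only_biomarker",
                                lines),
    importance = checkEnum(trimws(raw$importance), "importance",
                           IMPORTANCE_LEVELS, lines),
    has_endogenous_isomers = if (is.null(raw$has_endogenous_isomers))
      FALSE else parseYesNo(raw$has_endogenous_isomers,
                            "has_endogenous_isomers", lines),
    isomer_names = if (is.null(raw$isomer_names)) "" else
      raw$isomer_names,
    line = lines,
    stringsAsFactors = FALSE)

  firstRow <- !duplicated(raw$iem_id)
  getcol <- function(col) if (is.null(raw[[col]])) "" else
    raw[[col]][firstRow]
  diseases <- data.frame(
    iem_id = raw$iem_id[firstRow],
    name = raw$disease_name[firstRow],
    category = getcol("category"),
    gene = getcol("gene"),
    omim = getcol("omim"),
    incidence = getcol("incidence"),
    artefact_disclaimer = getcol("artefact_disclaimer"),
    is_condition = if (is.null(raw$is_condition)) FALSE else
      parseYesNo(raw$is_condition[firstRow], "is_condition",
                 lines[firstRow]),
    stringsAsFactors = FALSE)

  lib <- expectedLibrary(diseases, entries, weightConfig)
  message("expected library: ", nrow(entries), " entries, ",
          length(unique(entries$hmdb_id)), " unique metabolites, ",
          nrow(diseases), " diseases/conditions")
  lib
}

#' Write an expected library to a TSV file
#'
#' Inverse of [readExpectedLibrary()]: a read-write-read round trip
#' reproduces the library exactly.
#'
#' @param lib an [ExpectedLibrary-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpectedLibrary <- function(lib, path) {
  stopifnot(is(lib, "ExpectedLibrary"))
  e <- lib@entries
  d <- lib@diseases[match(e$iem_id, lib@diseases$iem_id), ]
  yn <- function(x) ifelse(x, "yes", "no")
  out <- data.frame(
    iem_id = e$iem_id, disease_name = d$name, category = d$category,
    gene = d$gene, omim = d$omim, incidence = d$incidence,
    artefact_disclaimer = d$artefact_disclaimer,
    is_condition = yn(d$is_condition),
    metabolite_name = e$metabolite_name, hmdb_id = e$hmdb_id,
    mz = sprintf("%.9g", e$mz), direction = e$direction,
    fluid = e$fluid, role = e$role,
    only_biomarker = yn(e$only_biomarker), importance = e$importance,
    has_endogenous_isomers = yn(e$has_endogenous_isomers),
    isomer_names = e$isomer_names, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @describeIn ExpectedLibrary-class entry table accessor.
#' @param lib an `ExpectedLibrary`.
#' @export
libraryEntries <- function(lib) lib@entries

#' @describeIn ExpectedLibrary-class disease table accessor.
#' @export
libraryDiseases <- function(lib) lib@diseases

#' @describeIn ExpectedLibrary-class weight configuration accessor.
#' @export
libraryWeightConfig <- function(lib) lib@weightConfig

#' Consistency checks on an expected library
#'
#' Reports, as a data.frame of findings with severity levels, every
#' duplicate (iem_id, hmdb_id) pair, disease without entries, entry
#' flagged both only-biomarker and substrate/product (legal but usually
#' a curation slip: only one factor is applied), and — when a mass table
#' is supplied — critical entry whose metabolite is absent from the mass
#' table and therefore can never be observed, which permanently gates
#' its disease out of every DD.
#'
#' @param lib an [ExpectedLibrary-class].
#' @param massTable optional mass table (see [readMassTable()]).
#' @return data.frame with columns `severity` ("warning"/"info"),
#'   `finding`, `iem_id`, `hmdb_id`, `lines`; zero rows when clean.
#' @export
validateLibrary <- function(lib, massTable = NULL) {
  stopifnot(is(lib, "ExpectedLibrary"))
  e <- lib@entries
  f <- list()
  add <- function(severity, finding, iem_id = "", hmdb_id = "",
                  lines = "")
    f[[length(f) + 1L]] <<- data.frame(severity, finding, iem_id,
                                       hmdb_id, lines)

  key <- paste(e$iem_id, e$hmdb_id, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    add("warning", "duplicate (iem_id, hmdb_id) entry",
        e$iem_id[idx[1]], e$hmdb_id[idx[1]],
        paste(e$line[idx], collapse = ","))
  }
  empty <- setdiff(lib@diseases$iem_id, e$iem_id)
  for (d in empty)
    add("warning", "disease has no metabolite entries", d)
  both <- which(e$only_biomarker & e$role == "substrate_or_product")
  for (i in both)
    add("info", "entry flagged both only_biomarker and substrate_or_product",
        e$iem_id[i], e$hmdb_id[i], as.character(e$line[i]))
  if (!is.null(massTable)) {
    crit <- which(e$importance == "critical" &
                  !(e$hmdb_id %in% massTable$hmdb_id))
    for (i in crit)
      add("warning", "critical entry absent from mass table",
          e$iem_id[i], e$hmdb_id[i], as.character(e$line[i]))
  }
  if (length(f)) do.call(rbind, f) else
    data.frame(severity = character(), finding = character(),
               iem_id = character(), hmdb_id = character(),
               lines = character())
}

setMethod("show", "ExpectedLibrary", function(object) {
  d <- object@diseases
  cat("ExpectedLibrary:", nrow(object@entries), "entries,",
      length(unique(object@entries$hmdb_id)), "unique metabolites,",
      sum(!d$is_condition), "IEM +", sum(d$is_condition),
      "conditions/interferences\n")
})
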
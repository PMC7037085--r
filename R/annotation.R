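#' Sorted mass index for ppm-tolerance peak annotation
#'
#' Holds per-ionization-mode theoretical m/z values for every metabolite
#' in a mass table, sorted so that annotation is a binary range search.
#' Theoretical m/z = neutral monoisotopic mass + adduct shift: by
#' default a single protonation per mode, [M+H]+ in positive and [M-H]-
#' in negative mode (proton mass 1.007276 Da).
#'
#' @slot table data.frame sorted by (`mode`, `mz_theo`) with columns
#'   `mode`, `mz_theo`, `hmdb_id`, `name`, `mass`.
#' @slot tolerancePpm matching tolerance in parts per million of the
#'   theoretical m/z (default 2, inclusive).
#' @slot adducts the adduct specification used (data.frame `mode`,
#'   `shift`).
#' @seealso [buildMassIndex()], [annotatePeaks()]
#' @export
setClass("MassIndex",
  representation(table = "data.frame", tolerancePpm = "numeric",
                 adducts = "data.frame"),
  validity = function(object) {
    t <- object@table
    if (!all(c("mode", "mz_theo", "hmdb_id") %in% names(t)))
      return("index table must have mode, mz_theo, hmdb_id")
    if (length(object@tolerancePpm) != 1L || object@tolerancePpm <= 0)
      return("tolerancePpm must be a single positive number")
    for (m in unique(t$mode))
      if (is.unsorted(t$mz_theo[t$mode == m]))
        return("index must be sorted by mz_theo within mode")
    TRUE
  })

#' Default single-protonation adduct specification
#'
#' @return data.frame with one adduct per mode: `[M+H]+` (shift
#'   +1.007276 Da) and `[M-H]-` (shift -1.007276 Da).
#' @export
protonAdducts <- function()
  data.frame(mode = MODE_LEVELS, shift = c(PROTON_MASS, -PROTON_MASS))

#' Read a metabolite mass table
#'
#' TSV with columns `hmdb_id`, `name`, `monoisotopic_mass` (neutral, in
#' Da) and `endogenous` (yes/no): the HMDB-style input of the
#' annotation stage.
#'
#' @param path path to the TSV file.
#' @return data.frame with those four columns, `endogenous` logical.
#' @export
readMassTable <- function(path) {
  if (!file.exists(path)) stop("mass table not found: ", path)
  raw <- read.delim(path, sep = "\t", colClasses = "character",
                    fileEncoding = "UTF-8")
  need <- c("hmdb_id", "name", "monoisotopic_mass", "endogenous")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("mass table is missing column(s): ",
         paste(missing, collapse = ", "))
  mass <- as.numeric(raw$monoisotopic_mass)
  if (anyNA(mass) || any(mass <= 0))
    stop("monoisotopic_mass must be positive numbers")
  data.frame(hmdb_id = raw$hmdb_id, name = raw$name,
             monoisotopic_mass = mass,
             endogenous = parseYesNo(raw$endogenous, "endogenous",
                                     seq_along(mass) + 1L),
             stringsAsFactors = FALSE)
}

#' Build a mass index from a metabolite mass table
#'
#' @param massTable data.frame as returned by [readMassTable()] (columns
#'   `hmdb_id`, `name`, `monoisotopic_mass`, `endogenous`).
#' @param adducts adduct specification, data.frame (`mode`, `shift` in
#'   Da); default [protonAdducts()].
#' @param tolerancePpm matching tolerance (ppm, inclusive); default 2.
#' @param endogenousOnly drop metabolites that cannot occur
#'   endogenously (default `TRUE`, matching how annotations are selected
#'   for human samples).
#' @return a [MassIndex-class] with one entry per metabolite per mode.
#' @examples
#' mt <- data.frame(hmdb_id = "HMDB0000122", name = "glucose",
#'                  monoisotopic_mass = 180.063388, endogenous = TRUE)
#' idx <- buildMassIndex(mt)
#' @export
buildMassIndex <- function(massTable, adducts = protonAdducts(),
                           tolerancePpm = 2, endogenousOnly = TRUE) {
  stopifnot(is.data.frame(massTable), nrow(massTable) > 0)
  if (endogenousOnly) massTable <- massTable[massTable$endogenous, ]
  if (nrow(massTable) == 0L)
    stop("no metabolites left after endogenous filtering")
  parts <- lapply(seq_len(nrow(adducts)), function(i)
    data.frame(mode = adducts$mode[i],
               mz_theo = massTable$monoisotopic_mass + adducts$shift[i],
               hmdb_id = massTable$hmdb_id, name = massTable$name,
               mass = massTable$monoisotopic_mass,
               stringsAsFactors = FALSE))
  tab <- do.call(rbind, parts)
  tab <- tab[order(tab$mode, tab$mz_theo, tab$hmdb_id), ]
  rownames(tab) <- NULL
  new("MassIndex", table = tab, tolerancePpm = tolerancePpm,
      adducts = adducts)
}

#' Annotate observed m/z peaks against a mass index
#'
#' A peak is annotated with every metabolite whose theoretical m/z
#' satisfies `|mz_obs - mz_theo| / mz_theo * 1e6 <= tolerancePpm`
#' (inclusive window, denominator the theoretical m/z). Because direct
#' infusion resolves features by m/z alone, isomers with identical mass
#' all land on the same peak: annotation is one-to-many and downstream
#' scoring sees one shared Z-score per peak. Peaks outside the
#' instrument scan range are excluded when `rangeFilter` is on;
#' unmatched peaks are kept with an empty annotation list (they are
#' dropped by scoring, which only consumes annotated features).
#'
#' @param peaks data.frame with columns `mode`
#'   ("positive"/"negative") and `mz` (observed, Da); extra columns are
#'   carried through.
#' @param index a [MassIndex-class].
#' @param mzRange numeric length-2 scan range in m/z (default
#'   `c(70, 600)`).
#' @param rangeFilter apply the scan-range filter (default `TRUE`).
#' @return the `peaks` data.frame (range-filtered, original order
#'   otherwise preserved) with a list-column `annotations` of hmdb_id
#'   character vectors and an integer column `n_annotations`.
#' @export
annotatePeaks <- function(peaks, index, mzRange = c(70, 600),
                          rangeFilter = TRUE) {
  stopifnot(is(index, "MassIndex"))
  if (!all(peaks$mode %in% MODE_LEVELS))
    stop("peak mode must be one of: ", paste(MODE_LEVELS, collapse = ", "))
  if (rangeFilter)
    peaks <- peaks[peaks$mz >= mzRange[1] & peaks$mz <= mzRange[2], ,
                   drop = FALSE]
  rownames(peaks) <- NULL
  tol <- index@tolerancePpm * 1e-6
  ann <- vector("list", nrow(peaks))
  for (m in unique(peaks$mode)) {
    sub <- index@table[index@table$mode == m, ]
    pidx <- which(peaks$mode == m)
    # mz_theo in [mz/(1+tol), mz/(1-tol)] <=> |mz-mz_theo| <= tol*mz_theo
    lo <- findInterval(peaks$mz[pidx] / (1 + tol), sub$mz_theo,
                       left.open = TRUE) + 1L
    hi <- findInterval(peaks$mz[pidx] / (1 - tol), sub$mz_theo)
    for (j in seq_along(pidx))
      ann[[pidx[j]]] <- if (hi[j] >= lo[j])
        sub$hmdb_id[lo[j]:hi[j]] else character()
  }
  peaks$annotations <- ann
  peaks$n_annotations <- lengths(ann)
  peaks
}

#' Long-format annotation table
#'
#' Unnests the result of [annotatePeaks()] to one row per
#' (peak, metabolite) pair; unannotated peaks are dropped. This is the
#' join table the scoring stage uses to resolve library entries to
#' observed features.
#'
#' @param annotated output of [annotatePeaks()].
#' @return data.frame `mode`, `mz`, `hmdb_id`.
#' @export
annotationTable <- function(annotated) {
  n <- annotated$n_annotations
  data.frame(mode = rep(annotated$mode, n),
             mz = rep(annotated$mz, n),
             hmdb_id = unlist(annotated$annotations, use.names = FALSE),
             stringsAsFactors = FALSE)
}

setMethod("show", "MassIndex", function(object) {
  cat("MassIndex:", nrow(object@table), "theoretical m/z (",
      paste(unique(object@table$mode), collapse = "/"), "),",
      object@tolerancePpm, "ppm tolerance\n")
})
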
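#' Cohort performance summary
#'
#' Aggregates a set of per-sample differential diagnoses against the
#' true diagnoses: the share of patient samples whose true disease is
#' anywhere in the DD, in the top 3, and at rank 1, plus DD-length
#' statistics (median and nearest-rank 5th/95th percentiles). Control
#' samples are summarized separately with length statistics only.
#'
#' @slot patients list: `n_samples`, `n_patients`, `n_distinct_iem`,
#'   `n_in_dd`, `pct_in_dd`, `n_top3`, `pct_top3`, `n_rank1`,
#'   `pct_rank1`, `dd_length_median`, `dd_length_p5`, `dd_length_p95`.
#'   Percentages are `NA` when there are no patient samples.
#' @slot controls list: `n_samples`, `dd_length_median`,
#'   `dd_length_p5`, `dd_length_p95`.
#' @slot perSample data.frame with per-sample detail (`sample_id`,
#'   `true_iem_id`, `dd_length`, `dd_rank` of the true disease, `NA`
#'   when absent or control).
#' @export
setClass("PerformanceSummary",
  representation(patients = "list", controls = "list",
                 perSample = "data.frame"))

#' Read a truth manifest
#'
#' TSV with columns `sample_id`, `patient_id`, `set`, `matrix`,
#' `true_iem_id`; an empty `true_iem_id` marks a control sample.
#'
#' @param path path to the TSV file.
#' @return data.frame with those columns.
#' @export
readTruthManifest <- function(path) {
  if (!file.exists(path)) stop("truth manifest not found: ", path)
  raw <- read.delim(path, sep = "\t", colClasses = "character",
                    na.strings = NULL, fileEncoding = "UTF-8")
  need <- c("sample_id", "patient_id", "true_iem_id")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("truth manifest is missing column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(raw$sample_id))
    stop("duplicate sample_id in truth manifest")
  if (is.null(raw$set)) raw$set <- ""
  if (is.null(raw$matrix)) raw$matrix <- ""
  raw
}

# nearest-rank percentile: smallest value with at least p*n observations
# at or below it
nearestRank <- function(x, p) {
  x <- sort(x)
  if (!length(x)) return(NA_real_)
  x[max(1L, ceiling(p * length(x)))]
}

#' Evaluate a set of differential diagnoses against the truth
#'
#' @param dds list of [DifferentialDiagnosis-class].
#' @param truth truth manifest data.frame ([readTruthManifest()]):
#'   `sample_id`, `patient_id`, `true_iem_id` (empty string or `NA` for
#'   controls).
#' @return a [PerformanceSummary-class].
#' @examples
#' # four patient samples with the true disease at DD ranks
#' # 1, 2, 5 and absent give 75% in-DD, 50% top-3, 25% rank-1
#' @export
evaluateSampleSet <- function(dds, truth) {
  ids <- vapply(dds, function(x) x@sampleId, "")
  missing <- setdiff(ids, truth$sample_id)
  if (length(missing))
    stop("sample(s) absent from truth manifest: ",
         paste(missing, collapse = ", "))
  tr <- truth[match(ids, truth$sample_id), ]
  isControl <- is.na(tr$true_iem_id) | !nzchar(tr$true_iem_id)
  ddLen <- vapply(dds, function(x) nrow(x@dd), 0L)
  ddRank <- vapply(seq_along(dds), function(i) {
    if (isControl[i]) return(NA_integer_)
    hit <- match(tr$true_iem_id[i], dds[[i]]@dd$iem_id)
    if (is.na(hit)) NA_integer_ else dds[[i]]@dd$dd_rank[hit]
  }, 0L)
  summarizeEvaluation(ids, tr, isControl, ddLen, ddRank)
}

#' Evaluate from a flat DD table
#'
#' Same metrics as [evaluateSampleSet()], computed from the flat TSV
#' representation of the DDs (`sample_id`, `dd_rank`, `iem_id`, ...) —
#' the form written by [writeDDReports()]. Every sample of the truth
#' manifest is evaluated; samples absent from the table have an empty
#' DD.
#'
#' @param ddFlat data.frame with columns `sample_id`, `dd_rank`,
#'   `iem_id`.
#' @param truth truth manifest data.frame.
#' @return a [PerformanceSummary-class].
#' @export
evaluateDDTable <- function(ddFlat, truth) {
  missing <- setdiff(unique(ddFlat$sample_id), truth$sample_id)
  if (length(missing))
    stop("sample(s) absent from truth manifest: ",
         paste(missing, collapse = ", "))
  ids <- truth$sample_id
  isControl <- is.na(truth$true_iem_id) | !nzchar(truth$true_iem_id)
  ddLen <- vapply(ids, function(s)
    sum(ddFlat$sample_id == s), 0L, USE.NAMES = FALSE)
  ddRank <- vapply(seq_along(ids), function(i) {
    if (isControl[i]) return(NA_integer_)
    hit <- which(ddFlat$sample_id == ids[i] &
                 ddFlat$iem_id == truth$true_iem_id[i])
    if (length(hit)) as.integer(ddFlat$dd_rank[hit[1]]) else
      NA_integer_
  }, 0L)
  summarizeEvaluation(ids, truth, isControl, ddLen, ddRank)
}

summarizeEvaluation <- function(ids, tr, isControl, ddLen, ddRank) {
  perSample <- data.frame(sample_id = ids,
                          true_iem_id = ifelse(isControl, "",
                                               tr$true_iem_id),
                          is_control = isControl,
                          dd_length = ddLen, dd_rank = ddRank)
  p <- !isControl
  np <- sum(p)
  pct <- function(n) if (np) 100 * n / np else NA_real_
  patients <- list(
    n_samples = np,
    n_patients = length(unique(tr$patient_id[p])),
    n_distinct_iem = length(unique(tr$true_iem_id[p])),
    n_in_dd = sum(!is.na(ddRank[p])),
    pct_in_dd = pct(sum(!is.na(ddRank[p]))),
    n_top3 = sum(ddRank[p] <= 3, na.rm = TRUE),
    pct_top3 = pct(sum(ddRank[p] <= 3, na.rm = TRUE)),
    n_rank1 = sum(ddRank[p] == 1, na.rm = TRUE),
    pct_rank1 = pct(sum(ddRank[p] == 1, na.rm = TRUE)),
    dd_length_median = if (np) median(ddLen[p]) else NA_real_,
    dd_length_p5 = nearestRank(ddLen[p], 0.05),
    dd_length_p95 = nearestRank(ddLen[p], 0.95))
  controls <- list(
    n_samples = sum(isControl),
    dd_length_median = if (any(isControl)) median(ddLen[isControl])
      else NA_real_,
    dd_length_p5 = nearestRank(ddLen[isControl], 0.05),
    dd_length_p95 = nearestRank(ddLen[isControl], 0.95))
  new("PerformanceSummary", patients = patients, controls = controls,
      perSample = perSample)
}

#' @describeIn PerformanceSummary-class patient metrics accessor.
#' @param x a `PerformanceSummary`.
#' @export
patientMetrics <- function(x) x@patients

#' @describeIn PerformanceSummary-class control metrics accessor.
#' @export
controlMetrics <- function(x) x@controls

#' @describeIn PerformanceSummary-class per-sample detail accessor.
#' @export
perSampleResults <- function(x) x@perSample

setMethod("show", "PerformanceSummary", function(object) {
  p <- object@patients; c0 <- object@controls
  cat("PerformanceSummary\n")
  if (p$n_samples) {
    cat(sprintf("  patients: %d samples, %d patients, %d distinct diseases\n",
                p$n_samples, p$n_patients, p$n_distinct_iem))
    cat(sprintf("  correct in DD  %d/%d; %.0f%%\n", p$n_in_dd,
                p$n_samples, p$pct_in_dd))
    cat(sprintf("  correct top 3  %d/%d; %.0f%%\n", p$n_top3,
                p$n_samples, p$pct_top3))
    cat(sprintf("  correct rank 1 %d/%d; %.0f%%\n", p$n_rank1,
                p$n_samples, p$pct_rank1))
    cat(sprintf("  DD length median %.1f (5th-95th: %g-%g)\n",
                p$dd_length_median, p$dd_length_p5, p$dd_length_p95))
  }
  if (c0$n_samples)
    cat(sprintf("  controls: %d samples, DD length median %.1f (%g-%g)\n",
                c0$n_samples, c0$dd_length_median, c0$dd_length_p5,
                c0$dd_length_p95))
})

#' Categorize why a diagnosis was missed
#'
#' For every patient sample whose true disease is absent from its DD,
#' reports the machine-detectable failure category: `"gated"` (a
#' critical entry failed its threshold; the entries are identified),
#' `"unmeasured"` (none of the disease's library entries resolved to an
#' observed feature), or `"subthreshold"` (scored but <= 1, the score is
#' reported).
#'
#' @param dds list of [DifferentialDiagnosis-class].
#' @param truth truth manifest data.frame.
#' @return data.frame `sample_id`, `true_iem_id`, `category`, `score`,
#'   `failed_entries` (semicolon-joined hmdb ids, gated misses only);
#'   zero rows when nothing was missed.
#' @export
failureBreakdown <- function(dds, truth) {
  rows <- list()
  for (x in dds) {
    tr <- truth[truth$sample_id == x@sampleId, ]
    if (!nrow(tr)) stop("sample absent from truth manifest: ", x@sampleId)
    id <- tr$true_iem_id[1]
    if (is.na(id) || !nzchar(id)) next
    if (id %in% x@dd$iem_id) next
    res <- x@results[[id]]
    if (is.null(res)) stop("true disease not in library: ", id)
    cat_ <- if (res@gated) "gated"
      else if (!any(res@contributions$observed)) "unmeasured"
      else "subthreshold"
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = x@sampleId, true_iem_id = id, category = cat_,
      score = res@probabilityScore,
      failed_entries = paste(res@gateReasons$hmdb_id, collapse = ";"))
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), true_iem_id = character(),
               category = character(), score = numeric(),
               failed_entries = character())
}

#' Write a performance summary as TSV and JSON
#'
#' The TSV mirrors the layout of a cohort performance table: one metric
#' per row, one column per evaluated set. Full precision is retained in
#' the JSON; the TSV prints percentages rounded to whole percent.
#'
#' @param summaries named list of [PerformanceSummary-class] (one per
#'   sample set).
#' @param tsvPath,jsonPath output paths (`NULL` to skip either).
#' @return invisibly, the paths written.
#' @export
writePerformanceSummary <- function(summaries, tsvPath = NULL,
                                    jsonPath = NULL) {
  if (is(summaries, "PerformanceSummary"))
    summaries <- list(cohort = summaries)
  if (!is.null(jsonPath))
    jsonlite::write_json(
      lapply(summaries, function(s)
        list(patients = s@patients, controls = s@controls)),
      jsonPath, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(tsvPath)) {
    fmt <- function(s) {
      p <- s@patients; c0 <- s@controls
      c(samples = p$n_samples,
        patients = p$n_patients,
        iem = p$n_distinct_iem,
        correct_in_dd = sprintf("%d/%d; %.0f%%", p$n_in_dd,
                                p$n_samples, p$pct_in_dd),
        correct_top3 = sprintf("%d/%d; %.0f%%", p$n_top3, p$n_samples,
                               p$pct_top3),
        correct_rank1 = sprintf("%d/%d; %.0f%%", p$n_rank1,
                                p$n_samples, p$pct_rank1),
        dd_length = sprintf("%g; (%g-%g)", p$dd_length_median,
                            p$dd_length_p5, p$dd_length_p95),
        control_samples = c0$n_samples,
        control_dd_length = sprintf("%g; (%g-%g)", c0$dd_length_median,
                                    c0$dd_length_p5, c0$dd_length_p95))
    }
    cols <- lapply(summaries, fmt)
    out <- data.frame(metric = names(cols[[1]]), cols,
                      check.names = FALSE)
    names(out) <- c("metric", names(summaries))
    write.table(out, tsvPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(tsv = tsvPath, json = jsonPath))
}
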
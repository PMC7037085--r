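#' Per-sample Z-score profile with signed ranks
#'
#' For one sample, holds the Z-score of every retained m/z feature and
#' the feature's rank within its sign class: positive Z-scores are
#' ranked from the maximum downwards (the highest observed Z-score gets
#' rank 1), negative Z-scores from the minimum upwards (the most
#' negative gets rank 1). Features with Z exactly 0 carry no rank and
#' never contribute to a score. Ties in Z are broken by ascending m/z,
#' then positive mode before negative, so ranking is deterministic.
#'
#' @slot sampleId sample identifier.
#' @slot features data.frame with columns `mode`, `mz`, `z`, `rank`
#'   (integer, `NA` for Z = 0) and `sign_class`
#'   ("positive"/"negative"/"zero").
#' @seealso [rankZScores()], [computeZScores()]
#' @export
setClass("RankedProfile",
  representation(sampleId = "character", features = "data.frame"),
  validity = function(object) {
    f <- object@features
    if (!all(c("mode", "mz", "z", "rank") %in% names(f)))
      return("features must have mode, mz, z, rank")
    for (cls in c(1, -1)) {
      r <- f$rank[sign(f$z) == cls]
      if (length(r) && !identical(sort(r), seq_along(r)))
        return("ranks within a sign class must be a permutation of 1..n")
    }
    if (any(!is.na(f$rank[f$z == 0])))
      return("zero Z-scores must carry no rank")
    TRUE
  })

#' @describeIn RankedProfile-class feature table accessor.
#' @param profile a `RankedProfile`.
#' @export
profileFeatures <- function(profile) profile@features

#' @describeIn RankedProfile-class sample identifier accessor.
#' @export
profileSampleId <- function(profile) profile@sampleId

setMethod("show", "RankedProfile", function(object) {
  f <- object@features
  cat("RankedProfile for", object@sampleId, "-", nrow(f), "features (",
      sum(f$z > 0), "positive /", sum(f$z < 0), "negative Z )\n")
})

#' Read a peak intensity table into a SummarizedExperiment
#'
#' TSV with columns `mode`, `mz`, then one intensity column per
#' sample-replicate named `sample_id#rep` (e.g. `P001#1`, `P001#2`);
#' a bare `sample_id` column name means a single replicate.
#'
#' @param path path to the TSV file.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `intensity`, rowData `mode`/`mz`, and colData `sample_id` and
#'   `replicate`.
#' @export
readPeakTable <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  raw <- read.delim(path, sep = "\t", check.names = FALSE,
                    fileEncoding = "UTF-8")
  if (!all(c("mode", "mz") %in% names(raw)))
    stop("peak table must have 'mode' and 'mz' columns")
  sampleCols <- setdiff(names(raw), c("mode", "mz"))
  mat <- as.matrix(raw[, sampleCols, drop = FALSE])
  storage.mode(mat) <- "double"
  peakSE(mat, raw$mode, raw$mz)
}

# assemble the standard intensity container from a matrix whose column
# names follow the sample_id#rep convention
peakSE <- function(mat, mode, mz, assayName = "intensity") {
  parts <- strsplit(colnames(mat), "#", fixed = TRUE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = setNames(list(mat), assayName),
    rowData = S4Vectors::DataFrame(mode = mode, mz = mz),
    colData = S4Vectors::DataFrame(
      sample_id = vapply(parts, `[`, "", 1L),
      replicate = vapply(parts, function(p)
        if (length(p) > 1L) p[2L] else "1", ""),
      row.names = colnames(mat)))
  se
}

#' Aggregate technical replicates to one intensity per sample
#'
#' DI-HRMS samples are typically infused in technical triplicate; the
#' per-sample intensity is the arithmetic mean of the replicates
#' (default) or their median. Missing replicate values are dropped
#' per feature; a feature with all replicates missing becomes `NA` for
#' that sample.
#'
#' @param se a SummarizedExperiment from [readPeakTable()] (assay
#'   `intensity`, colData `sample_id`).
#' @param method "mean" (default) or "median".
#' @return a SummarizedExperiment with one column per sample.
#' @examples
#' # three replicates 9, 10, 11 average to 10
#' @export
aggregateReplicates <- function(se, method = c("mean", "median")) {
  method <- match.arg(method)
  fun <- if (method == "mean") function(x) mean(x, na.rm = TRUE) else
    function(x) median(x, na.rm = TRUE)
  ids <- SummarizedExperiment::colData(se)$sample_id
  mat <- SummarizedExperiment::assay(se)
  samples <- unique(ids)
  agg <- vapply(samples, function(s)
    apply(mat[, ids == s, drop = FALSE], 1L, fun), numeric(nrow(mat)))
  agg <- matrix(agg, nrow = nrow(mat), dimnames = list(NULL, samples))
  agg[is.nan(agg)] <- NA_real_
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = agg),
    rowData = SummarizedExperiment::rowData(se),
    colData = S4Vectors::DataFrame(sample_id = samples,
                                   row.names = samples))
  out
}

#' Z-scores of every sample against the control cohort
#'
#' Per feature, `Z = (x - mean(controls)) / sd(controls)` with the
#' sample standard deviation (n-1 denominator) over the control
#' samples of the same batch. Z-scores are computed for control samples
#' too, so control DDs can be evaluated. Features whose control
#' standard deviation is zero (or with missing control values) are
#' excluded from the batch with a warning and recorded in
#' `metadata(result)$dropped_features`.
#'
#' @param se a SummarizedExperiment of per-sample intensities
#'   ([aggregateReplicates()] output).
#' @param controlIds character vector of control sample ids.
#' @param minControls minimum number of controls required (default 3).
#' @return a SummarizedExperiment with assay `z`, rowData `mode`/`mz`
#'   and colData flag `is_control`.
#' @export
computeZScores <- function(se, controlIds, minControls = 3) {
  ids <- colnames(se)
  if (!all(controlIds %in% ids))
    stop("control ids absent from matrix: ",
         paste(setdiff(controlIds, ids), collapse = ", "))
  if (length(controlIds) < minControls)
    stop("need at least ", minControls, " control samples, got ",
         length(controlIds))
  mat <- SummarizedExperiment::assay(se)
  ctl <- mat[, controlIds, drop = FALSE]
  mu <- rowMeans(ctl)
  sdev <- apply(ctl, 1L, sd)
  bad <- !is.finite(sdev) | sdev == 0 | !is.finite(mu)
  if (any(bad))
    warning(sum(bad), " feature(s) with zero/undefined control spread ",
            "excluded from this batch")
  z <- (mat[!bad, , drop = FALSE] - mu[!bad]) / sdev[!bad]
  rd <- SummarizedExperiment::rowData(se)
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(z = z),
    rowData = rd[!bad, , drop = FALSE],
    colData = S4Vectors::DataFrame(sample_id = ids,
                                   is_control = ids %in% controlIds,
                                   row.names = ids))
  S4Vectors::metadata(out)$dropped_features <-
    as.data.frame(rd[bad, , drop = FALSE])
  out
}

#' Read a precomputed Z-score matrix
#'
#' Accepts a TSV with columns `mode`, `mz` and one Z-score column per
#' sample, bypassing intensity aggregation and Z-scoring — the entry
#' point for externally computed Z-score result files.
#'
#' @param path path to the TSV file.
#' @param controlIds optional character vector marking which columns
#'   are controls.
#' @return a SummarizedExperiment with assay `z`.
#' @export
readZMatrix <- function(path, controlIds = character()) {
  if (!file.exists(path)) stop("Z-matrix not found: ", path)
  raw <- read.delim(path, sep = "\t", check.names = FALSE,
                    fileEncoding = "UTF-8")
  if (!all(c("mode", "mz") %in% names(raw)))
    stop("Z-matrix must have 'mode' and 'mz' columns")
  sampleCols <- setdiff(names(raw), c("mode", "mz"))
  mat <- as.matrix(raw[, sampleCols, drop = FALSE])
  storage.mode(mat) <- "double"
  SummarizedExperiment::SummarizedExperiment(
    assays = list(z = mat),
    rowData = S4Vectors::DataFrame(mode = raw$mode, mz = raw$mz),
    colData = S4Vectors::DataFrame(
      sample_id = sampleCols,
      is_control = sampleCols %in% controlIds,
      row.names = sampleCols))
}

# deterministic ordering inside one sign class: extreme Z first, ties
# by ascending m/z, then positive mode before negative
rankWithin <- function(z, mz, mode, decreasing) {
  modeOrd <- match(mode, MODE_LEVELS)
  ord <- order(if (decreasing) -z else z, mz, modeOrd)
  rank <- integer(length(z))
  rank[ord] <- seq_along(ord)
  rank
}

#' Assign signed ranks to a sample's Z-scores
#'
#' Positive Z-scores are ranked 1..n_pos from the maximum down; negative
#' Z-scores are ranked 1..n_neg from the minimum up; zero Z-scores get
#' `NA`. See [RankedProfile-class] for the tie rule.
#'
#' @param z numeric vector of Z-scores (one per feature).
#' @param mode,mz feature coordinates, same length as `z`.
#' @param sampleId sample identifier stored in the result.
#' @return a [RankedProfile-class].
#' @examples
#' p <- rankZScores(c(3.2, -2.5, 1.1, -0.4), rep("positive", 4),
#'                  c(100, 200, 300, 400), "S1")
#' profileFeatures(p)$rank  # 1, 1, 2, 2
#' @export
rankZScores <- function(z, mode, mz, sampleId = "sample") {
  stopifnot(length(z) == length(mode), length(z) == length(mz))
  keep <- is.finite(z)
  z <- z[keep]; mode <- mode[keep]; mz <- mz[keep]
  rank <- rep(NA_integer_, length(z))
  pos <- z > 0; neg <- z < 0
  if (any(pos))
    rank[pos] <- rankWithin(z[pos], mz[pos], mode[pos], TRUE)
  if (any(neg))
    rank[neg] <- rankWithin(z[neg], mz[neg], mode[neg], FALSE)
  new("RankedProfile", sampleId = sampleId,
      features = data.frame(
        mode = mode, mz = mz, z = z, rank = rank,
        sign_class = c("negative", "zero", "positive")[sign(z) + 2],
        stringsAsFactors = FALSE))
}

#' Ranked profiles for every sample of a Z-score matrix
#'
#' @param zse a SummarizedExperiment with assay `z` (from
#'   [computeZScores()] or [readZMatrix()]).
#' @return named list of [RankedProfile-class], one per sample.
#' @export
rankedProfiles <- function(zse) {
  rd <- SummarizedExperiment::rowData(zse)
  z <- SummarizedExperiment::assay(zse, "z")
  setNames(lapply(colnames(zse), function(s)
    rankZScores(z[, s], rd$mode, rd$mz, s)), colnames(zse))
}
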
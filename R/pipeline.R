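#' Run the full scoring pipeline on an intensity cohort
#'
#' Convenience wrapper chaining replicate aggregation, Z-scoring
#' against the controls, peak annotation, signed ranking and
#' per-sample DD construction.
#'
#' @param se SummarizedExperiment of replicate intensities
#'   ([readPeakTable()] / [simulateCohort()]).
#' @param massTable metabolite mass table ([readMassTable()]).
#' @param lib an [ExpectedLibrary-class].
#' @param controlIds character vector of control sample ids.
#' @param tolerancePpm annotation tolerance in ppm (default 2).
#' @param gates a [GateThresholds-class].
#' @param mzRange scan range for annotation (default `c(70, 600)`).
#' @param endogenousOnly restrict annotation to endogenous metabolites.
#' @param aggregate replicate aggregation method ("mean"/"median").
#' @param minControls minimum control count for Z-scoring.
#' @return named list of [DifferentialDiagnosis-class], one per sample
#'   (controls included), with the Z-score SummarizedExperiment in
#'   attribute `"zse"`.
#' @export
scoreCohort <- function(se, massTable, lib, controlIds,
                        tolerancePpm = 2, gates = gateThresholds(),
                        mzRange = c(70, 600), endogenousOnly = TRUE,
                        aggregate = "mean", minControls = 3) {
  agg <- aggregateReplicates(se, aggregate)
  zse <- computeZScores(agg, controlIds, minControls)
  dds <- scoreZMatrix(zse, massTable, lib, tolerancePpm, gates,
                      mzRange, endogenousOnly)
  attr(dds, "zse") <- zse
  dds
}

#' Run annotation + scoring on a precomputed Z-score matrix
#'
#' Entry point for externally computed Z-scores ([readZMatrix()]):
#' skips aggregation and Z-scoring.
#'
#' @param zse SummarizedExperiment with assay `z`.
#' @inheritParams scoreCohort
#' @return named list of [DifferentialDiagnosis-class].
#' @export
scoreZMatrix <- function(zse, massTable, lib, tolerancePpm = 2,
                         gates = gateThresholds(), mzRange = c(70, 600),
                         endogenousOnly = TRUE) {
  idx <- buildMassIndex(massTable, tolerancePpm = tolerancePpm,
                        endogenousOnly = endogenousOnly)
  rd <- SummarizedExperiment::rowData(zse)
  annotated <- annotatePeaks(data.frame(mode = rd$mode, mz = rd$mz),
                             idx, mzRange)
  annot <- annotationTable(annotated)
  profs <- rankedProfiles(zse)
  lapply(profs, function(p) buildDD(lib, p, annot, gates))
}
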
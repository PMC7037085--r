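#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by [simulateReference()] and
#' [simulateCohort()]: a mass table of metabolites with well-separated
#' masses (plus optional deliberate isomer collisions), an expected
#' library assigning signature metabolites to synthetic diseases, and a
#' cohort of log-normal control intensities with patient samples whose
#' signature metabolites are spiked up or down to a target Z-score.
#'
#' @param nMetabolites number of metabolites in the mass table.
#' @param nIem number of synthetic diseases.
#' @param entriesPerIem length-2 integer range of library entries per
#'   disease.
#' @param nControls number of control samples (>= 3).
#' @param nPatients number of patient samples (one disease each).
#' @param effectSizeZ target |Z| of spiked signature metabolites
#'   (>= 0; 0 makes patients generatively identical to controls).
#' @param directionMix probability that a library entry expects an
#'   increase (default 0.8: curated libraries are dominated by
#'   accumulating substrates).
#' @param fractionCritical probability that an entry is marked
#'   critical (default 0.25).
#' @param isomerFraction fraction of metabolites involved in deliberate
#'   exact-mass isomer pairs (default 0).
#' @param noiseCv coefficient of variation of technical replicate
#'   noise (default 0.1).
#' @param controlCv biological + analytical coefficient of variation
#'   of control intensities per feature (default 0.2).
#' @param nReplicates technical replicates per sample (default 3,
#'   mirroring triplicate infusion).
#' @param seed integer seed fixing the full random stream.
#' @return a validated list of class `SimulationConfig`.
#' @export
simConfig <- function(nMetabolites = 60, nIem = 12,
                      entriesPerIem = c(2, 5), nControls = 30,
                      nPatients = 60, effectSizeZ = 8,
                      directionMix = 0.8, fractionCritical = 0.25,
                      isomerFraction = 0, noiseCv = 0.1,
                      controlCv = 0.2, nReplicates = 3, seed = 1) {
  cfg <- list(nMetabolites = as.integer(nMetabolites),
              nIem = as.integer(nIem),
              entriesPerIem = as.integer(entriesPerIem),
              nControls = as.integer(nControls),
              nPatients = as.integer(nPatients),
              effectSizeZ = effectSizeZ, directionMix = directionMix,
              fractionCritical = fractionCritical,
              isomerFraction = isomerFraction, noiseCv = noiseCv,
              controlCv = controlCv,
              nReplicates = as.integer(nReplicates),
              seed = as.integer(seed))
  stopifnot(cfg$nControls >= 3, cfg$effectSizeZ >= 0,
            length(cfg$entriesPerIem) == 2,
            cfg$entriesPerIem[1] >= 1,
            cfg$entriesPerIem[2] >= cfg$entriesPerIem[1],
            cfg$directionMix >= 0, cfg$directionMix <= 1,
            cfg$isomerFraction >= 0, cfg$isomerFraction < 1,
            cfg$noiseCv > 0, cfg$controlCv > 0,
            cfg$nMetabolites >= cfg$nIem * cfg$entriesPerIem[2])
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a mass table and expected library with known ground truth
#'
#' Metabolite masses are drawn from a 10-ppm-spaced log grid over
#' [71, 599] Da with sub-ppm jitter, so all pairwise gaps exceed 3 ppm
#' (well clear of the 2 ppm annotation window) except for the requested
#' fraction of deliberate isomer pairs, which share a mass exactly.
#' Each disease receives `entriesPerIem` signature metabolites,
#' disjoint across diseases, with direction / fluid / role / importance
#' drawn per the configuration; a disease with a single entry has it
#' flagged as the only known biomarker.
#'
#' @param config a [simConfig()] object.
#' @return list with elements `massTable` (data.frame as from
#'   [readMassTable()]) and `library` (an [ExpectedLibrary-class]).
#' @export
simulateReference <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  ratio <- 1 + 1e-5   # 10 ppm grid spacing
  nGrid <- floor(log(599 / 71) / log(ratio))
  nIso <- floor(config$isomerFraction * config$nMetabolites / 2)
  nBase <- config$nMetabolites - nIso
  if (nBase > nGrid)
    stop("cannot place ", nBase, " metabolites at > 3 ppm spacing")
  mass <- 71 * ratio^sort(sample.int(nGrid, nBase))
  mass <- mass * (1 + runif(nBase, -5e-7, 5e-7))  # keeps gaps > 9 ppm
  hmdb <- sprintf("SYN%07d", seq_len(config$nMetabolites))
  isoOf <- sample.int(nBase, nIso)
  massTable <- data.frame(
    hmdb_id = hmdb,
    name = paste("synthetic metabolite", seq_len(config$nMetabolites)),
    monoisotopic_mass = c(mass, mass[isoOf]),
    endogenous = TRUE, stringsAsFactors = FALSE)

  nEntries <- sample(seq(config$entriesPerIem[1],
                         config$entriesPerIem[2]),
                     config$nIem, replace = TRUE)
  picks <- sample(hmdb, sum(nEntries))
  iemIds <- sprintf("IEM%03d", seq_len(config$nIem))
  entries <- data.frame(
    iem_id = rep(iemIds, nEntries),
    hmdb_id = picks, stringsAsFactors = FALSE)
  mt <- match(entries$hmdb_id, massTable$hmdb_id)
  entries$metabolite_name <- massTable$name[mt]
  entries$mz <- massTable$monoisotopic_mass[mt]
  entries$direction <- ifelse(runif(nrow(entries)) < config$directionMix,
                              "increase", "decrease")
  entries$fluid <- sample(FLUID_LEVELS, nrow(entries), replace = TRUE,
                          prob = c(0.55, 0.2, 0.1, 0.15))
  entries$role <- sample(ROLE_LEVELS, nrow(entries), replace = TRUE)
  entries$only_biomarker <- rep(nEntries == 1L, nEntries)
  u <- runif(nrow(entries))
  entries$importance <- ifelse(u < config$fractionCritical, "critical",
                        ifelse(u < (1 + config$fractionCritical) / 2,
                               "important", "supportive"))
  dupMass <- massTable$monoisotopic_mass[
    duplicated(massTable$monoisotopic_mass) |
    duplicated(massTable$monoisotopic_mass, fromLast = TRUE)]
  entries$has_endogenous_isomers <- entries$mz %in% dupMass
  entries$isomer_names <- ""
  diseases <- data.frame(
    iem_id = iemIds,
    name = sprintf("synthetic disorder %03d", seq_len(config$nIem)),
    is_condition = FALSE, stringsAsFactors = FALSE)
  list(massTable = massTable,
       library = expectedLibrary(diseases, entries))
}

#' Simulate a control/patient intensity cohort
#'
#' Control intensities per feature are log-normal with a
#' feature-specific location (mean intensity log-uniform over 1e4-1e6
#' arbitrary units) and coefficient of variation `controlCv`. Every
#' metabolite produces one feature per ionization mode
#' (m/z = mass +/- 1.007276 Da). Each patient is assigned one disease
#' and the intensities of all its signature metabolites are multiplied
#' by `k = 1 + z * cv_total` (expected-increase entries, `z =
#' effectSizeZ`) or `k = max(1 - z * cv_total, 0.02)`
#' (expected-decrease entries), where `cv_total` is the total
#' coefficient of variation of a replicate-averaged control intensity —
#' so the expected observed Z of a spiked feature equals the target.
#' Decrease targets beyond the attainable range of a positive intensity
#' clamp near zero. Technical replicates add mean-one multiplicative
#' log-normal noise at `noiseCv`.
#'
#' @param config a [simConfig()] object.
#' @param ref output of [simulateReference()] (or a list with
#'   `massTable` and `library`).
#' @return list with `se` (SummarizedExperiment of replicate
#'   intensities, columns `sample#rep`), `truth` (truth manifest
#'   data.frame) and `controlIds`.
#' @export
simulateCohort <- function(config, ref = simulateReference(config)) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  massTable <- ref$massTable
  lib <- ref$library
  nMet <- nrow(massTable)
  mode <- rep(MODE_LEVELS, each = nMet)
  mz <- c(massTable$monoisotopic_mass + PROTON_MASS,
          massTable$monoisotopic_mass - PROTON_MASS)
  featHmdb <- rep(massTable$hmdb_id, 2)
  nFeat <- 2L * nMet

  meanI <- 10^runif(nFeat, 4, 6)
  tau <- sqrt(log(1 + config$controlCv^2))
  mu <- log(meanI) - tau^2 / 2
  sNoise <- sqrt(log(1 + config$noiseCv^2))
  cvTot <- sqrt((1 + config$controlCv^2) *
                (1 + config$noiseCv^2 / config$nReplicates) - 1)

  controls <- sprintf("C%03d", seq_len(config$nControls))
  patients <- sprintf("P%03d", seq_len(config$nPatients))
  assigned <- sample(lib@diseases$iem_id, config$nPatients,
                     replace = TRUE)
  samples <- c(controls, patients)
  nS <- length(samples)

  base <- matrix(rlnorm(nFeat * nS, mu, tau), nrow = nFeat)
  entries <- lib@entries
  for (j in seq_along(patients)) {
    sig <- entries[entries$iem_id == assigned[j], ]
    for (i in seq_len(nrow(sig))) {
      k <- if (sig$direction[i] == "increase")
        1 + config$effectSizeZ * cvTot else
        max(1 - config$effectSizeZ * cvTot, 0.02)
      rows <- which(featHmdb == sig$hmdb_id[i])
      base[rows, config$nControls + j] <-
        base[rows, config$nControls + j] * k
    }
  }

  reps <- lapply(seq_len(config$nReplicates), function(r)
    base * matrix(rlnorm(nFeat * nS, -sNoise^2 / 2, sNoise),
                  nrow = nFeat))
  mat <- do.call(cbind, reps)
  colnames(mat) <- paste0(rep(samples, config$nReplicates), "#",
                          rep(seq_len(config$nReplicates), each = nS))
  ord <- order(rep(seq_len(nS), config$nReplicates))
  mat <- mat[, ord, drop = FALSE]

  truth <- data.frame(
    sample_id = samples,
    patient_id = samples,
    set = "simulated", matrix = "plasma",
    true_iem_id = c(rep("", config$nControls), assigned),
    stringsAsFactors = FALSE)
  list(se = peakSE(mat, mode, mz), truth = truth,
       controlIds = controls)
}
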
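#' Critical-metabolite gate thresholds
#'
#' A library entry marked `critical` is indispensable for its diagnosis.
#' After the probability score is computed, a disease is gated out
#' (score set to exactly 0) when any critical entry expected increased
#' was not found increased (observed Z < `zIncreaseMin`) or any critical
#' entry expected decreased was not found decreased (observed Z >
#' `zDecreaseMax`). A critical entry with no observable feature at all
#' also fails its gate: an unmeasured indispensable marker cannot
#' support inclusion. The thresholds are inclusive of the surviving
#' side: Z exactly 1.6 passes the increase gate, Z exactly -1.2 passes
#' the decrease gate.
#'
#' @slot zIncreaseMin minimum Z for an expected increase to count as
#'   observed (default 1.6).
#' @slot zDecreaseMax maximum Z for an expected decrease to count as
#'   observed (default -1.2).
#' @include library.R profile.R
#' @export
setClass("GateThresholds",
  representation(zIncreaseMin = "numeric", zDecreaseMax = "numeric"),
  prototype(zIncreaseMin = 1.6, zDecreaseMax = -1.2),
  validity = function(object) {
    if (!(object@zIncreaseMin > 0 && object@zDecreaseMax < 0))
      return("need zIncreaseMin > 0 > zDecreaseMax")
    TRUE
  })

#' @rdname GateThresholds-class
#' @param ... named overrides of the slots.
#' @export
gateThresholds <- function(...) new("GateThresholds", ...)

#' Probability score of one disease for one sample
#'
#' Carries the score, gate status and classification, plus the full
#' per-entry decomposition so a reviewer can see exactly which observed
#' metabolite contributed how much — the plain-data replacement for an
#' interactive score inspector.
#'
#' @slot iemId disease identifier.
#' @slot probabilityScore the summed score (0 when gated).
#' @slot ungatedScore the sum before gating (equal to
#'   `probabilityScore` when not gated).
#' @slot gated `TRUE` when a critical entry failed its gate.
#' @slot gateReasons data.frame (`hmdb_id`, `rule`, `z`) of the failing
#'   critical entries.
#' @slot classification one of very_likely / likely / possible /
#'   unlikely / very_unlikely.
#' @slot contributions data.frame, one row per library entry of the
#'   disease: `hmdb_id`, `mode`, `mz`, `weight`, `z`, `rank`,
#'   `metabolite_score`, `product`, `observed`, `counted` (FALSE for
#'   entries deduplicated away or unobserved).
#' @export
setClass("DiagnosisScore",
  representation(iemId = "character", probabilityScore = "numeric",
                 ungatedScore = "numeric", gated = "logical",
                 gateReasons = "data.frame", classification = "character",
                 contributions = "data.frame"),
  validity = function(object) {
    if (object@gated && object@probabilityScore != 0)
      return("gated scores must be exactly 0")
    TRUE
  })

#' Ranked differential diagnosis for one sample
#'
#' @slot sampleId sample identifier.
#' @slot dd data.frame of the differential diagnosis: every disease
#'   with probability score > 1, sorted by descending score (ties by
#'   disease name); columns `dd_rank`, `iem_id`, `name`, `score`,
#'   `classification`.
#' @slot scores data.frame of all diseases (`iem_id`, `name`, `score`,
#'   `ungated_score`, `gated`, `classification`).
#' @slot results named list of [DiagnosisScore-class], one per disease.
#' @export
setClass("DifferentialDiagnosis",
  representation(sampleId = "character", dd = "data.frame",
                 scores = "data.frame", results = "list"))

#' Metabolite score from Z-score and rank
#'
#' `Z / (rank * 0.9)`: the Z-score attenuated by the feature's rank
#' within its sign class, the rank being weighted slightly less than
#' the Z-score itself (hence the 0.9).
#'
#' @param z Z-score(s).
#' @param rank positive integer rank(s) within the sign class.
#' @param rankFactor the attenuation constant (default 0.9).
#' @return numeric, `z / (rank * rankFactor)`.
#' @examples
#' metaboliteScore(2.95, 3)    #  1.0926
#' metaboliteScore(-1.64, 24)  # -0.0759
#' @export
metaboliteScore <- function(z, rank, rankFactor = 0.9) {
  if (any(rank < 1, na.rm = TRUE)) stop("rank must be >= 1")
  z / (rank * rankFactor)
}

#' Resolve library entries to observed features
#'
#' Joins each entry's `hmdb_id` to the annotated features of a sample's
#' profile. When a metabolite is annotated to features in both
#' ionization modes, the feature with the larger |Z| is used (ties by
#' ascending m/z, positive mode first). Entries whose metabolite is not
#' carried by any annotated feature are returned with `observed =
#' FALSE`.
#'
#' @param entries library entry data.frame (needs `hmdb_id`).
#' @param profile a [RankedProfile-class].
#' @param annotations long annotation table from [annotationTable()].
#' @return data.frame aligned with `entries`: `observed`, `mode`, `mz`,
#'   `z`, `rank`.
#' @export
resolveObservations <- function(entries, profile, annotations) {
  f <- profileFeatures(profile)
  fkey <- paste(f$mode, f$mz)
  idx <- match(paste(annotations$mode, annotations$mz), fkey)
  ok <- !is.na(idx)
  byHmdb <- split(idx[ok], annotations$hmdb_id[ok])
  n <- nrow(entries)
  out <- data.frame(observed = logical(n), mode = NA_character_,
                    mz = NA_real_, z = NA_real_, rank = NA_integer_)
  for (i in seq_len(n)) {
    cands <- unique(byHmdb[[entries$hmdb_id[i]]])
    if (is.null(cands) || !length(cands)) next
    best <- cands[order(-abs(f$z[cands]), f$mz[cands],
                        match(f$mode[cands], MODE_LEVELS))][1L]
    out$observed[i] <- TRUE
    out$mode[i] <- f$mode[best]
    out$mz[i] <- f$mz[best]
    out$z[i] <- f$z[best]
    out$rank[i] <- f$rank[best]
  }
  out
}

#' Classify a probability score into a likelihood bin
#'
#' Bins (lower-exclusive, upper-inclusive, so every score maps to
#' exactly one class): score > 50 very_likely; 10 < score <= 50 likely;
#' 1 < score <= 10 possible; 0 < score <= 1 unlikely; score <= 0
#' very_unlikely. The DD comprises the classes above score 1
#' (very_likely, likely, possible).
#'
#' @param score numeric vector of probability scores.
#' @return character vector of classifications.
#' @examples
#' classifyScore(c(55, 20, 5, 0.5, -3))
#' @export
classifyScore <- function(score) {
  stopifnot(all(is.finite(score)))
  as.character(cut(score, c(-Inf, 0, 1, 10, 50, Inf),
                   labels = CLASS_LEVELS, right = TRUE))
}

# scoring engine for one disease; entries/resolved already restricted
# to that disease, weights precomputed
scoreOneDisease <- function(iemId, entries, resolved, weights, gates,
                            rankFactor = 0.9) {
  mscore <- rep(0, nrow(entries))
  has <- resolved$observed & !is.na(resolved$rank)
  mscore[has] <- metaboliteScore(resolved$z[has], resolved$rank[has],
                                 rankFactor)
  # "unique m/z": several entries of one disease resolving to the same
  # observed feature (isomer masking) must not double-count it; keep
  # the entry with the largest |weight|, ties by hmdb_id
  counted <- resolved$observed
  if (any(resolved$observed)) {
    obs <- which(resolved$observed)
    featKey <- paste(resolved$mode[obs], resolved$mz[obs])
    keepOrd <- obs[order(featKey, -abs(weights[obs]),
                         entries$hmdb_id[obs])]
    dupped <- keepOrd[duplicated(paste(resolved$mode[keepOrd],
                                       resolved$mz[keepOrd]))]
    counted[dupped] <- FALSE
  }
  product <- weights * mscore
  score <- sum(product[counted])

  crit <- which(entries$importance == "critical")
  failInc <- crit[entries$direction[crit] == "increase" &
    (!resolved$observed[crit] |
     !(resolved$z[crit] >= gates@zIncreaseMin))]
  failDec <- crit[entries$direction[crit] == "decrease" &
    (!resolved$observed[crit] |
     !(resolved$z[crit] <= gates@zDecreaseMax))]
  gated <- length(failInc) + length(failDec) > 0
  gateReasons <- data.frame(
    hmdb_id = entries$hmdb_id[c(failInc, failDec)],
    rule = c(rep("critical_increase_not_observed", length(failInc)),
             rep("critical_decrease_not_observed", length(failDec))),
    z = resolved$z[c(failInc, failDec)])

  contributions <- data.frame(
    hmdb_id = entries$hmdb_id, mode = resolved$mode, mz = resolved$mz,
    weight = weights, z = resolved$z, rank = resolved$rank,
    metabolite_score = mscore, product = product,
    observed = resolved$observed, counted = counted)
  finalScore <- if (gated) 0 else score
  new("DiagnosisScore", iemId = iemId, probabilityScore = finalScore,
      ungatedScore = score, gated = gated, gateReasons = gateReasons,
      classification = classifyScore(finalScore),
      contributions = contributions)
}

#' Probability score of one disease for one sample
#'
#' Sums, over the disease's library entries deduplicated to unique
#' observed m/z features, the product of the entry's weight score and
#' the feature's metabolite score `Z/(rank * 0.9)`; entries with no
#' observable feature contribute 0. Critical-metabolite gating then
#' zeroes the score when any indispensable alteration is absent (see
#' [GateThresholds-class]). The per-entry decomposition is retained
#' even when gated.
#'
#' @param iemId disease identifier present in `lib`.
#' @param lib an [ExpectedLibrary-class].
#' @param profile a [RankedProfile-class] for the sample.
#' @param annotations long annotation table ([annotationTable()]).
#' @param gates a [GateThresholds-class].
#' @param rankFactor rank attenuation constant (default 0.9).
#' @return a [DiagnosisScore-class].
#' @export
iemProbability <- function(iemId, lib, profile, annotations,
                           gates = gateThresholds(), rankFactor = 0.9) {
  stopifnot(is(lib, "ExpectedLibrary"), is(profile, "RankedProfile"))
  if (!iemId %in% lib@diseases$iem_id)
    stop("unknown iem_id: ", iemId)
  entries <- lib@entries[lib@entries$iem_id == iemId, , drop = FALSE]
  resolved <- resolveObservations(entries, profile, annotations)
  weights <- weightScore(entries, lib@weightConfig)
  scoreOneDisease(iemId, entries, resolved, weights, gates, rankFactor)
}

#' Differential diagnosis for one sample
#'
#' Scores every disease and condition in the library against the
#' sample's ranked Z-score profile and keeps those with probability
#' score > 1 (the very_likely / likely / possible classes), sorted by
#' descending score with ties broken alphabetically by disease name.
#' Conditions and interferences (`is_condition = TRUE`) are scored and
#' listed identically to IEM.
#'
#' @inheritParams iemProbability
#' @param profile a [RankedProfile-class]; its sample id names the DD.
#' @return a [DifferentialDiagnosis-class].
#' @export
buildDD <- function(lib, profile, annotations, gates = gateThresholds(),
                    rankFactor = 0.9) {
  stopifnot(is(lib, "ExpectedLibrary"), is(profile, "RankedProfile"))
  d <- lib@diseases
  entries <- lib@entries
  resolvedAll <- resolveObservations(entries, profile, annotations)
  weightsAll <- weightScore(entries, lib@weightConfig)
  results <- lapply(d$iem_id, function(id) {
    sel <- entries$iem_id == id
    scoreOneDisease(id, entries[sel, , drop = FALSE],
                    resolvedAll[sel, , drop = FALSE], weightsAll[sel],
                    gates, rankFactor)
  })
  names(results) <- d$iem_id
  scores <- data.frame(
    iem_id = d$iem_id, name = d$name,
    score = vapply(results, slot, 0, "probabilityScore"),
    ungated_score = vapply(results, slot, 0, "ungatedScore"),
    gated = vapply(results, slot, FALSE, "gated"),
    classification = vapply(results, slot, "", "classification"),
    row.names = NULL)
  keep <- scores[scores$score > 1, , drop = FALSE]
  keep <- keep[order(-keep$score, keep$name), , drop = FALSE]
  dd <- data.frame(dd_rank = seq_len(nrow(keep)),
                   iem_id = keep$iem_id, name = keep$name,
                   score = keep$score,
                   classification = keep$classification,
                   row.names = NULL)
  new("DifferentialDiagnosis", sampleId = profileSampleId(profile),
      dd = dd, scores = scores, results = results)
}

#' @describeIn DifferentialDiagnosis-class the ranked DD table.
#' @param x a `DifferentialDiagnosis`.
#' @export
ddTable <- function(x) x@dd

#' @describeIn DifferentialDiagnosis-class the full score table (all
#'   diseases, including gated and sub-threshold ones).
#' @export
ddScores <- function(x) x@scores

#' @describeIn DifferentialDiagnosis-class the per-disease
#'   [DiagnosisScore-class] results.
#' @export
ddResults <- function(x) x@results

setMethod("show", "DiagnosisScore", function(object) {
  cat(sprintf("DiagnosisScore %s: %.4g (%s%s)\n", object@iemId,
              object@probabilityScore, object@classification,
              if (object@gated) ", gated" else ""))
})

setMethod("show", "DifferentialDiagnosis", function(object) {
  cat("DifferentialDiagnosis for", object@sampleId, "-",
      nrow(object@dd), "of", nrow(object@scores),
      "diseases above score 1\n")
  if (nrow(object@dd)) print(head(object@dd, 10))
})

#' Write DD reports for a set of samples
#'
#' Produces a JSON report (per sample: the ranked DD with score,
#' classification, gate flags and the per-entry score decomposition of
#' every DD member) and a flat TSV (`sample_id`, `dd_rank`, `iem_id`,
#' `score`, `classification`).
#'
#' @param dds list of [DifferentialDiagnosis-class].
#' @param jsonPath,tsvPath output paths (either may be `NULL` to skip).
#' @return invisibly, the list of paths written.
#' @export
writeDDReports <- function(dds, jsonPath = NULL, tsvPath = NULL) {
  if (!is.null(jsonPath)) {
    payload <- lapply(dds, function(x) {
      members <- lapply(seq_len(nrow(x@dd)), function(i) {
        id <- x@dd$iem_id[i]
        res <- x@results[[id]]
        out <- list(dd_rank = x@dd$dd_rank[i], iem_id = id,
                    name = x@dd$name[i], score = x@dd$score[i],
                    classification = x@dd$classification[i])
        if (!is.null(res)) {
          out$gated <- res@gated
          out$contributions <- res@contributions
        }
        out
      })
      list(sample_id = x@sampleId, dd = members)
    })
    jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", na = "null")
  }
  if (!is.null(tsvPath)) {
    flat <- do.call(rbind, lapply(dds, function(x)
      if (nrow(x@dd)) cbind(sample_id = x@sampleId,
                            x@dd[c("dd_rank", "iem_id", "score",
                                   "classification")])
      else NULL))
    if (is.null(flat))
      flat <- data.frame(sample_id = character(), dd_rank = integer(),
                         iem_id = character(), score = numeric(),
                         classification = character())
    write.table(flat, tsvPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(json = jsonPath, tsv = tsvPath))
}
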
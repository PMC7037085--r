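# independent reference implementations (deliberately naive loops and
# explicit arithmetic; they share no code with the package internals)

# all-pairs ppm annotation scan
oracleAnnotate <- function(peaks, massTable, adductShift, tolPpm) {
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    hits <- character()
    shift <- if (peaks$mode[i] == "positive") adductShift else
      -adductShift
    for (j in seq_len(nrow(massTable))) {
      theo <- massTable$monoisotopic_mass[j] + shift
      if (abs(peaks$mz[i] - theo) / theo * 1e6 <= tolPpm)
        hits <- c(hits, massTable$hmdb_id[j])
    }
    out[[i]] <- sort(hits)
  }
  out
}

# sort-based signed ranking
oracleRanks <- function(z, mode, mz) {
  modeNum <- ifelse(mode == "positive", 1, 2)
  rank <- rep(NA_integer_, length(z))
  pos <- which(z > 0)
  pos <- pos[order(-z[pos], mz[pos], modeNum[pos])]
  rank[pos] <- seq_along(pos)
  neg <- which(z < 0)
  neg <- neg[order(z[neg], mz[neg], modeNum[neg])]
  rank[neg] <- seq_along(neg)
  rank
}

# explicit per-entry weight product
oracleWeight <- function(e, cfg = list(inc = 1, dec = -1.5, ob = 5,
                                       sp = 3, other = 1, blood = 2,
                                       urine = 1, crit = 5, imp = 3,
                                       supp = 1)) {
  dirF <- if (e$direction == "increase") cfg$inc else cfg$dec
  spec <- if (e$only_biomarker) cfg$ob else
    if (e$role == "substrate_or_product") cfg$sp else cfg$other
  flu <- if (e$fluid == "urine") cfg$urine else cfg$blood
  imp <- switch(e$importance, critical = cfg$crit, important = cfg$imp,
                supportive = cfg$supp)
  dirF * spec * flu * imp
}

# naive double loop over (disease entry, feature): resolves each entry
# to its best feature, deduplicates shared features by max |weight|,
# sums weight * z/(rank*0.9), then applies the critical gates
oracleIemScore <- function(iemId, lib, profile, annot,
                           zIncMin = 1.6, zDecMax = -1.2) {
  entries <- libraryEntries(lib)
  entries <- entries[entries$iem_id == iemId, , drop = FALSE]
  feat <- profileFeatures(profile)
  n <- nrow(entries)
  obsMode <- obsKey <- rep(NA_character_, n)
  obsZ <- rep(NA_real_, n)
  obsRank <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best <- NULL
    for (j in seq_len(nrow(feat))) {
      carried <- any(annot$mode == feat$mode[j] &
                     annot$mz == feat$mz[j] &
                     annot$hmdb_id == entries$hmdb_id[i])
      if (!carried) next
      if (is.null(best)) { best <- j; next }
      better <- abs(feat$z[j]) > abs(feat$z[best]) ||
        (abs(feat$z[j]) == abs(feat$z[best]) &&
         (feat$mz[j] < feat$mz[best] ||
          (feat$mz[j] == feat$mz[best] &&
           feat$mode[j] == "positive")))
      if (better) best <- j
    }
    if (!is.null(best)) {
      obsMode[i] <- feat$mode[best]
      obsKey[i] <- paste(feat$mode[best], feat$mz[best])
      obsZ[i] <- feat$z[best]
      obsRank[i] <- feat$rank[best]
    }
  }
  w <- vapply(seq_len(n), function(i) oracleWeight(entries[i, ]), 0)
  # dedup: among entries resolved to the same feature keep max |w|
  counted <- !is.na(obsKey)
  for (k in unique(obsKey[!is.na(obsKey)])) {
    grp <- which(!is.na(obsKey) & obsKey == k)
    if (length(grp) < 2) next
    keep <- grp[order(-abs(w[grp]), entries$hmdb_id[grp])][1]
    counted[setdiff(grp, keep)] <- FALSE
  }
  score <- 0
  for (i in seq_len(n))
    if (counted[i] && !is.na(obsRank[i]) && obsZ[i] != 0)
      score <- score + w[i] * obsZ[i] / (obsRank[i] * 0.9)
  gated <- FALSE
  for (i in seq_len(n)) {
    if (entries$importance[i] != "critical") next
    if (entries$direction[i] == "increase" &&
        (is.na(obsZ[i]) || obsZ[i] < zIncMin)) gated <- TRUE
    if (entries$direction[i] == "decrease" &&
        (is.na(obsZ[i]) || obsZ[i] > zDecMax)) gated <- TRUE
  }
  list(score = if (gated) 0 else score, ungated = score,
       gated = gated)
}
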
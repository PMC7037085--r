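test_that("the metabolite score is Z/(rank * 0.9)", {
  expect_equal(metaboliteScore(2.95, 3), 2.95 / 2.7)
  expect_equal(metaboliteScore(-1.64, 24), -1.64 / 21.6)
  expect_equal(metaboliteScore(0, 17), 0)
  expect_equal(metaboliteScore(3.6, 1), 4)
  expect_error(metaboliteScore(1, 0), "rank must be >= 1")
})

test_that("classification bins match the score thresholds, boundaries inclusive below", {
  grid <- c(-3, -0.001, 0, 0.5, 1, 1.001, 5, 10, 10.5, 50, 55, 1e6)
  expect_equal(classifyScore(grid),
               c("very_unlikely", "very_unlikely", "very_unlikely",
                 "unlikely", "unlikely", "possible", "possible",
                 "possible", "likely", "likely", "very_likely",
                 "very_likely"))
})

test_that("entries resolve to the max-|Z| feature across modes", {
  p <- rankZScores(c(2.1, -0.4, 5), c("negative", "positive", "positive"),
                   c(150.1, 150.2, 300), "S1")
  annot <- data.frame(mode = c("negative", "positive", "positive"),
                      mz = c(150.1, 150.2, 300),
                      hmdb_id = c("M1", "M1", "M2"))
  entries <- rbind(entryRow(hmdb_id = "M1"), entryRow(hmdb_id = "M2"),
                   entryRow(hmdb_id = "M9"))
  res <- resolveObservations(entries, p, annot)
  expect_equal(res$observed, c(TRUE, TRUE, FALSE))
  expect_equal(res$z[1], 2.1)            # |2.1| beats |-0.4|
  expect_equal(res$mode[1], "negative")
  expect_equal(res$z[2], 5)
  expect_true(is.na(res$z[3]))
})

test_that("a one-entry library reproduces the probability score by hand", {
  # weight 50 (increase, only biomarker, plasma, critical),
  # z = 3.6 at rank 1 -> 50 * 3.6 / 0.9 = 200
  entries <- entryRow(iem_id = "D1", hmdb_id = "M1",
                      only_biomarker = TRUE, importance = "critical")
  lib <- makeLibrary(entries)
  p <- makeProfile(3.6, mz = 100)
  annot <- identityAnnotation(p, "M1")
  ds <- iemProbability("D1", lib, p, annot)
  expect_equal(ds@probabilityScore, 200)
  expect_false(ds@gated)
  expect_equal(ds@classification, "very_likely")
  expect_error(iemProbability("NOPE", lib, p, annot), "unknown iem_id")
})

test_that("critical gating zeroes the score and records the entry", {
  entries <- rbind(
    entryRow(iem_id = "D1", hmdb_id = "M1", importance = "critical"),
    entryRow(iem_id = "D1", hmdb_id = "M2", importance = "supportive"))
  lib <- makeLibrary(entries)
  annot <- data.frame(mode = "positive", mz = c(100, 101),
                      hmdb_id = c("M1", "M2"))
  gated <- iemProbability("D1", lib,
                          makeProfile(c(1.5, 8), mz = c(100, 101)), annot)
  expect_true(gated@gated)
  expect_identical(gated@probabilityScore, 0)
  expect_equal(gated@gateReasons$hmdb_id, "M1")
  expect_equal(gated@gateReasons$rule, "critical_increase_not_observed")
  expect_gt(nrow(gated@contributions), 0)  # decomposition retained

  # z exactly at the threshold survives the gate
  pass <- iemProbability("D1", lib,
                         makeProfile(c(1.6, 8), mz = c(100, 101)), annot)
  expect_false(pass@gated)
  expect_gt(pass@probabilityScore, 0)

  # decrease side: z exactly -1.2 passes, above it gates; missing gates
  entriesD <- entryRow(iem_id = "D1", hmdb_id = "M1",
                       direction = "decrease", importance = "critical")
  libD <- makeLibrary(entriesD)
  aD <- data.frame(mode = "positive", mz = 100, hmdb_id = "M1")
  expect_false(iemProbability("D1", libD, makeProfile(-1.2, mz = 100),
                              aD)@gated)
  expect_true(iemProbability("D1", libD, makeProfile(-1.1, mz = 100),
                             aD)@gated)
  missing <- iemProbability("D1", libD, makeProfile(-5, mz = 999), aD)
  expect_true(missing@gated)
})

test_that("isomer-masked entries are counted once via the max-weight entry", {
  # two entries of one disease share the same observed feature
  entries <- rbind(
    entryRow(iem_id = "D1", hmdb_id = "Mgal", role = "substrate_or_product"),
    entryRow(iem_id = "D1", hmdb_id = "Mglc", role = "other"))
  lib <- makeLibrary(entries)
  p <- makeProfile(2.7, mz = 180)
  annot <- data.frame(mode = "positive", mz = c(180, 180),
                      hmdb_id = c("Mgal", "Mglc"))
  ds <- iemProbability("D1", lib, p, annot)
  # only the substrate/product entry (weight 6) counts: 6 * 2.7/0.9 = 18
  expect_equal(ds@probabilityScore, 18)
  expect_equal(sum(ds@contributions$counted), 1)
  expect_equal(ds@contributions$hmdb_id[ds@contributions$counted],
               "Mgal")
})

test_that("expected decreases with observed negative Z contribute positively", {
  entries <- entryRow(iem_id = "D1", hmdb_id = "M1",
                      direction = "decrease")
  lib <- makeLibrary(entries)
  annot <- data.frame(mode = "positive", mz = 100, hmdb_id = "M1")
  ds <- iemProbability("D1", lib, makeProfile(-2.7, mz = 100), annot)
  # weight -3, metabolite score -3: product +9
  expect_equal(ds@probabilityScore, 9)
  expect_gt(ds@probabilityScore, 0)
})

test_that("an ungated score is monotone in the Z of an expected increase", {
  entries <- rbind(
    entryRow(iem_id = "D1", hmdb_id = "M1"),
    entryRow(iem_id = "D1", hmdb_id = "M2", direction = "decrease"))
  lib <- makeLibrary(entries)
  annot <- data.frame(mode = "positive", mz = c(100, 101),
                      hmdb_id = c("M1", "M2"))
  # hold ranks fixed: M1 is always the top positive, add a filler
  scores <- vapply(c(0.5, 1, 2, 4, 8), function(zv) {
    p <- rankZScores(c(zv, -1.5, zv / 2), rep("positive", 3),
                     c(100, 101, 102), "S")
    iemProbability("D1", lib, p, annot)@probabilityScore
  }, 0)
  expect_true(all(diff(scores) > 0))
})

test_that("the DD is exactly the score > 1 subset, sorted and tie-broken", {
  lib <- suppressMessages(readExpectedLibrary(toyLibraryPath()))
  mt <- readMassTable(toyMassTablePath())
  idx <- buildMassIndex(mt)
  # phenylalanine-increase profile: Phe high, HVA/5HIAA normal
  feats <- data.frame(
    mode = "positive",
    mz = mt$monoisotopic_mass[match(
      c("HMDB0000159", "HMDB0000158", "HMDB0000118", "HMDB0000763",
        "HMDB0000187", "HMDB0000161", "HMDB0000641"), mt$hmdb_id)] +
      1.007276)
  annot <- annotationTable(annotatePeaks(feats, idx))
  z <- c(9, -0.5, 0.2, 0.1, 0.4, 0.3, 0.6)
  p <- rankZScores(z, feats$mode, feats$mz, "patient")
  dd <- buildDD(lib, p, annot)
  tab <- ddTable(dd)
  # PKU first: its phenylalanine weight (30) is the highest
  expect_equal(tab$iem_id[1], "PKU")
  expect_true(all(c("DHPR", "DNAJC12") %in% tab$iem_id))
  # serine deficiency and galactosaemia are gated out (criticals absent)
  expect_false(any(c("SERDEF", "GALT") %in% tab$iem_id))
  all_scores <- ddScores(dd)
  expect_setequal(tab$iem_id, all_scores$iem_id[all_scores$score > 1])
  expect_true(all(diff(tab$score) <= 0))
  # DHPR and DNAJC12 hold identical scores here (same weights on the
  # shared feature set): the tie breaks alphabetically by name
  tied <- tab[tab$iem_id %in% c("DHPR", "DNAJC12"), ]
  if (nrow(tied) == 2 && tied$score[1] == tied$score[2])
    expect_equal(tied$iem_id, c("DHPR", "DNAJC12"))

  # an empty DD when nothing scores above 1
  flat <- rankZScores(rep(0.01, 7), feats$mode, feats$mz, "flat")
  expect_equal(nrow(ddTable(buildDD(lib, flat, annot))), 0)
})

test_that("iemProbability equals the naive double-loop oracle on random instances", {
  for (seed in 1:40) {
    inst <- randomScoringInstance(seed)
    for (id in libraryDiseases(inst$lib)$iem_id) {
      got <- iemProbability(id, inst$lib, inst$profile, inst$annot)
      want <- oracleIemScore(id, inst$lib, inst$profile, inst$annot)
      expect_equal(got@probabilityScore, want$score, tolerance = 1e-12)
      expect_equal(got@gated, want$gated)
    }
  }
})

test_that("removing the critical flag restores the ungated sum", {
  nGated <- 0
  for (seed in 41:60) {
    inst <- randomScoringInstance(seed)
    entries <- libraryEntries(inst$lib)
    # restrict importance to {critical, supportive} so flipping
    # critical -> important (with wImportant pinned to the critical
    # factor) changes gating only, never any weight
    entries$importance <- ifelse(entries$importance == "critical",
                                 "critical", "supportive")
    lib <- expectedLibrary(libraryDiseases(inst$lib), entries)
    for (id in libraryDiseases(lib)$iem_id) {
      ds <- iemProbability(id, lib, inst$profile, inst$annot)
      if (!ds@gated) next
      nGated <- nGated + 1
      expect_identical(ds@probabilityScore, 0)
      e2 <- entries
      e2$importance[e2$importance == "critical"] <- "important"
      lib2 <- expectedLibrary(libraryDiseases(lib), e2,
                              weightConfig(wImportant = 5))
      ds2 <- iemProbability(id, lib2, inst$profile, inst$annot)
      expect_false(ds2@gated)
      expect_equal(ds2@probabilityScore, ds@ungatedScore)
    }
  }
  expect_gt(nGated, 10)  # the property was actually exercised
})
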
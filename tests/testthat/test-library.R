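test_that("weight scores are the product of the four stated factors", {
  cases <- list(
    # direction, role, only_biomarker, fluid, importance, expected
    list(entryRow(direction = "increase", only_biomarker = TRUE,
                  fluid = "plasma", importance = "critical"), 50),
    list(entryRow(direction = "decrease", role = "substrate_or_product",
                  fluid = "urine", importance = "supportive"), -4.5),
    list(entryRow(direction = "decrease", only_biomarker = TRUE,
                  fluid = "dbs", importance = "critical"), -75),
    list(entryRow(direction = "increase", role = "other",
                  fluid = "csf", importance = "important"), 6),
    list(entryRow(direction = "increase", role = "other",
                  fluid = "urine", importance = "supportive"), 1))
  for (c in cases)
    expect_equal(weightScore(c[[1]]), c[[2]])
})

test_that("weight magnitudes span exactly the factor products, max 75, max positive 50", {
  grid <- expand.grid(direction = c("increase", "decrease"),
                      role = c("substrate_or_product", "other"),
                      only_biomarker = c(TRUE, FALSE),
                      fluid = c("plasma", "dbs", "csf", "urine"),
                      importance = c("critical", "important",
                                     "supportive"),
                      stringsAsFactors = FALSE)
  w <- weightScore(grid)
  expected <- sort(unique(c(outer(c(1, 1.5),
                    c(outer(c(1, 3, 5), c(outer(c(1, 2), c(1, 3, 5)))))))))
  expect_setequal(unique(abs(w)), expected)
  expect_equal(max(abs(w)), 75)
  expect_equal(max(w), 50)
  # independent per-row oracle over the whole grid
  expect_equal(w, vapply(seq_len(nrow(grid)), function(i)
    oracleWeight(grid[i, ]), 0))
})

test_that("weight score is multiplicative in each config factor", {
  grid <- expand.grid(direction = c("increase", "decrease"),
                      role = c("substrate_or_product", "other"),
                      only_biomarker = c(TRUE, FALSE),
                      fluid = c("plasma", "urine"),
                      importance = c("critical", "supportive"),
                      stringsAsFactors = FALSE)
  base <- weightScore(grid)
  doubled <- weightConfig(wCritical = 10)
  w2 <- weightScore(grid, doubled)
  crit <- grid$importance == "critical"
  expect_equal(w2[crit], 2 * base[crit])
  expect_equal(w2[!crit], base[!crit])
  # specificity precedence: only-biomarker uses 5 even for
  # substrates/products, never 15
  both <- entryRow(only_biomarker = TRUE, role = "substrate_or_product",
                   importance = "supportive")
  expect_equal(weightScore(both), 1 * 5 * 2 * 1)
})

test_that("the toy library loads with counts, order and types preserved", {
  expect_message(lib <- readExpectedLibrary(toyLibraryPath()),
                 "12 entries.*8 unique metabolites.*6 diseases")
  e <- libraryEntries(lib)
  d <- libraryDiseases(lib)
  expect_equal(nrow(e), 12)
  expect_equal(nrow(d), 6)
  expect_equal(e$iem_id[1:2], c("PKU", "PKU"))  # row order kept
  expect_true(is.numeric(e$mz) && all(e$mz > 0))
  expect_true(is.logical(e$only_biomarker))
  expect_equal(sum(d$is_condition), 1)
  expect_equal(d$name[d$iem_id == "GALT"], "Galactosaemia type I")
})

test_that("schema violations are reported with column and line", {
  lib <- suppressMessages(readExpectedLibrary(toyLibraryPath()))
  tmp <- withr::local_tempfile(fileext = ".tsv")

  # invalid enum value names the allowed set and the line
  raw <- read.delim(toyLibraryPath(), check.names = FALSE)
  raw$direction[3] <- "elevated"
  write.table(raw, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(readExpectedLibrary(tmp)),
               "direction.*elevated.*line 4.*increase, decrease")

  # missing mandatory column is named
  raw <- read.delim(toyLibraryPath(), check.names = FALSE)
  raw$hmdb_id <- NULL
  write.table(raw, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(readExpectedLibrary(tmp)),
               "missing mandatory column.*hmdb_id")

  # unknown columns are ignored with a warning
  raw <- read.delim(toyLibraryPath(), check.names = FALSE)
  raw$comment <- "x"
  write.table(raw, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(suppressMessages(readExpectedLibrary(tmp)),
                 "unknown library column.*comment")
})

test_that("read -> write -> read round trip is lossless", {
  lib <- suppressMessages(readExpectedLibrary(toyLibraryPath()))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeExpectedLibrary(lib, tmp)
  lib2 <- suppressMessages(readExpectedLibrary(tmp))
  expect_equal(libraryEntries(lib2), libraryEntries(lib))
  expect_equal(libraryDiseases(lib2), libraryDiseases(lib))
})

test_that("a column map loads foreign headers onto the schema", {
  raw <- read.delim(toyLibraryPath(), check.names = FALSE)
  names(raw)[names(raw) == "hmdb_id"] <- "HMDB code"
  names(raw)[names(raw) == "direction"] <- "expected alteration"
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(raw, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(readExpectedLibrary(tmp)))
  lib <- suppressMessages(suppressWarnings(readExpectedLibrary(
    tmp, columnMap = c(hmdb_id = "HMDB code",
                       direction = "expected alteration"))))
  expect_equal(nrow(libraryEntries(lib)), 12)
})

test_that("validateLibrary reports duplicates, empty diseases and unmeasurable criticals", {
  lib <- suppressMessages(readExpectedLibrary(toyLibraryPath()))
  expect_equal(nrow(validateLibrary(lib)), 0)  # clean toy library

  e <- libraryEntries(lib)
  d <- libraryDiseases(lib)
  e2 <- rbind(e, e[1, ])               # duplicate (PKU, phenylalanine)
  d2 <- rbind(d, data.frame(iem_id = "EMPTY", name = "no entries",
                            category = "", gene = "", omim = "",
                            incidence = "", artefact_disclaimer = "",
                            is_condition = FALSE))
  rep <- validateLibrary(expectedLibrary(d2, e2))
  expect_true(any(rep$finding == "duplicate (iem_id, hmdb_id) entry" &
                  rep$iem_id == "PKU"))
  dup <- rep[rep$finding == "duplicate (iem_id, hmdb_id) entry", ]
  expect_match(dup$lines, ",")         # both line numbers reported
  expect_true(any(rep$finding == "disease has no metabolite entries" &
                  rep$iem_id == "EMPTY"))

  # critical entry missing from the mass table
  mt <- readMassTable(toyMassTablePath())
  mt2 <- mt[mt$hmdb_id != "HMDB0000187", ]
  rep2 <- validateLibrary(lib, mt2)
  expect_true(any(rep2$finding == "critical entry absent from mass table" &
                  rep2$iem_id == "SERDEF"))
})

test_that("weight config YAML overrides defaults and rejects unknown keys", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines("wDecrease: -2\nwUrine: 0.5", tmp)
  cfg <- readWeightConfig(tmp)
  expect_equal(cfg@wDecrease, -2)
  expect_equal(cfg@wUrine, 0.5)
  expect_equal(cfg@wCritical, 5)
  writeLines("wBogus: 3", tmp)
  expect_error(readWeightConfig(tmp), "unknown weight config key")
})
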
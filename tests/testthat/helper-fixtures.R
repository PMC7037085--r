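# in-code fixture builders shared across test files

# minimal entry row with overridable attributes
entryRow <- function(iem_id = "D1", hmdb_id = "M1", mz = 100,
                     direction = "increase", fluid = "plasma",
                     role = "other", only_biomarker = FALSE,
                     importance = "supportive",
                     metabolite_name = hmdb_id) {
  data.frame(iem_id = iem_id, metabolite_name = metabolite_name,
             hmdb_id = hmdb_id, mz = mz, direction = direction,
             fluid = fluid, role = role,
             only_biomarker = only_biomarker, importance = importance,
             stringsAsFactors = FALSE)
}

makeLibrary <- function(entries, conditions = character()) {
  ids <- unique(entries$iem_id)
  diseases <- data.frame(iem_id = ids, name = paste("disease", ids),
                         is_condition = ids %in% conditions,
                         stringsAsFactors = FALSE)
  expectedLibrary(diseases, entries)
}

# a profile straight from z/mode/mz vectors
makeProfile <- function(z, mode = rep("positive", length(z)),
                        mz = seq(100, by = 1, length.out = length(z)),
                        sampleId = "S1")
  rankZScores(z, mode, mz, sampleId)

# identity annotation: feature i carries metabolite hmdb[i]
identityAnnotation <- function(profile, hmdb) {
  f <- profileFeatures(profile)
  data.frame(mode = f$mode, mz = f$mz, hmdb_id = hmdb,
             stringsAsFactors = FALSE)
}

toyLibraryPath <- function()
  system.file("extdata", "toy_library.tsv", package = "iemrank")
toyMassTablePath <- function()
  system.file("extdata", "toy_mass_table.tsv", package = "iemrank")

# random single-sample scoring instance for property tests: features
# with unique m/z, isomer-sharing annotations, diseases with random
# entries that may share metabolites across modes and features
randomScoringInstance <- function(seed, nDiseases = 4, nFeatures = 40,
                                  nMetabolites = 25, maxEntries = 25,
                                  zeroFrac = 0.1) {
  set.seed(seed)
  mode <- sample(c("positive", "negative"), nFeatures, replace = TRUE)
  mz <- sort(runif(nFeatures, 70, 600))
  z <- rnorm(nFeatures, 0, 2.5)
  z[runif(nFeatures) < zeroFrac] <- 0
  profile <- rankZScores(z, mode, mz, "S1")
  hmdb <- sprintf("M%03d", seq_len(nMetabolites))
  # each feature annotated with 0-2 metabolites; a metabolite may land
  # on several features (and modes)
  annot <- do.call(rbind, lapply(seq_len(nFeatures), function(i) {
    k <- sample(0:2, 1, prob = c(0.2, 0.6, 0.2))
    if (!k) return(NULL)
    data.frame(mode = mode[i], mz = mz[i],
               hmdb_id = sample(hmdb, k), stringsAsFactors = FALSE)
  }))
  nEntries <- sample(seq_len(maxEntries), nDiseases, replace = TRUE)
  entries <- do.call(rbind, lapply(seq_len(nDiseases), function(d)
    do.call(rbind, lapply(seq_len(nEntries[d]), function(i)
      entryRow(iem_id = sprintf("D%02d", d),
               hmdb_id = sample(hmdb, 1),
               mz = runif(1, 70, 600),
               direction = sample(c("increase", "decrease"), 1),
               fluid = sample(c("plasma", "dbs", "csf", "urine"), 1),
               role = sample(c("substrate_or_product", "other"), 1),
               only_biomarker = runif(1) < 0.15,
               importance = sample(c("critical", "important",
                                     "supportive"), 1))))))
  list(lib = makeLibrary(entries), profile = profile, annot = annot)
}
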
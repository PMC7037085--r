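#' Weight configuration for expected-library entries
#'
#' Each library entry's weight score is the product of four factors:
#' direction (is the metabolite expected increased or decreased),
#' specificity (only known biomarker, substrate/product of the affected
#' enzyme, or neither), body fluid (blood-derived fluids and CSF count
#' double relative to urine when scoring blood samples), and importance
#' of the alteration for the diagnosis. Decreases carry a negative
#' factor of larger magnitude than increases because decreases are
#' usually more subtle, so an observed decrease (negative Z) should pull
#' the disease up at least as strongly as a comparable increase.
#'
#' Defaults: increase 1, decrease -1.5, only-biomarker 5,
#' substrate/product 3, other role 1, plasma/DBS/CSF 2, urine 1,
#' critical 5, important 3, supportive 1. Under these defaults the
#' largest attainable positive weight is 1 x 5 x 2 x 5 = 50 and the
#' largest magnitude is |-1.5 x 5 x 2 x 5| = 75.
#'
#' @slot wIncrease direction factor for expected increases.
#' @slot wDecrease direction factor for expected decreases (negative).
#' @slot wOnlyBiomarker specificity factor when the metabolite is the
#'   only known biomarker of the disease.
#' @slot wSubstrateProduct specificity factor for substrates/products of
#'   the affected enzyme.
#' @slot wRoleOther specificity factor for all other entries.
#' @slot wBloodCsf fluid factor for plasma, DBS and CSF.
#' @slot wUrine fluid factor for urine.
#' @slot wCritical,wImportant,wSupportive importance factors.
#'
#' @seealso [weightScore()], [readWeightConfig()]
#' @export
setClass("WeightConfig",
  representation(
    wIncrease = "numeric", wDecrease = "numeric",
    wOnlyBiomarker = "numeric", wSubstrateProduct = "numeric",
    wRoleOther = "numeric", wBloodCsf = "numeric", wUrine = "numeric",
    wCritical = "numeric", wImportant = "numeric",
    wSupportive = "numeric"),
  prototype(
    wIncrease = 1, wDecrease = -1.5,
    wOnlyBiomarker = 5, wSubstrateProduct = 3, wRoleOther = 1,
    wBloodCsf = 2, wUrine = 1,
    wCritical = 5, wImportant = 3, wSupportive = 1),
  validity = function(object) {
    vals <- vapply(slotNames(object), function(s) slot(object, s), 0)
    if (any(!is.finite(vals)))
      return("all weight factors must be finite numbers")
    TRUE
  })

#' Create a weight configuration
#'
#' @param ... named overrides of any `WeightConfig` slot, e.g.
#'   `weightConfig(wDecrease = -2)`.
#' @return a [WeightConfig-class] object.
#' @examples
#' cfg <- weightConfig()
#' cfg@wDecrease
#' @export
weightConfig <- function(...) new("WeightConfig", ...)

#' Read weight-factor overrides from a YAML file
#'
#' The YAML file maps slot names of [WeightConfig-class] to numbers;
#' unknown keys are an error. Missing keys keep their defaults.
#'
#' @param path path to a YAML file.
#' @return a [WeightConfig-class].
#' @export
readWeightConfig <- function(path) {
  if (!file.exists(path)) stop("weight config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L) return(weightConfig())
  bad <- setdiff(names(raw), slotNames("WeightConfig"))
  if (length(bad))
    stop("unknown weight config keys: ", paste(bad, collapse = ", "))
  do.call(weightConfig, lapply(raw, as.numeric))
}

#' Weight score of expected-library entries
#'
#' The signed weight of an entry is the product
#' direction x specificity x fluid x importance. The specificity factor
#' is `wOnlyBiomarker` when the entry is flagged as the only known
#' biomarker, else `wSubstrateProduct` when its role is
#' substrate/product, else `wRoleOther`; only-biomarker takes precedence
#' (the factors are alternatives within one category, never multiplied
#' together). The sign of the result is the sign of the direction
#' factor: positive weights expect increases, negative weights expect
#' decreases.
#'
#' @param entries a data.frame of library entries with columns
#'   `direction`, `fluid`, `role`, `only_biomarker`, `importance` (as in
#'   [libraryEntries()]), or a single entry as a one-row data.frame.
#' @param cfg a [WeightConfig-class]; defaults to the standard factors.
#' @return numeric vector of signed weights, one per entry row.
#' @examples
#' e <- data.frame(direction = "increase", fluid = "plasma",
#'                 role = "other", only_biomarker = TRUE,
#'                 importance = "critical")
#' weightScore(e)  # 1 * 5 * 2 * 5 = 50
#' @export
weightScore <- function(entries, cfg = weightConfig()) {
  stopifnot(is(cfg, "WeightConfig"))
  dirF <- ifelse(entries$direction == "increase", cfg@wIncrease,
                 cfg@wDecrease)
  specF <- ifelse(entries$only_biomarker, cfg@wOnlyBiomarker,
           ifelse(entries$role == "substrate_or_product",
                  cfg@wSubstrateProduct, cfg@wRoleOther))
  fluF <- ifelse(entries$fluid == "urine", cfg@wUrine, cfg@wBloodCsf)
  impF <- c(critical = cfg@wCritical, important = cfg@wImportant,
            supportive = cfg@wSupportive)[entries$importance]
  unname(dirF * specF * fluF * impF)
}

setMethod("show", "WeightConfig", function(object) {
  cat("WeightConfig\n")
  for (s in slotNames(object))
    cat(sprintf("  %-18s %g\n", s, slot(object, s)))
})
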
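#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' RiskFactorModel: one environmental risk factor's odds-ratio model
#'
#' Encodes a single environmental risk factor as a lookup from a subject's
#' value to an odds ratio, either over an exhaustive category set
#' (categorical) or over contiguous half-open bins `[low, high)` of a
#' continuous measurement (a boundary value falls in the upper bin).
#' Medication override flags force the maximal OR of the factor regardless
#' of the measured value (e.g. a treated hypertensive whose pressure reads
#' normal still carries the hypertension risk). The source effect measure
#' (OR/RR/HR) and the unexposed-group prevalence are carried along so the
#' rare-disease validity of treating an RR or HR as an OR can be checked.
#'
#' @slot factorId character scalar identifier.
#' @slot valueKind `"categorical"` or `"continuous"`.
#' @slot categories category labels (categorical factors only).
#' @slot breaks lower bin bounds, strictly increasing (continuous factors
#'   only); the first bound is the domain minimum, the last bin is open
#'   above.
#' @slot ors odds ratios, one per category or bin, all positive.
#' @slot ageDependent whether the curve is indexed by age.
#' @slot medicationOverrides medication flags that trigger the max-OR rule.
#' @slot sourceMeasure `"OR"`, `"RR"` or `"HR"` as published.
#' @slot sourcePrevalence unexposed-group disease prevalence in `[0,1)`
#'   used for the RR-to-OR validity check (`NA` if unknown).
#' @slot role `"standard"` (enters the environmental score),
#'   `"family_history"` (held out of the environmental score, used by the
#'   family-history substitution analysis) or `"optional"`.
#'
#' @seealso [riskFactorModel()], [factorOR()]
#' @exportClass RiskFactorModel
setClass("RiskFactorModel",
  representation(
    factorId = "character",
    valueKind = "character",
    categories = "character",
    breaks = "numeric",
    ors = "numeric",
    ageDependent = "logical",
    medicationOverrides = "character",
    sourceMeasure = "character",
    sourcePrevalence = "numeric",
    role = "character"
  ),
  prototype(
    categories = character(0),
    breaks = numeric(0),
    ageDependent = FALSE,
    medicationOverrides = character(0),
    sourceMeasure = "OR",
    sourcePrevalence = NA_real_,
    role = "standard"
  )
)

setValidity("RiskFactorModel", function(object) {
  msg <- character(0)
  if (length(object@factorId) != 1L || !nzchar(object@factorId))
    msg <- c(msg, "factorId must be a non-empty string")
  if (!object@valueKind %in% c("categorical", "continuous"))
    msg <- c(msg, "valueKind must be 'categorical' or 'continuous'")
  if (any(!is.finite(object@ors)) || any(object@ors <= 0))
    msg <- c(msg, "all ORs must be finite and > 0")
  if (object@valueKind == "categorical") {
    if (length(object@categories) != length(object@ors))
      msg <- c(msg, "categories and ors must have equal length")
    if (anyDuplicated(object@categories))
      msg <- c(msg, "categories must be unique")
  } else {
    if (length(object@breaks) != length(object@ors))
      msg <- c(msg, "breaks and ors must have equal length")
    if (length(object@breaks) > 1L && any(diff(object@breaks) <= 0))
      msg <- c(msg, "breaks must be strictly increasing")
  }
  if (!object@sourceMeasure %in% c("OR", "RR", "HR"))
    msg <- c(msg, "sourceMeasure must be OR, RR or HR")
  if (!is.na(object@sourcePrevalence) &&
      (object@sourcePrevalence < 0 || object@sourcePrevalence >= 1))
    msg <- c(msg, "sourcePrevalence must be in [0, 1)")
  if (!object@role %in% c("standard", "family_history", "optional"))
    msg <- c(msg, "role must be standard, family_history or optional")
  if (length(msg)) msg else TRUE
})

#' T2DCohort: subject-level cohort with genotype dosages
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' genotype dosage matrix (SNPs in rows, subjects in columns, dosage of the
#' catalogue risk allele in `{0, 1, 2, NA}`) as the `"dosage"` assay and
#' the subject-level environmental values, baseline flags and endpoint in
#' `colData`. Synthetic cohorts store the generator truth record in
#' `metadata(x)$truth`.
#'
#' Expected `colData` columns used by the pipeline:
#' `prevalent_t2d_baseline`, `env_complete`, `censored`, `incident_t2d`
#' (logical; `NA` iff censored), plus one column per environmental factor
#' and logical medication flag columns.
#'
#' @seealso [T2DCohort()], [generateCohort()], [applyExclusions()]
#' @exportClass T2DCohort
setClass("T2DCohort", contains = "SummarizedExperiment")

setValidity("T2DCohort", function(object) {
  msg <- character(0)
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- !is.na(d) & !(d %in% c(0, 1, 2))
    if (any(bad)) msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  cd <- SummarizedExperiment::colData(object)
  if ("incident_t2d" %in% colnames(cd) && "censored" %in% colnames(cd)) {
    if (!all(is.na(cd$incident_t2d) == (cd$censored %in% TRUE)))
      msg <- c(msg, "incident_t2d must be NA exactly for censored subjects")
  }
  if (length(msg)) msg else TRUE
})

#' BlockSelection: LD-block representative SNPs with per-subject fallback
#'
#' Result of [selectBlockRepresentatives()]. Per LD block, SNPs are ranked
#' by evidence score; the cohort-level representative is the
#' highest-ranked SNP genotyped in at least `availabilityThreshold` of
#' subjects. Subjects missing the representative's genotype fall back to
#' the next-ranked SNP available for them; blocks with no genotyped SNP at
#' all are recorded in `blocksUnavailable` and excluded from scoring for
#' every subject. Subjects lacking data for any usable block are listed in
#' `incompleteSubjects`.
#'
#' @slot ranking named list: block id -> rsids in score order.
#' @slot representative named character: usable block id -> chosen rsid.
#' @slot fallback data.frame with columns `subject_id`, `block`, `rsid`
#'   (per-subject substitutions of the representative).
#' @slot blocksUnavailable block ids with no genotyped SNP.
#' @slot incompleteSubjects subject ids with at least one usable block
#'   uncovered.
#' @slot availabilityThreshold the cohort-availability fraction used.
#' @exportClass BlockSelection
setClass("BlockSelection",
  representation(
    ranking = "list",
    representative = "character",
    fallback = "data.frame",
    blocksUnavailable = "character",
    incompleteSubjects = "character",
    availabilityThreshold = "numeric"
  )
)

setValidity("BlockSelection", function(object) {
  msg <- character(0)
  if (length(intersect(names(object@representative), object@blocksUnavailable)))
    msg <- c(msg, "a block cannot be both usable and unavailable")
  if (!all(names(object@representative) %in% names(object@ranking)))
    msg <- c(msg, "every usable block must appear in the ranking")
  if (length(msg)) msg else TRUE
})

#' BootstrapResult: point estimate with percentile bootstrap CI and p-value
#'
#' @slot statistic short label of the resampled statistic.
#' @slot estimate observed (full-sample) value.
#' @slot ciLow,ciHigh percentile bootstrap interval bounds.
#' @slot pValue two-sided sign-crossing bootstrap p-value, clamped to
#'   `[1/B, 1]`; `pBound` is `TRUE` when no resample crossed zero, i.e.
#'   the value should be read as "< 1/B".
#' @slot pBound logical, see `pValue`.
#' @slot nResamples number of bootstrap resamples B.
#' @slot seed RNG seed used.
#' @slot level confidence level of the interval.
#' @slot resamples the resampled statistics (kept for diagnostics).
#' @exportClass BootstrapResult
setClass("BootstrapResult",
  representation(
    statistic = "character",
    estimate = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    pValue = "numeric",
    pBound = "logical",
    nResamples = "integer",
    seed = "integer",
    level = "numeric",
    resamples = "numeric"
  ),
  prototype(pBound = FALSE, level = 0.95)
)

setValidity("BootstrapResult", function(object) {
  msg <- character(0)
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (object@nResamples < 1L) msg <- c(msg, "nResamples must be >= 1")
  if (object@level <= 0 || object@level >= 1)
    msg <- c(msg, "level must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' RiskGroups: median-split environmental and tertile genetic risk groups
#'
#' Per-subject assignment to one of two environmental risk groups (ERG,
#' median split of the aggregate environmental OR; values exactly at the
#' median go to ERG1) and one of three genetic risk groups (GRG, tertiles
#' of the aggregate genetic OR; values at a cutoff go to the lower group).
#'
#' @slot erg integer vector in `{1, 2}`.
#' @slot grg integer vector in `{1, 2, 3}`.
#' @slot envCutoff the median environmental OR.
#' @slot genCutoffs the two genetic tertile cutoffs.
#' @slot degenerate TRUE when tied cutoffs made groups unbalanced.
#' @exportClass RiskGroups
setClass("RiskGroups",
  representation(
    erg = "integer",
    grg = "integer",
    envCutoff = "numeric",
    genCutoffs = "numeric",
    degenerate = "logical"
  ),
  prototype(degenerate = FALSE)
)

setValidity("RiskGroups", function(object) {
  msg <- character(0)
  if (length(object@erg) != length(object@grg))
    msg <- c(msg, "erg and grg must be aligned")
  if (!all(object@erg %in% 1:2)) msg <- c(msg, "erg values must be 1 or 2")
  if (!all(object@grg %in% 1:3)) msg <- c(msg, "grg values must be 1, 2 or 3")
  if (length(object@genCutoffs) != 2L)
    msg <- c(msg, "genCutoffs must have length 2")
  if (length(msg)) msg else TRUE
})

#' IncidenceTable: ERG x GRG incidence grid with bootstrap uncertainty
#'
#' The 2x3 gene-by-environment incidence grid: per cell the subject count,
#' case count, incidence and percentile bootstrap CI; plus, within each
#' environmental risk group, pairwise bootstrap p-values for the
#' difference in incidence between genetic risk groups.
#'
#' @slot grid data.frame with columns `erg`, `grg`, `n`, `cases`,
#'   `incidence`, `ci_low`, `ci_high`.
#' @slot pairwise data.frame with columns `erg`, `grg_a`, `grg_b`,
#'   `delta`, `p_value`.
#' @slot nResamples,seed,level bootstrap configuration used.
#' @exportClass IncidenceTable
setClass("IncidenceTable",
  representation(
    grid = "data.frame",
    pairwise = "data.frame",
    nResamples = "integer",
    seed = "integer",
    level = "numeric"
  )
)

setValidity("IncidenceTable", function(object) {
  g <- object@grid
  msg <- character(0)
  need <- c("erg", "grg", "n", "cases", "incidence", "ci_low", "ci_high")
  if (!all(need %in% colnames(g)))
    msg <- c(msg, "grid is missing required columns")
  else {
    ok <- g$n == 0 | (g$incidence >= 0 & g$incidence <= 1)
    if (!all(ok, na.rm = TRUE)) msg <- c(msg, "incidence must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
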
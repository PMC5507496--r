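#' Read environmental risk-factor models from YAML
#'
#' One document key `factors:` with a list of entries:
#' `factor_id`, `kind` (`continuous`/`categorical`), `ors` (map of
#' category label or lower bin bound to OR), and optionally
#' `age_dependent`, `medication_overrides`, `source_measure`, `p0`,
#' `role`.
#'
#' @param path YAML file.
#' @return named list of [RiskFactorModel-class] objects.
#' @export
readRiskModels <- function(path) {
  y <- yaml::read_yaml(path)
  recs <- if (!is.null(y$factors)) y$factors else y
  models <- lapply(recs, function(r) {
    riskFactorModel(
      factorId = r$factor_id,
      valueKind = r$kind,
      ors = unlist(r$ors),
      ageDependent = isTRUE(r$age_dependent),
      medicationOverrides = as.character(r$medication_overrides %||%
                                           character(0)),
      sourceMeasure = r$source_measure %||% "OR",
      sourcePrevalence = as.numeric(r$p0 %||% NA_real_),
      role = r$role %||% "standard")
  })
  names(models) <- vapply(models, function(m) m@factorId, character(1))
  models
}

`%||%` <- function(a, b) if (is.null(a)) b else a

extdata <- function(file) {
  p <- system.file("extdata", file, package = "t2drisk")
  if (!nzchar(p)) stop("packaged file not found: ", file)
  p
}

#' Packaged default configurations
#'
#' `defaultRiskModels()` loads the 13-factor environmental risk-model
#' configuration shipped with the package (synthetic odds-ratio curves
#' of realistic magnitude; the age curve dominates the aggregate OR, as
#' a reference age of 20 implies for a late-middle-aged cohort).
#' `defaultSnpCatalogue()` loads the synthetic SNP catalogue: the 19
#' representative rsIDs, genes, chromosomes, block ranks and the two
#' per-subject fallback SNPs follow the published selection, the three
#' published allelic ORs are used verbatim, and the remaining ORs,
#' frequencies and evidence metadata are realistic synthetic values; the
#' record counts reproduce the published filter cascade (154 to 53 to 28
#' records, 24 LD blocks, 19 usable).
#'
#' @return `defaultRiskModels()`: named list of
#'   [RiskFactorModel-class]; `defaultSnpCatalogue()`: catalogue
#'   data.frame (unfiltered, 154 records).
#' @export
defaultRiskModels <- function() {
  readRiskModels(extdata("risk_models.yaml"))
}

#' @rdname defaultRiskModels
#' @export
defaultSnpCatalogue <- function() {
  readSnpCatalogue(extdata("snp_catalogue_synthetic.csv"))
}

#' @rdname defaultRiskModels
#' @export
defaultPointScoreConfigs <- function() {
  list(
    finnish = readPointScoreConfig(extdata("findrisc_points_synthetic.yaml")),
    framingham = readPointScoreConfig(
      extdata("framingham_points_synthetic.yaml")))
}
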
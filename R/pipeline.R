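#' Run the full risk-stratification analysis
#'
#' Orchestrates the whole study on a cohort: SNP catalogue filtering and
#' LD-block representative selection, the exclusion cascade, aggregate
#' environmental/genetic/combined odds ratios, median/tertile risk-group
#' stratification, comparator point-score AUCs, genetic-OR/case-status
#' correlations (full cohort and per environmental stratum), the 2x3
#' stratified incidence grid with pairwise bootstrap p-values, paired
#' AUC comparisons of the environmental model against the combined model
#' (full cohort and per stratum), and the family-history substitution
#' comparison. Fully deterministic given `seed`.
#'
#' @param cohort a [T2DCohort-class] (e.g. from [generateCohort()]).
#' @param models risk-factor models (default [defaultRiskModels()]).
#' @param catalogue unfiltered SNP catalogue (default
#'   [defaultSnpCatalogue()]).
#' @param pointScores named list of point-score configs (default
#'   [defaultPointScoreConfigs()]); set `NULL` to skip comparators.
#' @param B bootstrap resamples (default 10000).
#' @param seed RNG seed for every bootstrap.
#' @param level confidence level.
#' @param normalizeGenetics HWE mean-centre per-SNP ORs (default TRUE).
#' @return list of class `t2d_report` with elements `provenance`,
#'   `filter_audit`, `selection`, `exclusion_audit`,
#'   `excluded_comparison`, `scores`, `groups`, `comparator_aucs`,
#'   `correlations`, `incidence`, `auc_shift`, `family_history`,
#'   `sens_spec`.
#' @export
runFullAnalysis <- function(cohort, models = defaultRiskModels(),
                            catalogue = defaultSnpCatalogue(),
                            pointScores = defaultPointScoreConfigs(),
                            B = 10000L, seed = 1L, level = 0.95,
                            normalizeGenetics = TRUE) {
  stopifnot(is(cohort, "T2DCohort"))
  stageFail <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", stage, "]: ", conditionMessage(e), call. = FALSE))
  }

  filt <- stageFail("snp_filter", filterCatalogue(catalogue))
  selection <- stageFail("block_selection",
    selectBlockRepresentatives(filt$catalogue, cohort))
  excl <- stageFail("exclusions", applyExclusions(cohort, selection))
  ana <- excl$cohort
  cd <- as.data.frame(SummarizedExperiment::colData(ana))

  envOR <- stageFail("environmental_scoring",
                     cohortEnvironmentalOR(cd, models))
  genOR <- stageFail("genetic_scoring",
    aggregateGeneticOR(ana, selection, filt$catalogue,
                       normalize = normalizeGenetics))
  combOR <- combineOR(envOR, genOR)
  labels <- as.numeric(cd$incident_t2d)

  # censored-vs-retained comparability check (pre-genotype-stage set)
  exclComp <- local({
    cdAll <- as.data.frame(SummarizedExperiment::colData(cohort))
    pre <- !(cdAll$prevalent_t2d_baseline %in% TRUE) &
      (cdAll$env_complete %in% TRUE)
    cens <- pre & (cdAll$censored %in% TRUE)
    kept <- pre & !(cdAll$censored %in% TRUE)
    if (sum(cens) >= 2 && sum(kept) >= 2) {
      envAll <- cohortEnvironmentalOR(cdAll, models)
      genAll <- aggregateGeneticOR(cohort, selection, filt$catalogue,
                                   normalize = normalizeGenetics)
      okC <- cens & !is.na(envAll) & !is.na(genAll)
      okK <- kept & !is.na(envAll) & !is.na(genAll)
      if (sum(okC) >= 2 && sum(okK) >= 2)
        compareExcluded(envAll[okK], genAll[okK],
                        envAll[okC], genAll[okC])
      else NULL
    } else NULL
  })

  groups <- stageFail("stratification", stratifyRisk(envOR, genOR))
  erg <- ergAssignments(groups)

  comparators <- NULL
  if (!is.null(pointScores) && length(pointScores)) {
    comparators <- lapply(pointScores, function(cfg) stageFail(
      paste0("comparator_", cfg$name), {
        ps <- pointScore(cfg, cd)
        cmp <- compareAUCs(ps, envOR, labels, B = B, seed = seed,
                           level = level)
        list(name = cfg$name, auc = cmp$auc_a, auc_env = cmp$auc_b,
             delta = cmp$delta)
      }))
  }

  corFor <- function(sel) pearsonCaseCorrelation(
    genOR[sel], labels[sel], B = B, seed = seed, level = level)
  correlations <- stageFail("correlations", list(
    full = corFor(rep(TRUE, length(genOR))),
    erg1 = corFor(erg == 1L),
    erg2 = corFor(erg == 2L)))

  incidence <- stageFail("incidence",
    incidenceTable(groups, labels, B = B, seed = seed, level = level))

  shiftFor <- function(sel) compareAUCs(
    envOR[sel], combOR[sel], labels[sel], B = B, seed = seed,
    level = level)
  aucShift <- stageFail("auc_shift", list(
    full = shiftFor(rep(TRUE, length(envOR))),
    erg1 = shiftFor(erg == 1L),
    erg2 = shiftFor(erg == 2L)))

  familyHistory <- stageFail("family_history", {
    fhModels <- Filter(function(m) m@role %in% c("standard",
                                                 "family_history"),
                       models)
    if (any(vapply(fhModels, function(m) m@role == "family_history",
                   logical(1))) &&
        "family_history" %in% colnames(cd)) {
      envFh <- cohortEnvironmentalOR(cd, fhModels,
                                     roles = c("standard",
                                               "family_history"))
      compareAUCs(envOR, envFh, labels, B = B, seed = seed,
                  level = level)
    } else NULL
  })

  sensSpec <- stageFail("sens_spec",
    sensitivitySpecificityGain(envOR, combOR, labels))

  structure(list(
    provenance = list(seed = seed, B = B, level = level,
                      n_input = ncol(cohort), n_analysis = ncol(ana),
                      normalize_genetics = normalizeGenetics,
                      timestamp = NULL),
    filter_audit = filt$audit,
    selection = selection,
    exclusion_audit = excl$audit,
    excluded_comparison = exclComp,
    scores = data.frame(subject_id = colnames(ana), env_or = envOR,
                        gen_or = genOR, combined_or = combOR,
                        incident = labels),
    groups = groups,
    comparator_aucs = comparators,
    correlations = correlations,
    incidence = incidence,
    auc_shift = aucShift,
    family_history = familyHistory,
    sens_spec = sensSpec), class = "t2d_report")
}

#' Flatten an analysis report to plain lists for JSON serialisation
#'
#' @param report a `t2d_report` from [runFullAnalysis()].
#' @return a nested plain list mirroring the report tables.
#' @export
reportToList <- function(report) {
  br <- function(x) if (is.null(x)) NULL else list(
    estimate = x@estimate, ci_low = x@ciLow, ci_high = x@ciHigh,
    p_value = x@pValue, p_is_bound = x@pBound, n_resamples = x@nResamples,
    seed = x@seed)
  shift <- function(s) if (is.null(s)) NULL else list(
    auc_env = s$auc_a, auc_combined = s$auc_b, delta = br(s$delta))
  list(
    provenance = report$provenance,
    filter_audit = report$filter_audit,
    exclusion_audit = report$exclusion_audit,
    excluded_comparison = as.list(report$excluded_comparison),
    cutoffs = list(env_median = envCutoff(report$groups),
                   gen_tertiles = genCutoffs(report$groups)),
    comparator_aucs = lapply(report$comparator_aucs, function(cc) list(
      name = cc$name, auc = cc$auc, auc_env = cc$auc_env,
      delta = br(cc$delta))),
    correlations = lapply(report$correlations, br),
    incidence = list(grid = incidenceGrid(report$incidence),
                     pairwise = pairwisePValues(report$incidence)),
    auc_shift = lapply(report$auc_shift, shift),
    family_history = shift(report$family_history),
    sens_spec = list(
      max_sensitivity_gain = report$sens_spec$max_sensitivity_gain,
      max_specificity_gain = report$sens_spec$max_specificity_gain))
}

#' Write an analysis report as JSON
#'
#' @param report a `t2d_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeReportJSON <- function(report, path) {
  jsonlite::write_json(reportToList(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @export
print.t2d_report <- function(x, ...) {
  cat("Multifactorial T2D risk analysis report\n")
  cat("  subjects:", x$provenance$n_input, "input,",
      x$provenance$n_analysis, "analysed\n")
  cat("  exclusion cascade:\n")
  print(x$exclusion_audit, row.names = FALSE)
  cat("  SNP filter audit:\n")
  print(x$filter_audit, row.names = FALSE)
  cat(sprintf("  median env OR %.4g; genetic tertile cutoffs %.4g / %.4g\n",
              envCutoff(x$groups), genCutoffs(x$groups)[1],
              genCutoffs(x$groups)[2]))
  s <- x$auc_shift$full
  cat(sprintf("  AUC env %.4f -> env+gen %.4f (delta %+.4f, p %s)\n",
              s$auc_a, s$auc_b, s$delta@estimate,
              if (s$delta@pBound) paste0("< ", 1 / s$delta@nResamples)
              else format(s$delta@pValue, digits = 3)))
  invisible(x)
}
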
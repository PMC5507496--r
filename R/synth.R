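#' Published marginal characteristics the generator emulates
#'
#' Counts and moments of the Swedish population cohort the synthetic
#' generator is calibrated to: category counts out of 3,426 analysis-set
#' subjects and means/SDs of the continuous measurements. These counts
#' are also the source of the generator's default category
#' probabilities.
#'
#' @return list with `n`, `counts` (data.frame `variable`, `category`,
#'   `count`) and `moments` (data.frame `variable`, `mean`, `sd`).
#' @export
referenceMarginals <- function() {
  list(
    n = 3426L,
    counts = data.frame(
      variable = c("gender", "gender",
                   "physical_activity", "physical_activity",
                   "physical_activity",
                   "family_history", "family_history", "family_history",
                   "smoking", "smoking", "smoking", "smoking"),
      category = c("male", "female",
                   "very_low", "low", "moderate",
                   "none", "one", "two",
                   "never", "past", "current_sometimes",
                   "current_regularly"),
      count = c(1298L, 2128L,
                3238L, 186L, 2L,
                3337L, 89L, 0L,
                1471L, 1151L, 152L, 652L)),
    moments = data.frame(
      variable = c("age", "bmi", "alcohol", "sbp", "dbp",
                   "triglycerides", "hdl"),
      mean = c(57.1, 25.6, 5.15, 140, 86.5, 1.32, 1.41),
      sd = c(5.93, 3.75, 5.94, 18.3, 9.24, 0.69, 0.37)))
}

#' Parameters of the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the pipeline assumes: the
#' environmental marginals of [referenceMarginals()] (factors drawn
#' independently), Hardy-Weinberg genotypes at the catalogue allele
#' frequencies, an overall 15-year incidence of 402/3426, and the
#' exclusion-stage magnitudes of the published cascade (prevalent
#' baseline diabetes 267/6094, missing environmental data 1287/6094,
#' censoring 497/4540, missing genotype coverage 617/4043). Exclusion
#' counts are assigned to disjoint subject sets in cascade order, so a
#' pre-exclusion pool of 6,094 reproduces the printed stage counts
#' exactly.
#'
#' @param nSubjects pre-exclusion cohort size. The default 3426 with
#'   `applyExclusionStructure = FALSE` generates a clean analysis set;
#'   use `nSubjects = 6094` with `applyExclusionStructure = TRUE` for
#'   the full cascade.
#' @param seed RNG seed; the generator is fully deterministic given it.
#' @param targetIncidence overall incidence the baseline risk is
#'   calibrated to (default 402/3426).
#' @param applyExclusionStructure draw prevalence/missing-data/censoring
#'   flags (default `TRUE` when `nSubjects > 3426`).
#' @param exclusionRates stage rates, interpreted relative to the stage
#'   denominators of the published cascade.
#' @param fallbackMissing named integer: per rsID, how many subjects
#'   (with a ranked alternative SNP available) have that genotype
#'   missing; defaults mirror the two printed fallback counts (5 and 8).
#' @param medicationRates fraction on antihypertensive / lipid-lowering
#'   treatment at baseline.
#' @param gxeAttenuation optional scaling of genetic effects by
#'   environmental stratum (default 0 = off): latent log genetic ORs are
#'   multiplied by `1 + gxeAttenuation` below the median environmental
#'   OR and `1 - gxeAttenuation` above it.
#' @return list of class `synth_params`.
#' @export
synthParams <- function(nSubjects = 3426L, seed = 1L,
                        targetIncidence = 402 / 3426,
                        applyExclusionStructure = nSubjects > 3426L,
                        exclusionRates = c(prevalent = 267 / 6094,
                                           missing_env = 1287 / 6094,
                                           censored = 497 / 4540,
                                           missing_genotype = 617 / 4043),
                        fallbackMissing = c(rs4402960 = 5L,
                                            rs7903146 = 8L),
                        medicationRates = c(antihypertensive = 0.15,
                                            lipid_lowering = 0.08),
                        gxeAttenuation = 0) {
  ref <- referenceMarginals()
  catProbs <- lapply(split(ref$counts, ref$counts$variable), function(d)
    stats::setNames(d$count / sum(d$count), d$category))
  for (v in names(catProbs)) {
    p <- catProbs[[v]]
    if (abs(sum(p) - 1) > 1e-9) stop("category probabilities of ", v,
                                     " do not sum to 1")
  }
  if (targetIncidence <= 0 || targetIncidence >= 1)
    stop("targetIncidence must be in (0, 1)")
  structure(list(
    nSubjects = as.integer(nSubjects), seed = as.integer(seed),
    targetIncidence = targetIncidence,
    applyExclusionStructure = isTRUE(applyExclusionStructure),
    exclusionRates = exclusionRates,
    fallbackMissing = fallbackMissing,
    medicationRates = medicationRates,
    gxeAttenuation = gxeAttenuation,
    catProbs = catProbs,
    moments = ref$moments), class = "synth_params")
}

#' Expected incidence implied by a relative odds ratio
#'
#' Inverts the odds-ratio relation at a reference incidence:
#' `p = p_ref OR / (1 - p_ref + p_ref OR)`. Maps `OR = 1` to `p_ref`,
#' is strictly increasing in OR and bounded in `(0, 1)`.
#'
#' @param orRelative odds ratio relative to the reference group, `> 0`.
#' @param pRef reference-group incidence in `(0, 1)`.
#' @return incidence fraction(s).
#' @examples
#' incidenceFromOR(2, 0.1)  # 0.2 / 1.1 = 0.1818
#' @export
incidenceFromOR <- function(orRelative, pRef) {
  if (any(orRelative <= 0)) stop("orRelative must be > 0")
  if (any(pRef <= 0 | pRef >= 1)) stop("pRef must be in (0, 1)")
  pRef * orRelative / (1 - pRef + pRef * orRelative)
}

#' Calibrate the baseline incidence to a target overall incidence
#'
#' Bisection on the reference incidence `p_ref` so that the expected
#' cohort incidence `mean(incidenceFromOR(or, p_ref))` over the supplied
#' relative odds ratios matches the target. Under a null model (all ORs
#' equal to 1) the solution is the target itself.
#'
#' @param targetIncidence desired overall incidence in `(0, 1)`.
#' @param relativeORs latent per-subject relative odds ratios.
#' @param tol convergence tolerance on the expected incidence
#'   (default 1e-8).
#' @return the calibrated `p_ref`.
#' @export
calibrateBaseline <- function(targetIncidence, relativeORs, tol = 1e-8) {
  if (targetIncidence <= 0 || targetIncidence >= 1)
    stop("targetIncidence must be in (0, 1)")
  f <- function(p) mean(incidenceFromOR(relativeORs, p)) - targetIncidence
  lo <- 1e-12
  hi <- 1 - 1e-12
  if (f(lo) > 0 || f(hi) < 0)
    stop("target incidence is not bracketed by the OR distribution")
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * 1e-4 && abs(f((lo + hi) / 2)) < tol) break
  }
  (lo + hi) / 2
}

# Truncated-at-zero normal draw (redraws the negative tail mass at 0+).
rnormTrunc0 <- function(n, mean, sd) {
  pmax(stats::rnorm(n, mean, sd), 0)
}

#' Generate a synthetic cohort
#'
#' Draws environmental values independently from the configured
#' marginals and genotypes under Hardy-Weinberg equilibrium at the
#' catalogue allele frequencies (on-array SNPs only), computes each
#' subject's latent environmental and genetic odds ratio with the risk
#' engine itself, calibrates the baseline incidence to the target via
#' [calibrateBaseline()], draws incident status Bernoulli from
#' [incidenceFromOR()], and (optionally) overlays the exclusion
#' structure: prevalent-baseline flags, blanked environmental values,
#' censoring, and whole-block genotype dropout, assigned to disjoint
#' subject sets in cascade order. The latent risks and generator
#' configuration are stored as the truth record in `metadata(x)$truth`.
#'
#' @param params a `synth_params` list from [synthParams()].
#' @param models list of [RiskFactorModel-class] (default the packaged
#'   13-factor configuration, [defaultRiskModels()]).
#' @param catalogue SNP catalogue (default [defaultSnpCatalogue()],
#'   filtered to the usable records with [filterCatalogue()] defaults).
#' @return a [T2DCohort-class].
#' @export
generateCohort <- function(params = synthParams(),
                           models = defaultRiskModels(),
                           catalogue = NULL) {
  stopifnot(inherits(params, "synth_params"))
  if (is.null(catalogue))
    catalogue <- filterCatalogue(defaultSnpCatalogue())$catalogue
  validateCatalogue(catalogue)
  if (!"on_array" %in% colnames(catalogue))
    catalogue$on_array <- TRUE
  n <- params$nSubjects
  mom <- function(v) {
    i <- match(v, params$moments$variable)
    params$moments[i, c("mean", "sd")]
  }
  drawCat <- function(v)
    sample(names(params$catProbs[[v]]), n, replace = TRUE,
           prob = params$catProbs[[v]])

  withSeed(params$seed, {
    age <- stats::rnorm(n, mom("age")$mean, mom("age")$sd)
    bmi <- rnormTrunc0(n, mom("bmi")$mean, mom("bmi")$sd)
    alcohol <- rnormTrunc0(n, mom("alcohol")$mean, mom("alcohol")$sd)
    sbp <- stats::rnorm(n, mom("sbp")$mean, mom("sbp")$sd)
    dbp <- stats::rnorm(n, mom("dbp")$mean, mom("dbp")$sd)
    tg <- rnormTrunc0(n, mom("triglycerides")$mean,
                      mom("triglycerides")$sd)
    hdl <- rnormTrunc0(n, mom("hdl")$mean, mom("hdl")$sd)
    waist <- rnormTrunc0(n, 84, 11)
    gender <- drawCat("gender")
    smoking <- drawCat("smoking")
    pa <- drawCat("physical_activity")
    fh <- drawCat("family_history")
    onAH <- stats::runif(n) < params$medicationRates[["antihypertensive"]]
    onLL <- stats::runif(n) < params$medicationRates[["lipid_lowering"]]

    data <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      age = pmax(age, 25), bmi = bmi, alcohol = alcohol,
      sbp = sbp, dbp = dbp, triglycerides = tg, hdl = hdl, waist = waist,
      gender = gender, smoking = smoking,
      past_smoking = ifelse(smoking == "past", "yes", "no"),
      physical_activity = pa, family_history = fh,
      ethnicity = "european",
      hypertension = hypertensionCategory(sbp, dbp),
      on_antihypertensive = onAH, on_lipid_lowering = onLL,
      stringsAsFactors = FALSE)

    # HWE genotypes for on-array SNPs
    onArray <- catalogue[catalogue$on_array %in% TRUE, , drop = FALSE]
    dosage <- matrix(NA_real_, nrow(onArray), n,
                     dimnames = list(onArray$rsid, data$subject_id))
    for (i in seq_len(nrow(onArray)))
      dosage[i, ] <- stats::rbinom(n, 2, onArray$risk_allele_freq[i])

    # latent risks from the engine itself (before any blanking)
    envOR <- cohortEnvironmentalOR(data, models)
    selection <- selectBlockRepresentatives(catalogue, dosage)
    genOR <- aggregateGeneticOR(dosage, selection, catalogue)
    logGen <- log(genOR)
    if (params$gxeAttenuation != 0) {
      lowEnv <- envOR <= stats::median(envOR)
      logGen <- logGen * ifelse(lowEnv, 1 + params$gxeAttenuation,
                                1 - params$gxeAttenuation)
    }
    envRel <- envOR / exp(mean(log(envOR)))
    relOR <- envRel * exp(logGen)
    pRef <- calibrateBaseline(params$targetIncidence, relOR)
    pInc <- incidenceFromOR(relOR, pRef)
    incident <- stats::runif(n) < pInc

    prevalent <- rep(FALSE, n)
    envComplete <- rep(TRUE, n)
    censored <- rep(FALSE, n)
    envFactorCols <- vapply(
      Filter(function(m) m@role == "standard", models),
      function(m) m@factorId, character(1))
    if (params$applyExclusionStructure) {
      r <- params$exclusionRates
      pool <- seq_len(n)
      nPrev <- round(n * r[["prevalent"]])
      iPrev <- sample(pool, nPrev)
      pool <- setdiff(pool, iPrev)
      nMiss <- round(n * r[["missing_env"]])
      iMiss <- sample(pool, nMiss)
      pool <- setdiff(pool, iMiss)
      nCens <- round(length(pool) * r[["censored"]])
      iCens <- sample(pool, nCens)
      pool <- setdiff(pool, iCens)
      nGeno <- round(length(pool) * r[["missing_genotype"]])
      iGeno <- sample(pool, nGeno)
      prevalent[iPrev] <- TRUE
      censored[iCens] <- TRUE
      # blank one random required factor per missing-env subject
      blankCol <- sample(envFactorCols, nMiss, replace = TRUE)
      for (k in seq_along(iMiss)) data[iMiss[k], blankCol[k]] <- NA
      envComplete[iMiss] <- FALSE
      # whole-block genotype dropout: blank every SNP of the first
      # single-SNP usable block for the affected subjects
      blk <- names(Filter(function(x) length(x) == 1, selection@ranking))
      blk <- intersect(blk, names(selection@representative))[1]
      dosage[selection@ranking[[blk]], iGeno] <- NA_real_
    }

    # per-subject fallback missingness on SNPs with a ranked alternative
    for (rs in names(params$fallbackMissing)) {
      if (!rs %in% rownames(dosage)) next
      k <- params$fallbackMissing[[rs]]
      eligible <- which(!prevalent & envComplete & !censored &
                          !is.na(dosage[rs, ]))
      take <- sample(eligible, min(k, length(eligible)))
      dosage[rs, take] <- NA_real_
    }

    incidentOut <- incident
    incidentOut[censored] <- NA
    cd <- data
    cd$prevalent_t2d_baseline <- prevalent
    cd$env_complete <- envComplete
    cd$censored <- censored
    cd$incident_t2d <- incidentOut
    rownames(cd) <- cd$subject_id

    truth <- list(params = params, p_ref = pRef, env_or = envOR,
                  gen_or = genOR, relative_or = relOR,
                  p_incidence = pInc, incident_latent = incident)
    T2DCohort(dosage, cd, metadata = list(truth = truth))
  })
}

#' Blood-pressure category from systolic and diastolic readings
#'
#' Hypertension risk reflects elevation of either reading; the category
#' is the worse of the two.
#'
#' @param sbp,dbp numeric mmHg (vectorised; `NA` propagates).
#' @return character vector in
#'   `normal < high_normal < stage1 < stage2`.
#' @export
hypertensionCategory <- function(sbp, dbp) {
  s <- cut(sbp, c(-Inf, 130, 140, 160, Inf), right = FALSE,
           labels = c("normal", "high_normal", "stage1", "stage2"))
  d <- cut(dbp, c(-Inf, 85, 90, 100, Inf), right = FALSE,
           labels = c("normal", "high_normal", "stage1", "stage2"))
  lv <- c("normal", "high_normal", "stage1", "stage2")
  out <- lv[pmax(as.integer(s), as.integer(d))]
  out
}

#' Write a synthetic cohort to the pipeline's on-disk formats
#'
#' Emits the subject-level CSV, the subjects-by-SNP dosage CSV and the
#' truth record JSON side-car that [readCohortTable()] and
#' [readDosageMatrix()] read back.
#'
#' @param cohort a [T2DCohort-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"cohort"`).
#' @return invisibly, the three file paths.
#' @export
writeCohortFiles <- function(cohort, dir, prefix = "cohort") {
  stopifnot(is(cohort, "T2DCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  subjects <- file.path(dir, paste0(prefix, "_subjects.csv"))
  utils::write.csv(cd, subjects, row.names = FALSE, na = "")
  d <- t(dosages(cohort))
  dosageFile <- file.path(dir, paste0(prefix, "_dosage.csv"))
  utils::write.csv(cbind(data.frame(subject_id = rownames(d)),
                         as.data.frame(d)),
                   dosageFile, row.names = FALSE, na = "")
  truthFile <- file.path(dir, paste0(prefix, "_truth.json"))
  tr <- truthRecord(cohort)
  if (!is.null(tr)) {
    tr$params <- unclass(tr$params)
    jsonlite::write_json(tr, truthFile, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(c(subjects = subjects, dosage = dosageFile,
              truth = truthFile))
}
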
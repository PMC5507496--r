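#' Default endpoint ascertainment thresholds
#'
#' Diabetes is ascertained from any of several sources; the measurement
#' criteria are: at least `hba1c_min_count` HbA1c recordings at or above
#' `hba1c_monos_min` percent on the Swedish Mono-S scale (6.0% Mono-S
#' corresponds to 7.0% NGSP — stored as a correspondence, no conversion
#' formula is applied), fasting plasma glucose `>= fpg_min` mmol/L,
#' fasting whole-blood glucose `>= fwbg_min` mmol/L (corresponding to an
#' FPG of 7.0), or a 2-hour post-OGTT plasma glucose strictly greater
#' than `ogtt_2h_gt` mmol/L. All cut-offs are inclusive except the OGTT.
#'
#' @return named list of thresholds.
#' @export
defaultEndpointThresholds <- function() {
  list(hba1c_monos_min = 6.0, hba1c_min_count = 2L,
       hba1c_ngsp_equivalent = 7.0,
       fpg_min = 7.0, fwbg_min = 6.1, ogtt_2h_gt = 11.0)
}

#' Read endpoint thresholds from YAML
#'
#' @param path YAML file with any of the names in
#'   [defaultEndpointThresholds()]; unspecified entries keep defaults.
#' @return named list of thresholds.
#' @export
readEndpointThresholds <- function(path) {
  out <- defaultEndpointThresholds()
  y <- yaml::read_yaml(path)
  for (k in names(y)) out[[k]] <- y[[k]]
  out
}

#' Ascertain diabetes from multi-source measurements
#'
#' Returns `TRUE` if ANY source criterion fires: a registry flag; at
#' least two HbA1c (Mono-S) recordings `>= 6.0%`; fasting plasma glucose
#' `>= 7.0` mmol/L; fasting whole-blood glucose `>= 6.1` mmol/L; 2-hour
#' post-OGTT plasma glucose `> 11.0` mmol/L (strict); self-reported
#' physician diagnosis; or antidiabetic medication. An all-empty record
#' is `FALSE`. Adding a positive criterion can never flip a `TRUE` to
#' `FALSE` (the rule is a pure disjunction).
#'
#' @param hba1c_monos numeric vector of HbA1c recordings (% Mono-S).
#' @param fpg fasting plasma glucose values, mmol/L.
#' @param fwbg fasting whole-blood glucose values, mmol/L.
#' @param ogtt_2h 2-hour post-OGTT plasma glucose values, mmol/L.
#' @param registry_flags character vector of register sources that
#'   reported the subject (any non-empty entry counts).
#' @param self_report self-reported physician diagnosis (logical).
#' @param on_medication antidiabetic medication use (logical).
#' @param thresholds threshold list, see [defaultEndpointThresholds()].
#' @return logical scalar.
#' @examples
#' ascertainDiabetes(hba1c_monos = c(6.1, 6.3))  # TRUE (two recordings)
#' ascertainDiabetes(hba1c_monos = 6.1)          # FALSE (only one)
#' ascertainDiabetes(ogtt_2h = 11.0)             # FALSE (criterion is >)
#' @export
ascertainDiabetes <- function(hba1c_monos = numeric(0),
                              fpg = numeric(0), fwbg = numeric(0),
                              ogtt_2h = numeric(0),
                              registry_flags = character(0),
                              self_report = FALSE, on_medication = FALSE,
                              thresholds = defaultEndpointThresholds()) {
  th <- thresholds
  crit <- c(
    registry = length(registry_flags[nzchar(registry_flags)]) > 0,
    hba1c = sum(hba1c_monos >= th$hba1c_monos_min, na.rm = TRUE) >=
      th$hba1c_min_count,
    fpg = any(fpg >= th$fpg_min, na.rm = TRUE),
    fwbg = any(fwbg >= th$fwbg_min, na.rm = TRUE),
    ogtt = any(ogtt_2h > th$ogtt_2h_gt, na.rm = TRUE),
    self_report = isTRUE(self_report),
    medication = isTRUE(on_medication))
  any(crit)
}

#' Apply the cohort exclusion cascade
#'
#' Sequentially removes (1) subjects with prevalent diabetes at baseline,
#' (2) subjects with missing environmental risk-factor data,
#' (3) censored subjects (left the study with unknown end-of-follow-up
#' status) and (4) subjects with incomplete genotype coverage. A subject
#' failing several criteria is counted at the first failing stage, which
#' is only an attribution convention: the final analysis set is
#' independent of stage order because each stage is a pure flag filter.
#'
#' @param cohort a [T2DCohort-class] whose `colData` carries the logical
#'   columns `prevalent_t2d_baseline`, `env_complete`, `censored` and
#'   (unless `selection` is given) `genotype_complete`.
#' @param selection optional [BlockSelection-class]; when supplied,
#'   genotype completeness is derived from its `incompleteSubjects`.
#' @return list with `cohort` (the analysis set, a [T2DCohort-class])
#'   and `audit` (data.frame: `stage`, `n_before`, `n_excluded`,
#'   `n_after`).
#' @export
applyExclusions <- function(cohort, selection = NULL) {
  stopifnot(is(cohort, "T2DCohort"))
  cd <- SummarizedExperiment::colData(cohort)
  need <- c("prevalent_t2d_baseline", "env_complete", "censored")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    stop("colData is missing flag(s): ", paste(miss, collapse = ", "))
  genoComplete <- if (!is.null(selection)) {
    stopifnot(is(selection, "BlockSelection"))
    !(colnames(cohort) %in% selection@incompleteSubjects)
  } else if ("genotype_complete" %in% colnames(cd)) {
    cd$genotype_complete %in% TRUE
  } else stop("need a BlockSelection or a genotype_complete column")

  keep <- rep(TRUE, ncol(cohort))
  audit <- data.frame(stage = character(0), n_before = integer(0),
                      n_excluded = integer(0), n_after = integer(0))
  stage <- function(drop, name) {
    nBefore <- sum(keep)
    dropNow <- keep & drop
    keep <<- keep & !drop
    audit <<- rbind(audit, data.frame(
      stage = name, n_before = nBefore, n_excluded = sum(dropNow),
      n_after = sum(keep)))
  }
  stage(cd$prevalent_t2d_baseline %in% TRUE, "prevalent_t2d")
  stage(!(cd$env_complete %in% TRUE), "missing_environmental")
  stage(cd$censored %in% TRUE, "censored")
  stage(!genoComplete, "incomplete_genotype")
  list(cohort = cohort[, keep], audit = audit)
}

#' Compare excluded and included subjects on log odds ratios
#'
#' Two-sided two-sample t-tests on the logarithm of the environmental and
#' genetic odds ratios, checking that removing censored subjects did not
#' bias the risk distribution of the analysis set.
#'
#' @param includedEnv,includedGen positive OR vectors of the retained
#'   subjects.
#' @param excludedEnv,excludedGen positive OR vectors of the removed
#'   subjects.
#' @return named numeric: `p_env`, `p_gen`.
#' @export
compareExcluded <- function(includedEnv, includedGen,
                            excludedEnv, excludedGen) {
  chk <- function(x, nm) {
    x <- x[!is.na(x)]
    if (length(x) < 2) stop(nm, ": need at least 2 non-missing values")
    if (any(x <= 0)) stop(nm, ": odds ratios must be > 0")
    x
  }
  pOf <- function(a, b) {
    if (isTRUE(all.equal(stats::var(c(log(a), log(b))), 0))) return(1.0)
    stats::t.test(log(a), log(b), alternative = "two.sided")$p.value
  }
  c(p_env = pOf(chk(includedEnv, "included env"),
                chk(excludedEnv, "excluded env")),
    p_gen = pOf(chk(includedGen, "included gen"),
                chk(excludedGen, "excluded gen")))
}

#' Read a subject-level cohort table
#'
#' Delimited text (CSV/TSV) with header-named columns, one row per
#' subject; empty cells are missing. A `subject_id` column is required.
#' Endpoint register sources may be given as pipe-separated flags in an
#' `endpoint_sources` column (e.g. `"MHR|NDR"`). Repeated-measurement
#' columns (`hba1c_monos`) may hold semicolon-separated values.
#'
#' @param path file path.
#' @param envFactors optional character vector of required environmental
#'   columns; when given, an `env_complete` column is derived as "no
#'   missing value among them".
#' @return data.frame, one row per subject.
#' @export
readCohortTable <- function(path, envFactors = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (!"subject_id" %in% colnames(df))
    stop("cohort table needs a subject_id column")
  if (!is.null(envFactors)) {
    miss <- setdiff(envFactors, colnames(df))
    if (length(miss))
      stop("cohort table lacks environmental column(s): ",
           paste(miss, collapse = ", "))
    df$env_complete <- stats::complete.cases(df[envFactors])
  }
  df
}

#' Parse pipe-separated endpoint source flags
#'
#' @param x character vector like `"MHR|NDR"`; `NA`/empty means none.
#' @return list of character vectors.
#' @export
parseEndpointSources <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, "|", fixed = TRUE)[[1]]
  })
}
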
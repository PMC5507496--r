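#' Stratify a cohort into environmental and genetic risk groups
#'
#' Environmental risk groups (ERG1/ERG2) split at the median aggregate
#' environmental OR: subjects at or below the median go to ERG1. Genetic
#' risk groups (GRG1/2/3) split at the tertiles (type-7 quantiles) of the
#' aggregate genetic OR: subjects at or below a cutoff go to the lower
#' group. The two stratifications are independent, giving six cells.
#'
#' @param envORs,genORs aligned positive numeric vectors.
#' @return a [RiskGroups-class] object.
#' @examples
#' rg <- stratifyRisk(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
#' ergAssignments(rg)  # 1 1 1 2 2 2
#' grgAssignments(rg)  # 1 1 2 2 3 3
#' @export
stratifyRisk <- function(envORs, genORs) {
  if (length(envORs) != length(genORs))
    stop("envORs and genORs must be aligned")
  if (length(envORs) < 6)
    stop("need at least 6 subjects to form tertiles")
  if (anyNA(envORs) || anyNA(genORs))
    stop("odds ratios must be non-missing (exclude incomplete subjects first)")
  if (any(envORs <= 0) || any(genORs <= 0))
    stop("odds ratios must be > 0")
  envCut <- stats::median(envORs)
  genCut <- unname(stats::quantile(genORs, c(1, 2) / 3, type = 7))
  degenerate <- genCut[1] == genCut[2] ||
    envCut == min(envORs) && envCut == max(envORs)
  if (degenerate)
    warning("degenerate cutoffs: tied odds-ratio values flood one group")
  erg <- ifelse(envORs <= envCut, 1L, 2L)
  grg <- 1L + (genORs > genCut[1]) + (genORs > genCut[2])
  new("RiskGroups", erg = as.integer(erg), grg = as.integer(grg),
      envCutoff = envCut, genCutoffs = genCut, degenerate = degenerate)
}

#' Gene-by-environment stratified incidence table
#'
#' Computes the 15-year incidence in each of the six ERG x GRG cells with
#' percentile bootstrap confidence intervals, and within each ERG the
#' pairwise bootstrap p-values for differences in incidence between
#' genetic risk groups. All quantities come from one set of cohort-level
#' resamples (subjects resampled with replacement; cell membership and
#' incidences recomputed per resample), so the pairwise comparisons are
#' paired.
#'
#' @param groups a [RiskGroups-class].
#' @param labels aligned 0/1 (or logical) incident-case labels.
#' @param B number of bootstrap resamples (default 10000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return an [IncidenceTable-class] object.
#' @export
incidenceTable <- function(groups, labels, B = 10000L, seed = 1L,
                           level = 0.95) {
  stopifnot(is(groups, "RiskGroups"))
  labels <- as.numeric(labels)
  n <- length(labels)
  if (n != length(groups@erg)) stop("labels must align with groups")
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be 0/1 with no missing values")
  cell <- (groups@erg - 1L) * 3L + groups@grg   # 1..6, ERG-major
  cellN <- tabulate(cell, 6L)
  cellCases <- vapply(1:6, function(k) sum(labels[cell == k]), numeric(1))
  inc <- ifelse(cellN > 0, cellCases / cellN, NA_real_)

  bootInc <- matrix(NA_real_, B, 6L)
  withSeed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      cb6 <- tabulate(cell[idx][labels[idx] == 1], 6L)
      nb6 <- tabulate(cell[idx], 6L)
      bootInc[b, ] <- ifelse(nb6 > 0, cb6 / nb6, NA_real_)
    }
  })
  alpha <- (1 - level) / 2
  ci <- apply(bootInc, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE, type = 7)
  grid <- data.frame(
    erg = rep(1:2, each = 3), grg = rep(1:3, 2),
    n = cellN, cases = cellCases, incidence = inc,
    ci_low = ci[1, ], ci_high = ci[2, ])

  pairs <- data.frame(grg_a = c(3L, 3L, 2L), grg_b = c(1L, 2L, 1L))
  pw <- do.call(rbind, lapply(1:2, function(e) {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      a <- (e - 1L) * 3L + pairs$grg_a[i]
      b <- (e - 1L) * 3L + pairs$grg_b[i]
      deltas <- bootInc[, a] - bootInc[, b]
      deltas <- deltas[!is.na(deltas)]
      p <- if (length(deltas)) {
        if (all(deltas == 0)) 1.0 else signCrossP(deltas)$p
      } else NA_real_
      data.frame(erg = e, grg_a = pairs$grg_a[i], grg_b = pairs$grg_b[i],
                 delta = inc[a] - inc[b], p_value = p)
    }))
  }))
  new("IncidenceTable", grid = grid, pairwise = pw,
      nResamples = as.integer(B), seed = as.integer(seed), level = level)
}

#' Pearson correlation between genetic odds ratio and case status
#'
#' Standard Pearson r of the raw aggregate genetic OR against the 0/1
#' incident-case label, with a percentile bootstrap CI and a two-sided
#' sign-crossing bootstrap p-value for r != 0. Set `useLog = TRUE` to
#' correlate log genetic ORs instead.
#'
#' @param genORs positive numeric vector.
#' @param labels aligned 0/1 labels.
#' @param B,seed,level bootstrap configuration.
#' @param useLog correlate `log(genORs)` instead of raw ORs.
#' @return a [BootstrapResult-class].
#' @export
pearsonCaseCorrelation <- function(genORs, labels, B = 10000L, seed = 1L,
                                   level = 0.95, useLog = FALSE) {
  x <- if (useLog) log(genORs) else genORs
  y <- as.numeric(labels)
  if (length(x) != length(y)) stop("vectors must be aligned")
  if (length(x) < 3) stop("need at least 3 subjects")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  r <- stats::cor(x, y)
  res <- bootApply(length(x), B, seed, function(idx, b) {
    xb <- x[idx]; yb <- y[idx]
    if (stats::sd(xb) == 0 || stats::sd(yb) == 0) NA_real_
    else stats::cor(xb, yb)
  })
  makeBootstrapResult("pearson_r_gen_vs_case", r, res, seed, level)
}

#' Area under the ROC curve by pair concordance
#'
#' The probability that a randomly chosen case scores above a randomly
#' chosen control, ties counted half:
#' `AUC = (wins + 0.5 ties) / (cases x controls)`. Computed via the
#' rank-sum identity, equivalent to exhaustive pair enumeration and
#' invariant under any strictly monotone transform of the scores.
#'
#' @param scores numeric risk scores.
#' @param labels aligned 0/1 (or logical) case labels; both classes must
#'   be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' aucConcordance(c(1, 2, 2, 3), c(0, 1, 0, 1))  # 0.875
#' @export
aucConcordance <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("vectors must be aligned")
  if (anyNA(scores) || anyNA(labels)) stop("missing values not allowed")
  nCase <- sum(labels == 1)
  nCtrl <- sum(labels == 0)
  if (nCase == 0 || nCtrl == 0)
    stop("AUC needs at least one case and one control")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - nCase * (nCase + 1) / 2) / (nCase * nCtrl)
}

#' Paired bootstrap comparison of two risk scores' AUCs
#'
#' Computes the AUC of both scores and the bootstrap distribution of
#' their difference: every resample draws one set of subjects and
#' recomputes BOTH AUCs on it, so the difference is paired. The p-value
#' is the two-sided sign-crossing fraction, clamped to `[1/B, 1]` and
#' flagged as a bound ("< 1/B") when no resample crosses zero.
#'
#' @param scoresA,scoresB aligned risk-score vectors (e.g. environmental
#'   OR and combined OR).
#' @param labels aligned 0/1 case labels.
#' @param B,seed,level bootstrap configuration.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param onResample optional instrumentation hook `function(b, idx)`
#'   called with each resample's index vector (used to verify pairing).
#' @return list with `auc_a`, `auc_b` and `delta` (a
#'   [BootstrapResult-class] for `auc_b - auc_a`).
#' @export
compareAUCs <- function(scoresA, scoresB, labels, B = 10000L, seed = 1L,
                        level = 0.95, alternative = "two.sided",
                        onResample = NULL) {
  labels <- as.numeric(labels)
  n <- length(labels)
  if (length(scoresA) != n || length(scoresB) != n)
    stop("vectors must be aligned")
  aucA <- aucConcordance(scoresA, labels)
  aucB <- aucConcordance(scoresB, labels)
  deltas <- rep(NA_real_, B)
  withSeed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (!is.null(onResample)) onResample(b, idx)
      lb <- labels[idx]
      if (all(lb == 1) || all(lb == 0)) next  # degenerate resample
      deltas[b] <- aucConcordance(scoresB[idx], lb) -
        aucConcordance(scoresA[idx], lb)
    }
  })
  ok <- deltas[!is.na(deltas)]
  est <- aucB - aucA
  dRes <- if (all(ok == 0)) {
    # identical scores: delta is exactly zero in every resample
    new("BootstrapResult", statistic = "auc_delta", estimate = est,
        ciLow = 0, ciHigh = 0, pValue = 1.0, pBound = FALSE,
        nResamples = as.integer(B), seed = as.integer(seed),
        level = level, resamples = as.numeric(deltas))
  } else {
    makeBootstrapResult("auc_delta", est, deltas, seed, level, alternative)
  }
  list(auc_a = aucA, auc_b = aucB, delta = dRes)
}

#' Bootstrap confidence interval for one score's AUC
#'
#' @param scores,labels aligned score and 0/1 label vectors.
#' @param B,seed,level bootstrap configuration.
#' @return a [BootstrapResult-class] (p-value refers to AUC - 0.5).
#' @export
aucBootstrap <- function(scores, labels, B = 10000L, seed = 1L,
                         level = 0.95) {
  labels <- as.numeric(labels)
  est <- aucConcordance(scores, labels)
  res <- bootApply(length(labels), B, seed, function(idx, b) {
    lb <- labels[idx]
    if (all(lb == 1) || all(lb == 0)) return(NA_real_)
    aucConcordance(scores[idx], lb)
  })
  out <- makeBootstrapResult("auc", est, res, seed, level)
  pv <- signCrossP(res[!is.na(res)] - 0.5)
  out@pValue <- pv$p
  out@pBound <- pv$bound
  out
}

#' Read a point-based comparator risk score configuration
#'
#' YAML with a `name` and a `variables:` list; each variable has a
#' `factor` (cohort column), a `kind` (`continuous`/`categorical`) and
#' `points:` as either lower-bound bins (continuous, half-open
#' `[low, high)` like the risk models) or category labels.
#'
#' @param path YAML file.
#' @return list of class `point_score_config`.
#' @export
readPointScoreConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$name) || is.null(y$variables))
    stop("point-score config needs 'name' and 'variables'")
  structure(y, class = "point_score_config")
}

#' Evaluate a point-based comparator risk score
#'
#' Sums the per-variable points of a published point-table risk score
#' (e.g. the Finnish FINDRISC-style or Framingham-Offspring-style
#' comparators) over subject profiles. Deterministic; an unresolvable
#' variable is an error naming it.
#'
#' @param config a `point_score_config` (see [readPointScoreConfig()]).
#' @param data subject-level data.frame (one row per subject).
#' @return numeric vector of total points.
#' @export
pointScore <- function(config, data) {
  if (!inherits(config, "point_score_config"))
    stop("config must be a point_score_config")
  total <- numeric(nrow(data))
  for (v in config$variables) {
    if (!v$factor %in% colnames(data))
      stop("point score '", config$name, "': variable '", v$factor,
           "' not found in the data")
    x <- data[[v$factor]]
    if (anyNA(x))
      stop("point score '", config$name, "': variable '", v$factor,
           "' has missing values")
    pts <- unlist(v$points)
    if (identical(v$kind, "continuous")) {
      lo <- as.numeric(names(pts))
      o <- order(lo)
      idx <- findInterval(as.numeric(x), lo[o])
      if (any(idx == 0))
        stop("point score '", config$name, "': value of '", v$factor,
             "' below the declared range")
      total <- total + unname(pts[o][idx])
    } else {
      idx <- match(as.character(x), names(pts))
      if (anyNA(idx))
        stop("point score '", config$name, "': category of '", v$factor,
             "' outside the declared set")
      total <- total + unname(pts[idx])
    }
  }
  total
}

#' Sensitivity/specificity operating points of two scores
#'
#' For each specificity value on a grid, the best achievable sensitivity
#' of each score (and symmetrically, for each sensitivity value the best
#' specificity), with the paired gain of score B over score A and the
#' maximal gains. A 1% AUC advantage typically surfaces as a few-percent
#' sensitivity or specificity gain at matched operating points.
#'
#' @param scoresA,scoresB aligned risk scores.
#' @param labels aligned 0/1 case labels.
#' @param grid target values (default `seq(0.05, 0.95, 0.05)`).
#' @return list with data.frames `by_specificity` (`target`, `sens_a`,
#'   `sens_b`, `gain`) and `by_sensitivity` (`target`, `spec_a`,
#'   `spec_b`, `gain`), plus `max_sensitivity_gain` and
#'   `max_specificity_gain`.
#' @export
sensitivitySpecificityGain <- function(scoresA, scoresB, labels,
                                       grid = seq(0.05, 0.95, 0.05)) {
  labels <- as.numeric(labels)
  roc <- function(s) {
    # thresholds "predict positive if score >= t"; sweep unique scores
    o <- order(s, decreasing = TRUE)
    tp <- cumsum(labels[o] == 1)
    fp <- cumsum(labels[o] == 0)
    keep <- !duplicated(s[o][seq_along(o)], fromLast = TRUE)
    sens <- c(0, tp[keep] / sum(labels == 1))
    spec <- c(1, 1 - fp[keep] / sum(labels == 0))
    list(sens = sens, spec = spec)
  }
  ra <- roc(scoresA)
  rb <- roc(scoresB)
  sensAt <- function(r, specTarget)
    vapply(specTarget, function(t) {
      ok <- r$spec >= t
      if (any(ok)) max(r$sens[ok]) else 0
    }, numeric(1))
  specAt <- function(r, sensTarget)
    vapply(sensTarget, function(t) {
      ok <- r$sens >= t
      if (any(ok)) max(r$spec[ok]) else 0
    }, numeric(1))
  bySpec <- data.frame(target = grid,
                       sens_a = sensAt(ra, grid), sens_b = sensAt(rb, grid))
  bySpec$gain <- bySpec$sens_b - bySpec$sens_a
  bySens <- data.frame(target = grid,
                       spec_a = specAt(ra, grid), spec_b = specAt(rb, grid))
  bySens$gain <- bySens$spec_b - bySens$spec_a
  list(by_specificity = bySpec, by_sensitivity = bySens,
       max_sensitivity_gain = max(bySpec$gain),
       max_specificity_gain = max(bySens$gain))
}
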
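test_that("median split and tertiles follow the documented conventions", {
  rg <- stratifyRisk(c(1, 2, 3, 4, 10, 11), c(1, 2, 3, 4, 5, 6))
  expect_equal(envCutoff(rg), 3.5)
  expect_equal(ergAssignments(rg), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(grgAssignments(rg), c(1L, 1L, 2L, 2L, 3L, 3L))
  # subjects exactly at the median go to ERG1
  rg2 <- stratifyRisk(c(1, 2, 2, 2, 4, 5), rep(c(1, 2, 3), 2))
  expect_equal(envCutoff(rg2), 2)
  expect_equal(sum(ergAssignments(rg2) == 1), 4)
  expect_error(stratifyRisk(1:4, 1:4), "at least 6")
  expect_warning(rg3 <- stratifyRisk(rep(2, 8), rep(3, 8)), "degenerate")
  expect_true(all(ergAssignments(rg3) == 1L & grgAssignments(rg3) == 1L))
})

test_that("group sizes are balanced up to ties and cells partition the cohort", {
  set.seed(13)
  env <- exp(rnorm(901)); gen <- exp(rnorm(901))
  rg <- stratifyRisk(env, gen)
  expect_lte(abs(diff(tabulate(ergAssignments(rg), 2))), 1)
  expect_lte(max(tabulate(grgAssignments(rg), 3)) -
               min(tabulate(grgAssignments(rg), 3)), 1)
  # cutoffs reproduce membership deterministically
  expect_equal(ergAssignments(rg),
               ifelse(env <= envCutoff(rg), 1L, 2L))
  cuts <- genCutoffs(rg)
  expect_equal(grgAssignments(rg),
               1L + (gen > cuts[1]) + (gen > cuts[2]))
})

test_that("incidence table cells are exact ratios that sum over the cohort", {
  grp <- new("RiskGroups",
             erg = rep(1:2, each = 150)[sample(300)],
             grg = rep(1:3, 100)[sample(300)],
             envCutoff = 1, genCutoffs = c(0.9, 1.1))
  set.seed(3)
  lab <- rbinom(300, 1, 0.1)
  it <- incidenceTable(grp, lab, B = 200, seed = 4)
  g <- incidenceGrid(it)
  expect_equal(sum(g$n), 300)
  expect_equal(sum(g$cases), sum(lab))
  expect_equal(g$incidence, g$cases / g$n)
  # all-zero labels: zero incidence, pairwise p-values all 1
  it0 <- incidenceTable(grp, rep(0, 300), B = 100, seed = 4)
  expect_true(all(incidenceGrid(it0)$incidence == 0))
  expect_true(all(pairwisePValues(it0)$p_value == 1))
})

test_that("bootstrap CIs cover the generating incidences at nominal rate", {
  # truth set to the published 2x3 grid; n ~ 571 per cell
  truth <- matrix(c(0.033, 0.044, 0.082, 0.158, 0.193, 0.194), 2, 3,
                  byrow = TRUE)
  nCell <- 571
  erg <- rep(1:2, each = 3 * nCell)
  grg <- rep(rep(1:3, each = nCell), 2)
  covered <- 0; total <- 0
  for (s in 1:60) {
    set.seed(1000 + s)
    lab <- rbinom(length(erg), 1, truth[cbind(erg, grg)])
    grp <- new("RiskGroups", erg = as.integer(erg), grg = as.integer(grg),
               envCutoff = 1, genCutoffs = c(0.9, 1.1))
    it <- incidenceTable(grp, lab, B = 250, seed = s)
    g <- incidenceGrid(it)
    hit <- truth[cbind(g$erg, g$grg)] >= g$ci_low &
      truth[cbind(g$erg, g$grg)] <= g$ci_high
    covered <- covered + sum(hit); total <- total + length(hit)
  }
  expect_gte(covered / total, 0.90)
})

test_that("Pearson case-status correlation matches the closed form", {
  r <- pearsonCaseCorrelation(c(1, 2, 3, 4), c(0, 0, 1, 1), B = 200,
                              seed = 1)
  expect_equal(bootEstimate(r), 2 / sqrt(5), tolerance = 1e-12)
  r1 <- pearsonCaseCorrelation(c(0, 1, 0, 1, 1, 0), c(0, 1, 0, 1, 1, 0),
                               B = 100, seed = 1)
  expect_equal(bootEstimate(r1), 1.0)
  expect_error(pearsonCaseCorrelation(rep(1, 10), rbinom(10, 1, 0.5),
                                      B = 10, seed = 1), "constant")
  # independent labels: r near zero, p not extreme
  set.seed(21)
  g <- exp(rnorm(800)); l <- rbinom(800, 1, 0.15)
  r0 <- pearsonCaseCorrelation(g, l, B = 400, seed = 2)
  expect_lt(abs(bootEstimate(r0)), 0.1)
  expect_true(bootPValue(r0) >= 1 / 400 && bootPValue(r0) <= 1)
})

test_that("AUC equals exhaustive pair counting, including ties", {
  expect_equal(aucConcordance(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(aucConcordance(c(1, 2, 2, 3), c(0, 1, 0, 1)), 0.875)
  set.seed(17)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    s <- sample(round(rnorm(n, 0, 2), sample(0:2, 1)))  # induce ties
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_equal(aucConcordance(s, l), aucBruteForce(s, l),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(23)
  s <- rnorm(150); l <- rbinom(150, 1, 0.3)
  a <- aucConcordance(s, l)
  expect_equal(aucConcordance(exp(s), l), a)
  expect_equal(aucConcordance(5 * s - 2, l), a)
  expect_equal(aucConcordance(rank(s, ties.method = "average"), l), a)
  expect_error(aucConcordance(s, rep(1, 150)), "case and one control")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  s <- round(rnorm(300), 1); l <- rbinom(300, 1, 0.25)
  expect_equal(aucConcordance(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("null AUC concentrates at one half", {
  aucs <- vapply(31:35, function(sd) {
    set.seed(sd)
    s <- rnorm(10000); l <- rbinom(10000, 1, 0.3)
    aucConcordance(s, l)
  }, numeric(1))
  expect_true(all(abs(aucs - 0.5) < 0.02))
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("paired AUC comparison shares resample indices and is deterministic", {
  set.seed(37)
  s <- rnorm(120); l <- rbinom(120, 1, 0.4)
  s2 <- s + rnorm(120, 0, 0.2)
  seen <- list()
  res <- compareAUCs(s, s2, l, B = 50, seed = 9,
                     onResample = function(b, idx) seen[[b]] <<- idx)
  expect_length(seen, 50)
  # rerun under the same seed: identical resamples, identical result
  seen2 <- list()
  res2 <- compareAUCs(s, s2, l, B = 50, seed = 9,
                      onResample = function(b, idx) seen2[[b]] <<- idx)
  expect_identical(seen, seen2)
  expect_identical(res$delta@resamples, res2$delta@resamples)
  # identical scores: delta exactly zero with p = 1
  same <- compareAUCs(s, s, l, B = 100, seed = 2)
  expect_equal(same$delta@estimate, 0)
  expect_equal(bootPValue(same$delta), 1.0)
})

test_that("pure-noise additions to a score are not declared improvements", {
  set.seed(41)
  hits <- 0
  for (i in 1:20) {
    n <- 600
    a <- rnorm(n)
    l <- rbinom(n, 1, plogis(1.2 * a - 2))
    if (length(unique(l)) < 2) next
    b <- a + rnorm(n, 0, 1)      # same signal plus noise
    res <- compareAUCs(a, b, l, B = 200, seed = i)
    if (bootPValue(res$delta) < 0.05 && res$delta@estimate > 0)
      hits <- hits + 1
  }
  expect_lte(hits, 1)  # at most 5% false improvement calls
})

test_that("a genuine combined-score signal is detected", {
  co <- generateCohort(synthParams(nSubjects = 3426, seed = 1))
  cat <- filteredDefaultCatalogue()
  sel <- selectBlockRepresentatives(cat, co)
  cd <- as.data.frame(SummarizedExperiment::colData(co))
  env <- cohortEnvironmentalOR(cd, defaultRiskModels())
  gen <- aggregateGeneticOR(co, sel, cat)
  lab <- as.numeric(cd$incident_t2d)
  res <- compareAUCs(env, env * gen, lab, B = 500, seed = 1)
  expect_gt(res$delta@estimate, 0)
  expect_lt(bootPValue(res$delta), 0.05)
})

test_that("bootstrap results are deterministic and internally consistent", {
  set.seed(43)
  g <- exp(rnorm(400)); l <- rbinom(400, 1, 0.2)
  r1 <- pearsonCaseCorrelation(g, l, B = 300, seed = 5)
  r2 <- pearsonCaseCorrelation(g, l, B = 300, seed = 5)
  expect_identical(r1@resamples, r2@resamples)
  expect_identical(bootCI(r1), bootCI(r2))
  # percentile CI brackets the resample median
  expect_lte(r1@ciLow, median(r1@resamples))
  expect_gte(r1@ciHigh, median(r1@resamples))
  expect_true(bootPValue(r1) >= 1 / 300 && bootPValue(r1) <= 1)
})

test_that("point scores sum bin points and fail on unresolvable variables", {
  cfg <- structure(list(name = "toy", variables = list(
    list(factor = "age", kind = "continuous",
         points = list("0" = 0, "45" = 2)),
    list(factor = "bmi", kind = "continuous",
         points = list("0" = 0, "25" = 1)))),
    class = "point_score_config")
  expect_equal(pointScore(cfg, data.frame(age = 57, bmi = 25.6)), 3)
  expect_equal(pointScore(cfg, data.frame(age = 30, bmi = 20)), 0)
  expect_error(pointScore(cfg, data.frame(age = 57)), "bmi")
  cfgs <- defaultPointScoreConfigs()
  co <- generateCohort(synthParams(nSubjects = 200, seed = 5))
  cd <- as.data.frame(SummarizedExperiment::colData(co))
  for (cc in cfgs) expect_true(all(is.finite(pointScore(cc, cd))))
})

test_that("operating-point gains follow ROC dominance", {
  set.seed(47)
  l <- rbinom(400, 1, 0.3)
  perfect <- l + rnorm(400, 0, 1e-6)
  noise <- rnorm(400)
  same <- sensitivitySpecificityGain(noise, noise, l)
  expect_true(all(same$by_specificity$gain == 0))
  expect_true(all(same$by_sensitivity$gain == 0))
  dom <- sensitivitySpecificityGain(noise, perfect, l)
  expect_true(all(dom$by_specificity$sens_b >= 0.999))
  expect_gt(dom$max_sensitivity_gain, 0.3)
  # threshold-sweep oracle at one grid point
  sweepSens <- function(s, spec) {
    th <- sort(unique(s))
    best <- 0
    for (t in th) {
      sp <- mean(s[l == 0] < t)
      if (sp >= spec) best <- max(best, mean(s[l == 1] >= t))
    }
    best
  }
  g <- sensitivitySpecificityGain(noise, perfect, l, grid = 0.8)
  expect_equal(g$by_specificity$sens_a, sweepSens(noise, 0.8),
               tolerance = 1e-12)
})
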
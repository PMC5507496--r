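test_that("factor OR lookup matches declared categories and bins", {
  m <- tinyModels()
  expect_equal(factorOR(m[[1]], "never"), 1.0)
  expect_equal(factorOR(m[[1]], c("past", "current")), c(1.2, 1.6))
  # half-open [low, high) bins; 25.6 falls in [25, 30)
  expect_equal(factorOR(m[[2]], 25.6), 1.5)
  # boundary value falls in the upper bin
  expect_equal(factorOR(m[[2]], c(25, 30, 24.999)), c(1.5, 2.2, 1.0))
  expect_true(is.na(factorOR(m[[2]], NA)))
})

test_that("out-of-range and unknown values raise errors naming the factor", {
  m <- tinyModels()
  expect_error(factorOR(m[[2]], -3), "bmi")
  expect_error(factorOR(m[[1]], "pipe"), "smoking")
})

test_that("medication override forces the maximal OR", {
  bp <- tinyModels()[[3]]
  expect_equal(factorOR(bp, 120), 1.0)
  expect_equal(factorOR(bp, 120, onOverride = TRUE), 2.0)
  # override applies even when the measurement is missing
  expect_equal(factorOR(bp, NA, onOverride = TRUE), 2.0)
})

test_that("environmental aggregation is a product over factors", {
  models <- list(
    riskFactorModel("a", "categorical", c(x = 1.5)),
    riskFactorModel("b", "categorical", c(x = 2.0)),
    riskFactorModel("c", "categorical", c(x = 0.8)))
  prof <- data.frame(a = "x", b = "x", c = "x")
  expect_equal(aggregateEnvironmentalOR(prof, models)$env_or, 2.4)
  # all-reference profile
  ref <- lapply(models, function(m) m)
  for (i in seq_along(ref)) ref[[i]]@ors <- 1.0
  expect_equal(aggregateEnvironmentalOR(prof, ref)$env_or, 1.0)
})

test_that("a 13-factor profile with a dominant age OR lands at the product", {
  ors <- c(40, 1.7, rep(1, 11))
  models <- lapply(seq_along(ors), function(i)
    riskFactorModel(paste0("f", i), "categorical",
                    stats::setNames(ors[i], "x")))
  prof <- as.data.frame(as.list(stats::setNames(rep("x", 13),
                                                paste0("f", 1:13))))
  expect_equal(aggregateEnvironmentalOR(prof, models)$env_or, 68.0,
               tolerance = 1e-12)
})

test_that("aggregation is order-invariant and monotone in any factor", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    ors <- round(runif(k, 0.5, 3), 3)
    models <- lapply(seq_len(k), function(i)
      riskFactorModel(paste0("f", i), "categorical",
                      stats::setNames(ors[i], "x")))
    prof <- as.data.frame(as.list(stats::setNames(rep("x", k),
                                                  paste0("f", 1:k))))
    e1 <- aggregateEnvironmentalOR(prof, models)$env_or
    e2 <- aggregateEnvironmentalOR(prof, sample(models))$env_or
    expect_identical(e1, e2)
    # raise one factor's OR: env OR must not decrease
    j <- sample(k, 1)
    models[[j]]@ors <- models[[j]]@ors * 1.5
    expect_gte(aggregateEnvironmentalOR(prof, models)$env_or, e1)
  }
})

test_that("empty factor list returns reference OR with a warning", {
  expect_warning(res <- aggregateEnvironmentalOR(data.frame(x = 1),
                                                 list()),
                 "empty factor list")
  expect_equal(res$env_or, 1.0)
  expect_error(aggregateEnvironmentalOR(data.frame(x = 1), list(),
                                        strict = TRUE))
})

test_that("missing factor values propagate as NA (or error in strict mode)", {
  models <- tinyModels()[1:2]
  prof <- data.frame(smoking = "past", bmi = NA_real_)
  expect_true(is.na(aggregateEnvironmentalOR(prof, models)$env_or))
  expect_error(aggregateEnvironmentalOR(prof, models, strict = TRUE),
               "bmi")
  co <- data.frame(smoking = c("past", "never"), bmi = c(NA, 24))
  expect_equal(cohortEnvironmentalOR(co, models), c(NA, 1.0))
})

test_that("RR/OR conversion follows the closed form and round-trips", {
  expect_equal(rrToOR(1.0, 0.1)$or, 1.0)
  expect_equal(rrToOR(1.0, 0.1)$relative_error, 0)
  # p0 = 0.1, OR = 2: RR = 2/(0.9 + 0.2) and 9.09% relative error
  expect_equal(orToRR(2.0, 0.1), 2 / 1.1, tolerance = 1e-12)
  conv <- rrToOR(orToRR(2.0, 0.1), 0.1)
  expect_equal(conv$or, 2.0, tolerance = 1e-9)
  expect_equal(conv$relative_error, (2 - 2 / 1.1) / 2, tolerance = 1e-9)
  # rare-disease limit: measures coincide
  expect_equal(rrToOR(c(0.5, 1.3, 7), 0)$or, c(0.5, 1.3, 7))
  expect_error(rrToOR(3, 0.5), "incompatible")
})

test_that("OR -> RR -> OR round-trips across a parameter grid", {
  ors <- c(0.2, 0.8, 1, 1.5, 2, 5, 20)
  for (p0 in c(0, 0.01, 0.05, 0.1, 0.3)) {
    back <- rrToOR(orToRR(ors, p0), p0)$or
    expect_equal(back, ors, tolerance = 1e-9)
  }
})

test_that("combineOR multiplies and rejects non-positive input", {
  expect_equal(combineOR(1, 1), 1)
  expect_equal(combineOR(68.32, 0.755), 51.5816, tolerance = 1e-6)
  expect_equal(combineOR(2, 0.5), 1)
  expect_equal(combineOR(2, 3), combineOR(3, 2))
  expect_error(combineOR(-1, 2), "> 0")
})

test_that("validity check reports non-OR source measures without transforming", {
  models <- list(
    riskFactorModel("x", "categorical", c(a = 1, b = 1.8),
                    sourceMeasure = "RR", sourcePrevalence = 0.08),
    riskFactorModel("y", "categorical", c(a = 1, b = 3.5),
                    sourceMeasure = "HR", sourcePrevalence = 0.1),
    riskFactorModel("z", "categorical", c(a = 1.2)))
  chk <- checkApproximationValidity(models)
  expect_equal(nrow(chk), 2)            # OR-source factor not checked
  expect_true(chk$valid[chk$factor_id == "x"])
  expect_false(chk$valid[chk$factor_id == "y"])  # OR 3.5 at p0 0.1
  # stored values untouched
  expect_equal(factorOR(models[[1]], "b"), 1.8)
})

test_that("risk model YAML round-trips through the reader", {
  models <- defaultRiskModels()
  expect_length(models, 13)
  expect_s4_class(models$age, "RiskFactorModel")
  expect_true(models$age@ageDependent)
  expect_equal(models$family_history@role, "family_history")
  expect_true("on_antihypertensive" %in%
                models$hypertension@medicationOverrides)
  # 12 standard factors enter the environmental score
  expect_equal(sum(vapply(models, function(m) m@role == "standard",
                          logical(1))), 12)
})
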
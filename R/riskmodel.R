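#' Create an environmental risk-factor odds-ratio model
#'
#' @param factorId identifier, e.g. `"bmi"`.
#' @param valueKind `"categorical"` or `"continuous"`.
#' @param ors named numeric vector of odds ratios. For a categorical
#'   factor the names are the (exhaustive) category labels; for a
#'   continuous factor the names are the lower bin bounds, bins are
#'   half-open `[low, high)` with the last bin open above, so a value
#'   exactly at a bound falls in the upper bin.
#' @param ageDependent whether the curve is indexed by baseline age.
#' @param medicationOverrides medication flags that force the factor's
#'   maximal OR regardless of the measured value.
#' @param sourceMeasure published effect measure: `"OR"`, `"RR"` or
#'   `"HR"`. Non-OR measures are stored as-is (treated as an OR
#'   approximation); their rare-disease validity can be checked with
#'   [checkApproximationValidity()].
#' @param sourcePrevalence unexposed-group disease prevalence used for
#'   that validity check.
#' @param role `"standard"`, `"family_history"` or `"optional"`; only
#'   standard factors enter [aggregateEnvironmentalOR()] by default.
#' @return a [RiskFactorModel-class] object.
#' @examples
#' smoking <- riskFactorModel("smoking", "categorical",
#'   c(never = 1.0, past = 1.2, current = 1.6))
#' bmi <- riskFactorModel("bmi", "continuous",
#'   c("0" = 1.0, "25" = 1.5, "30" = 2.2))
#' factorOR(bmi, 25.6)   # falls in [25, 30) -> 1.5
#' @export
riskFactorModel <- function(factorId, valueKind, ors, ageDependent = FALSE,
                            medicationOverrides = character(0),
                            sourceMeasure = "OR", sourcePrevalence = NA_real_,
                            role = "standard") {
  if (is.null(names(ors)) || any(!nzchar(names(ors))))
    stop("ors must be fully named (categories or lower bin bounds)")
  if (valueKind == "continuous") {
    breaks <- as.numeric(names(ors))
    if (anyNA(breaks))
      stop("continuous factor '", factorId,
           "': names of ors must be numeric lower bounds")
    o <- order(breaks)
    new("RiskFactorModel", factorId = factorId, valueKind = valueKind,
        breaks = breaks[o], ors = unname(ors[o]),
        ageDependent = ageDependent,
        medicationOverrides = medicationOverrides,
        sourceMeasure = sourceMeasure, sourcePrevalence = sourcePrevalence,
        role = role)
  } else {
    new("RiskFactorModel", factorId = factorId, valueKind = valueKind,
        categories = names(ors), ors = unname(ors),
        ageDependent = ageDependent,
        medicationOverrides = medicationOverrides,
        sourceMeasure = sourceMeasure, sourcePrevalence = sourcePrevalence,
        role = role)
  }
}

#' Look up a subject's odds ratio for one risk factor
#'
#' Vectorised over subjects. If any of the factor's medication-override
#' flags is set for a subject, that subject receives the factor's maximal
#' OR regardless of the measured value (a treated value no longer reflects
#' the underlying risk).
#'
#' @param model a [RiskFactorModel-class].
#' @param values subject values: numbers for a continuous factor,
#'   category labels for a categorical one. `NA` means missing.
#' @param onOverride logical vector (recycled scalar allowed): whether the
#'   subject carries one of the factor's override medications.
#' @return numeric vector of odds ratios; `NA` where the value is missing.
#' @details A value below the lowest declared bound, or a label outside
#'   the declared category set, is an error naming the factor; missing
#'   values propagate as `NA` so the caller decides exclusion.
#' @export
factorOR <- function(model, values, onOverride = FALSE) {
  stopifnot(is(model, "RiskFactorModel"))
  onOverride <- rep_len(as.logical(onOverride), length(values))
  onOverride[is.na(onOverride)] <- FALSE
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  if (model@valueKind == "continuous") {
    v <- suppressWarnings(as.numeric(values[ok]))
    if (anyNA(v))
      stop("factor '", model@factorId, "': non-numeric value supplied")
    idx <- findInterval(v, model@breaks)
    if (any(idx == 0))
      stop("factor '", model@factorId, "': value below the declared range (",
           format(min(v[idx == 0])), " < ", format(model@breaks[1]), ")")
    out[ok] <- model@ors[idx]
  } else {
    idx <- match(as.character(values[ok]), model@categories)
    if (anyNA(idx))
      stop("factor '", model@factorId, "': value(s) outside declared ",
           "categories: ",
           paste(unique(values[ok][is.na(idx)]), collapse = ", "))
    out[ok] <- model@ors[idx]
  }
  # medication implies the maximal OR even when the measured value is missing
  out[onOverride] <- max(model@ors)
  out
}

#' Aggregate a subject's environmental odds ratio
#'
#' Multiplies the per-factor odds ratios of all `"standard"`-role models
#' over one subject profile. The product is accumulated in log space, so
#' the result is exactly order-invariant and robust to many factors.
#'
#' @param profile a one-row data.frame (or named list) with one column
#'   per `factorId`, plus optional logical medication-flag columns named
#'   after the models' `medicationOverrides`.
#' @param models a list of [RiskFactorModel-class] objects.
#' @param strict when `TRUE` a missing required value is an error; when
#'   `FALSE` (default) missing standard factors make the result `NA`.
#'   An empty model list returns 1.0 with a warning (all-reference
#'   profile), or errors under `strict`.
#' @return a list with `env_or` and `factors_used`.
#' @examples
#' models <- list(
#'   riskFactorModel("smoking", "categorical",
#'                   c(never = 1, past = 1.5, current = 2)),
#'   riskFactorModel("bmi", "continuous", c("0" = 1, "25" = 2)))
#' aggregateEnvironmentalOR(
#'   data.frame(smoking = "past", bmi = 26), models)$env_or  # 1.5 * 2 = 3
#' @export
aggregateEnvironmentalOR <- function(profile, models, strict = FALSE) {
  models <- Filter(function(m) m@role == "standard", models)
  if (!length(models)) {
    if (strict) stop("no standard risk-factor models supplied")
    warning("empty factor list: returning reference env_or = 1")
    return(list(env_or = 1.0, factors_used = character(0)))
  }
  # accumulate in a canonical factor order so the product is
  # bit-for-bit invariant under permutation of the model list
  models <- models[order(vapply(models, function(m) m@factorId,
                                character(1)))]
  prof <- as.list(profile)
  logSum <- 0
  used <- character(0)
  for (m in models) {
    v <- prof[[m@factorId]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) {
      if (strict)
        stop("subject is missing required factor '", m@factorId, "'")
      return(list(env_or = NA_real_, factors_used = used))
    }
    ov <- FALSE
    for (flag in m@medicationOverrides)
      if (isTRUE(as.logical(prof[[flag]]))) ov <- TRUE
    logSum <- logSum + log(factorOR(m, v, ov))
    used <- c(used, m@factorId)
  }
  list(env_or = exp(logSum), factors_used = used)
}

#' Environmental odds ratios for a whole cohort
#'
#' Vectorised cohort-level version of [aggregateEnvironmentalOR()]: one
#' [factorOR()] call per model over all subjects, products accumulated in
#' log space.
#'
#' @param data subject-level data.frame (one row per subject) with one
#'   column per factor and logical medication-flag columns.
#' @param models list of [RiskFactorModel-class] objects; only
#'   `"standard"`-role models enter the product unless `roles` says
#'   otherwise.
#' @param roles model roles to include (default `"standard"`).
#' @return numeric vector of aggregate environmental ORs, `NA` for
#'   subjects missing any required factor.
#' @export
cohortEnvironmentalOR <- function(data, models, roles = "standard") {
  models <- Filter(function(m) m@role %in% roles, models)
  if (!length(models)) {
    warning("empty factor list: returning reference env_or = 1")
    return(rep(1.0, nrow(data)))
  }
  models <- models[order(vapply(models, function(m) m@factorId,
                                character(1)))]
  logSum <- numeric(nrow(data))
  for (m in models) {
    if (!m@factorId %in% colnames(data))
      stop("cohort table lacks column for factor '", m@factorId, "'")
    ov <- rep(FALSE, nrow(data))
    for (flag in m@medicationOverrides)
      if (flag %in% colnames(data)) ov <- ov | (data[[flag]] %in% TRUE)
    logSum <- logSum + log(factorOR(m, data[[m@factorId]], ov))
  }
  exp(logSum)
}

#' Convert a relative risk to an odds ratio (and back)
#'
#' `rrToOR()` maps a published relative risk to the odds ratio implied by
#' the unexposed-group disease prevalence `p0`:
#' `OR = RR (1 - p0) / (1 - RR p0)`, and reports the relative error of
#' treating the RR as the OR directly, `|OR - RR| / OR`. `orToRR()` is
#' the exact inverse, `RR = OR / (1 - p0 + p0 OR)`. In the rare-disease
#' limit (`p0 = 0`) the two measures coincide; for `p0 <= 0.1` and true
#' OR `<= 2` the approximation error stays within 10%.
#'
#' @param rr relative risk, `> 0`.
#' @param or odds ratio, `> 0`.
#' @param p0 unexposed-group disease prevalence in `[0, 1)`; must satisfy
#'   `rr * p0 < 1`.
#' @return `rrToOR` returns a list with `or` and `relative_error`;
#'   `orToRR` the relative risk.
#' @examples
#' orToRR(2, 0.1)              # 1.8182
#' rrToOR(1.8182, 0.1)$or      # ~2
#' @export
rrToOR <- function(rr, p0) {
  if (any(rr <= 0)) stop("rr must be > 0")
  if (any(p0 < 0) || any(p0 >= 1)) stop("p0 must be in [0, 1)")
  if (any(rr * p0 >= 1))
    stop("rr * p0 >= 1: RR is incompatible with this baseline prevalence")
  or <- rr * (1 - p0) / (1 - rr * p0)
  list(or = or, relative_error = abs(or - rr) / or)
}

#' @rdname rrToOR
#' @export
orToRR <- function(or, p0) {
  if (any(or <= 0)) stop("or must be > 0")
  if (any(p0 < 0) || any(p0 >= 1)) stop("p0 must be in [0, 1)")
  or / (1 - p0 + p0 * or)
}

#' Check the rare-disease validity of non-OR source measures
#'
#' For every model whose `sourceMeasure` is `"RR"` or `"HR"`, computes the
#' worst-case relative error of treating the published measure as an OR
#' given the model's `sourcePrevalence`, without transforming the stored
#' values (published values are used directly).
#'
#' @param models list of [RiskFactorModel-class] objects.
#' @return data.frame with one row per checked model: `factor_id`,
#'   `source_measure`, `p0`, `max_or`, `max_relative_error`, `valid`
#'   (error `<= 0.1`).
#' @export
checkApproximationValidity <- function(models) {
  rows <- lapply(models, function(m) {
    if (m@sourceMeasure == "OR") return(NULL)
    p0 <- m@sourcePrevalence
    maxOR <- max(m@ors)
    err <- if (is.na(p0)) NA_real_ else {
      rr <- orToRR(maxOR, p0)
      abs(maxOR - rr) / maxOR
    }
    data.frame(factor_id = m@factorId, source_measure = m@sourceMeasure,
               p0 = p0, max_or = maxOR, max_relative_error = err,
               valid = !is.na(err) & err <= 0.1)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(factor_id = character(0),
                      source_measure = character(0), p0 = numeric(0),
                      max_or = numeric(0), max_relative_error = numeric(0),
                      valid = logical(0))
  out
}

#' Combine environmental and genetic odds ratios
#'
#' The final multifactorial odds ratio is the product of the aggregate
#' environmental and genetic odds ratios.
#'
#' @param envOR,genOR positive numerics (vectorised).
#' @return `envOR * genOR`.
#' @export
combineOR <- function(envOR, genOR) {
  if (any(envOR <= 0, na.rm = TRUE) || any(genOR <= 0, na.rm = TRUE))
    stop("odds ratios must be > 0")
  envOR * genOR
}
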
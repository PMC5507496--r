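#' @describeIn RiskFactorModel-class compact display
#' @param object a `RiskFactorModel`
#' @export
setMethod("show", "RiskFactorModel", function(object) {
  cat("RiskFactorModel '", object@factorId, "' (", object@valueKind, ", ",
      object@sourceMeasure, ")\n", sep = "")
  if (object@valueKind == "categorical") {
    cat("  categories:", paste0(object@categories, "=", object@ors,
                                collapse = ", "), "\n")
  } else {
    lo <- object@breaks
    hi <- c(lo[-1], Inf)
    cat("  bins:", paste0("[", lo, ",", hi, ")=", object@ors,
                          collapse = " "), "\n")
  }
  if (length(object@medicationOverrides))
    cat("  max-OR override on:",
        paste(object@medicationOverrides, collapse = ", "), "\n")
  if (object@role != "standard") cat("  role:", object@role, "\n")
})

#' @describeIn BlockSelection-class compact display
#' @param object a `BlockSelection`
#' @export
setMethod("show", "BlockSelection", function(object) {
  cat("BlockSelection:", length(object@representative), "usable LD blocks,",
      length(object@blocksUnavailable), "unavailable\n")
  cat("  per-subject fallback substitutions:", nrow(object@fallback), "\n")
  cat("  subjects with incomplete genotype coverage:",
      length(object@incompleteSubjects), "\n")
})

#' @describeIn BootstrapResult-class compact display
#' @param object a `BootstrapResult`
#' @export
setMethod("show", "BootstrapResult", function(object) {
  pv <- if (object@pBound) paste0("< ", format(1 / object@nResamples))
        else format(object@pValue)
  cat(sprintf(
    "BootstrapResult [%s]: %.4g (%g%% CI %.4g, %.4g), p %s, B = %d, seed %d\n",
    object@statistic, object@estimate, 100 * object@level,
    object@ciLow, object@ciHigh, pv, object@nResamples, object@seed))
})

#' @describeIn RiskGroups-class compact display
#' @param object a `RiskGroups`
#' @export
setMethod("show", "RiskGroups", function(object) {
  cat("RiskGroups:", length(object@erg), "subjects\n")
  cat(sprintf("  ERG median cutoff: %.4g  sizes: %s\n", object@envCutoff,
              paste(tabulate(object@erg, 2), collapse = "/")))
  cat(sprintf("  GRG tertile cutoffs: %.4g, %.4g  sizes: %s\n",
              object@genCutoffs[1], object@genCutoffs[2],
              paste(tabulate(object@grg, 3), collapse = "/")))
  if (object@degenerate) cat("  (degenerate cutoffs: tied values)\n")
})

#' @describeIn IncidenceTable-class compact display
#' @param object an `IncidenceTable`
#' @export
setMethod("show", "IncidenceTable", function(object) {
  cat("IncidenceTable (", object@nResamples, " bootstrap resamples, seed ",
      object@seed, ")\n", sep = "")
  print(object@grid, row.names = FALSE)
  if (nrow(object@pairwise)) {
    cat("Pairwise GRG differences within ERG:\n")
    print(object@pairwise, row.names = FALSE)
  }
})

#' Accessors for risk-group assignments and cutoffs
#'
#' @param x a [RiskGroups-class] object.
#' @return `ergAssignments`/`grgAssignments` return integer vectors;
#'   `envCutoff` the median environmental OR; `genCutoffs` the two genetic
#'   tertile cutoffs.
#' @export
ergAssignments <- function(x) {
  stopifnot(is(x, "RiskGroups"))
  x@erg
}

#' @rdname ergAssignments
#' @export
grgAssignments <- function(x) {
  stopifnot(is(x, "RiskGroups"))
  x@grg
}

#' @rdname ergAssignments
#' @export
envCutoff <- function(x) {
  stopifnot(is(x, "RiskGroups"))
  x@envCutoff
}

#' @rdname ergAssignments
#' @export
genCutoffs <- function(x) {
  stopifnot(is(x, "RiskGroups"))
  x@genCutoffs
}

#' Accessors for cohort containers
#'
#' `dosages()` returns the SNP-by-subject dosage matrix; `incidentT2D()`
#' the endpoint vector (`NA` for censored subjects); `truthRecord()` the
#' generator truth record of a synthetic cohort (or `NULL`).
#'
#' @param x a [T2DCohort-class] object.
#' @export
dosages <- function(x) {
  stopifnot(is(x, "T2DCohort"))
  SummarizedExperiment::assay(x, "dosage")
}

#' @rdname dosages
#' @export
incidentT2D <- function(x) {
  stopifnot(is(x, "T2DCohort"))
  SummarizedExperiment::colData(x)$incident_t2d
}

#' @rdname dosages
#' @export
truthRecord <- function(x) {
  stopifnot(is(x, "T2DCohort"))
  S4Vectors::metadata(x)$truth
}

#' Accessors for incidence tables and bootstrap results
#'
#' @param x an [IncidenceTable-class] or [BootstrapResult-class] object.
#' @return `incidenceGrid`/`pairwisePValues` return data.frames;
#'   `bootEstimate`, `bootCI` and `bootPValue` the corresponding scalars
#'   (CI as a length-2 vector).
#' @export
incidenceGrid <- function(x) {
  stopifnot(is(x, "IncidenceTable"))
  x@grid
}

#' @rdname incidenceGrid
#' @export
pairwisePValues <- function(x) {
  stopifnot(is(x, "IncidenceTable"))
  x@pairwise
}

#' @rdname incidenceGrid
#' @export
bootEstimate <- function(x) {
  stopifnot(is(x, "BootstrapResult"))
  x@estimate
}

#' @rdname incidenceGrid
#' @export
bootCI <- function(x) {
  stopifnot(is(x, "BootstrapResult"))
  c(x@ciLow, x@ciHigh)
}

#' @rdname incidenceGrid
#' @export
bootPValue <- function(x) {
  stopifnot(is(x, "BootstrapResult"))
  x@pValue
}

#' Construct a T2DCohort
#'
#' @param dosage numeric matrix, SNPs in rows (rsID rownames), subjects in
#'   columns (subject-id colnames); entries 0/1/2/NA.
#' @param colData subject-level data (data.frame or DataFrame) aligned
#'   with the dosage columns.
#' @param metadata optional list (e.g. generator truth record under
#'   `$truth`).
#' @return a [T2DCohort-class] object.
#' @examples
#' d <- matrix(c(0, 1, 2, 1), 2, 2,
#'             dimnames = list(c("rs1", "rs2"), c("s1", "s2")))
#' cd <- data.frame(age = c(55, 62), censored = c(FALSE, FALSE),
#'                  incident_t2d = c(FALSE, TRUE), row.names = c("s1", "s2"))
#' T2DCohort(d, cd)
#' @export
T2DCohort <- function(dosage, colData, metadata = list()) {
  if (is.null(rownames(dosage)))
    stop("dosage matrix must have rsID rownames")
  if (is.null(colnames(dosage)))
    stop("dosage matrix must have subject-id colnames")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    colData = S4Vectors::DataFrame(colData),
    metadata = metadata)
  new("T2DCohort", se)
}
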
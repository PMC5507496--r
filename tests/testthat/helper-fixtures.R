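# Shared fixtures and independent oracles, built in code.

# Exhaustive pair-counting AUC oracle (independent of the rank-based
# implementation): wins + half-ties over all case-control pairs.
aucBruteForce <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (x in cases) for (y in ctrls)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(cases) * length(ctrls))
}

# Welch two-sample t-test p-value from first principles.
welchP <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# Minimal three-factor model set for engine unit tests.
tinyModels <- function() {
  list(
    riskFactorModel("smoking", "categorical",
                    c(never = 1.0, past = 1.2, current = 1.6)),
    riskFactorModel("bmi", "continuous",
                    c("0" = 1.0, "25" = 1.5, "30" = 2.2)),
    riskFactorModel("bp", "continuous", c("0" = 1.0, "140" = 2.0),
                    medicationOverrides = "on_antihypertensive"))
}

# Small deterministic catalogue: two blocks of two SNPs plus one
# single-SNP block; scores rank rsA1 > rsA2 and rsB1 > rsB2.
tinyCatalogue <- function() {
  data.frame(
    rsid = c("rsA1", "rsA2", "rsB1", "rsB2", "rsC1"),
    gene = "g", chromosome = "1",
    ld_block = c("A", "A", "B", "B", "C"),
    risk_allele = "A",
    allelic_or = c(1.3, 1.25, 1.2, 1.18, 1.1),
    risk_allele_freq = c(0.3, 0.32, 0.5, 0.48, 0.2),
    ancestry = "European",
    study_sample_size = c(50000, 10000, 40000, 20000, 30000),
    p_value = c(1e-12, 1e-10, 1e-9, 1e-8, 1e-9),
    n_replications = c(3, 2, 3, 2, 2),
    stringsAsFactors = FALSE)
}

# Dosage matrix for tinyCatalogue: 4 subjects, rsB2 never genotyped.
tinyDosage <- function() {
  m <- matrix(c(
    0, 1, 2, 1,     # rsA1 (s3 NA below)
    1, 1, 0, 2,     # rsA2
    2, 0, 1, 1,     # rsB1
    0, 2, 1, 0),    # rsC1
    nrow = 4, byrow = TRUE,
    dimnames = list(c("rsA1", "rsA2", "rsB1", "rsC1"),
                    paste0("s", 1:4)))
  m["rsA1", "s3"] <- NA
  m
}

filteredDefaultCatalogue <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- filterCatalogue(defaultSnpCatalogue())$catalogue
    cache
  }
})
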
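test_that("catalogue filters apply in sequence with a conserved audit", {
  res <- filterCatalogue(defaultSnpCatalogue())
  expect_equal(res$audit$n_out[res$audit$stage == "ancestry"], 53)
  expect_equal(res$audit$n_out[res$audit$stage == "replication"], 28)
  expect_equal(length(unique(res$catalogue$ld_block)), 24)
  # conservation at every stage
  expect_true(all(res$audit$n_in ==
                    res$audit$n_excluded + res$audit$n_out))
  # stages chain: out of stage k is in of stage k+1
  expect_equal(res$audit$n_in[-1], res$audit$n_out[-nrow(res$audit)])
})

test_that("filtering an empty catalogue yields empty output and zero audit", {
  res <- filterCatalogue(defaultSnpCatalogue()[0, ])
  expect_equal(nrow(res$catalogue), 0)
  expect_true(all(res$audit$n_in == 0 & res$audit$n_out == 0))
})

test_that("SNP evidence score is monotone and matches the documented formula", {
  expect_equal(scoreSnp(20000, 1e-10, 3), log10(20000) + 10 + 3)
  expect_gt(scoreSnp(50000, 1e-10, 2), scoreSnp(10000, 1e-10, 2))
  expect_gt(scoreSnp(20000, 1e-30, 2), scoreSnp(20000, 1e-8, 2))
  expect_gt(scoreSnp(20000, 1e-10, 4), scoreSnp(20000, 1e-10, 3))
  expect_error(scoreSnp(NA, 1e-8, 2), "missing")
})

test_that("block representatives are the top-scoring genotyped SNPs", {
  sel <- selectBlockRepresentatives(tinyCatalogue(), tinyDosage(),
                                    availabilityThreshold = 0.5)
  expect_equal(sort(names(sel@representative)), c("A", "B", "C"))
  expect_equal(unname(sel@representative["A"]), "rsA1")
  expect_equal(unname(sel@representative["B"]), "rsB1")
  # s3 misses rsA1 but carries second-ranked rsA2
  expect_equal(sel@fallback$subject_id, "s3")
  expect_equal(sel@fallback$rsid, "rsA2")
  expect_length(sel@incompleteSubjects, 0)
})

test_that("blocks with no genotyped SNP are unavailable; uncovered subjects flagged", {
  cat <- tinyCatalogue()
  d <- tinyDosage()[c("rsB1", "rsC1"), , drop = FALSE]  # block A absent
  d["rsC1", "s4"] <- NA                                 # s4 uncovered in C
  sel <- selectBlockRepresentatives(cat, d, availabilityThreshold = 0.5)
  expect_equal(sel@blocksUnavailable, "A")
  expect_equal(sort(names(sel@representative)), c("B", "C"))
  expect_equal(sel@incompleteSubjects, "s4")
})

test_that("selection is deterministic and ties break by sample size then rsid", {
  cat <- tinyCatalogue()
  # equalise scores of the A block, leave sample sizes to break the tie
  cat$p_value[1:2] <- 1e-10
  cat$n_replications[1:2] <- 2
  cat$study_sample_size[1:2] <- c(30000, 30000)
  d <- tinyDosage()
  d["rsA1", "s3"] <- 1
  s1 <- selectBlockRepresentatives(cat, d)
  s2 <- selectBlockRepresentatives(cat, d)
  expect_identical(s1@representative, s2@representative)
  expect_equal(unname(s1@representative["A"]), "rsA1")  # lexicographic
})

test_that("the packaged catalogue reproduces the printed block structure", {
  sel <- selectBlockRepresentatives(
    filteredDefaultCatalogue(),
    generateCohort(synthParams(nSubjects = 400, seed = 7)))
  expect_length(sel@representative, 19)
  expect_length(sel@blocksUnavailable, 5)
  # the block whose top scorer is off-array uses its second-ranked SNP
  expect_equal(unname(sel@representative["LD19_SLC30A8"]), "rs13266634")
  expect_equal(unname(sel@representative["LD10_TCF7L2"]), "rs7903146")
})

test_that("per-genotype OR follows the log-additive model with HWE centring", {
  expect_equal(genotypeOR(1.0, 2, 0.3), 1.0)
  expect_equal(genotypeOR(2.0, 1, 0.5), 2 / 2.25)
  expect_equal(genotypeOR(2.0, 1, normalize = FALSE), 2)
  # HWE-weighted mean of normalised ORs is 1
  hw <- c(0.25, 0.5, 0.25)
  expect_equal(sum(hw * genotypeOR(2, 0:2, 0.5)), 1.0, tolerance = 1e-12)
  expect_error(genotypeOR(2, 3, 0.5), "dosage")
  expect_error(genotypeOR(2, 1, 1.5), "riskAlleleFreq")
})

test_that("HWE normalisation gives population mean 1 across a parameter grid", {
  for (a in c(0.5, 0.85, 1, 1.2, 2, 5)) {
    for (q in c(0.01, 0.1, 0.3, 0.5, 0.8, 0.99)) {
      hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
      expect_equal(sum(hw * genotypeOR(a, 0:2, q)), 1.0,
                   tolerance = 1e-12)
    }
  }
})

test_that("aggregate genetic OR is the product over chosen SNPs", {
  cat <- tinyCatalogue()[c(1, 3, 5), ]
  cat$allelic_or <- c(0.93, 0.85, 0.86)
  d <- matrix(1, 3, 2, dimnames = list(cat$rsid, c("s1", "s2")))
  d[, 2] <- c(1, 0, 0)
  sel <- selectBlockRepresentatives(cat, d)
  g <- aggregateGeneticOR(d, sel, cat, normalize = FALSE)
  # hand product of the three allelic ORs at dosage one
  expect_equal(unname(g["s1"]), 0.93 * 0.85 * 0.86, tolerance = 1e-12)
  expect_equal(unname(g["s2"]), 0.93)
  # permuting SNP order leaves the product unchanged
  perm <- c(3, 1, 2)
  selP <- selectBlockRepresentatives(cat[perm, ], d[perm, ])
  expect_equal(aggregateGeneticOR(d[perm, ], selP, cat[perm, ],
                                  normalize = FALSE), g)
})

test_that("incomplete subjects get NA genetic OR and fallbacks are honoured", {
  cat <- tinyCatalogue()
  d <- tinyDosage()
  d["rsC1", "s2"] <- NA   # single-SNP block: s2 incomplete
  sel <- selectBlockRepresentatives(cat, d, availabilityThreshold = 0.5)
  g <- aggregateGeneticOR(d, sel, cat)
  expect_true(is.na(g["s2"]))
  expect_false(anyNA(g[c("s1", "s3", "s4")]))
  # s3's A-block contribution uses second-ranked rsA2 (dosage 0)
  iB <- match("rsB1", cat$rsid); iC <- match("rsC1", cat$rsid)
  iA2 <- match("rsA2", cat$rsid)
  expected <- genotypeOR(cat$allelic_or[iA2], 0,
                         cat$risk_allele_freq[iA2]) *
    genotypeOR(cat$allelic_or[iB], d["rsB1", "s3"],
               cat$risk_allele_freq[iB]) *
    genotypeOR(cat$allelic_or[iC], d["rsC1", "s3"],
               cat$risk_allele_freq[iC])
  expect_equal(unname(g["s3"]), expected, tolerance = 1e-12)
})

test_that("a large HWE cohort has mean genetic OR near 1 and tertiles straddling 1", {
  co <- generateCohort(synthParams(nSubjects = 6000, seed = 11))
  cat <- filteredDefaultCatalogue()
  sel <- selectBlockRepresentatives(cat, co)
  g <- aggregateGeneticOR(co, sel, cat)
  g <- g[!is.na(g)]
  expect_equal(mean(g), 1.0, tolerance = 0.05)
  cuts <- quantile(g, c(1, 2) / 3)
  expect_lt(cuts[1], 1)
  expect_gt(cuts[2], 1)
})

test_that("dosage CSV and VCF readers agree on risk-allele dosage", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "g.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
          "INFO", "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "rsA1", "G", "A", ".", "PASS", ".", "GT",
          "0/1", "1/1", "./.", sep = "\t"),
    paste("1", "200", "rsB1", "A", "C", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t")), vcf)
  cat <- tinyCatalogue()[c(1, 3), ]   # risk allele A for both
  d <- readGenotypesVCF(vcf, cat)
  # rsA1: risk allele is ALT -> alt count; rsB1: risk allele is REF
  expect_equal(unname(d["rsA1", ]), c(1, 2, NA))
  expect_equal(unname(d["rsB1", ]), c(2, 1, 0))
  csv <- file.path(dir, "d.csv")
  writeLines(c("subject_id,rsA1,rsB1",
               "s1,1,2", "s2,2,1", "s3,-1,0"), csv)
  m <- readDosageMatrix(csv)
  expect_equal(m[rownames(d), colnames(d)], d)
})
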
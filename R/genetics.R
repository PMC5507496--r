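#' Validate a SNP catalogue table
#'
#' The catalogue is a plain data.frame with one row per SNP record:
#' `rsid`, `gene`, `chromosome`, `ld_block`, `risk_allele`, `allelic_or`,
#' `risk_allele_freq`, `ancestry` (semicolon-separated tags),
#' `study_sample_size`, `p_value`, `n_replications`, and optionally
#' `on_array` (whether the genotyping platform carries the SNP).
#'
#' @param catalogue data.frame of SNP records.
#' @return the catalogue, invisibly, after validation.
#' @export
validateCatalogue <- function(catalogue) {
  need <- c("rsid", "ld_block", "risk_allele", "allelic_or",
            "risk_allele_freq", "ancestry", "study_sample_size",
            "p_value", "n_replications")
  miss <- setdiff(need, colnames(catalogue))
  if (length(miss))
    stop("SNP catalogue is missing column(s): ", paste(miss, collapse = ", "))
  if (any(catalogue$allelic_or <= 0))
    stop("allelic ORs must be > 0")
  q <- catalogue$risk_allele_freq
  if (any(q <= 0 | q >= 1))
    stop("risk allele frequencies must lie strictly in (0, 1)")
  p <- catalogue$p_value
  if (any(p <= 0 | p >= 1))
    stop("p-values must lie strictly in (0, 1)")
  if (anyDuplicated(catalogue$rsid))
    stop("duplicated rsids in catalogue")
  invisible(catalogue)
}

#' Filter a SNP catalogue by evidence, ancestry and replication
#'
#' Applies the three data-driven inclusion filters in sequence:
#' (1) study evidence — minimum discovery sample size and genome-wide
#' significance; (2) ancestry — the record must carry the target ancestry
#' tag; (3) replication — association replicated in at least
#' `minReplications` independent studies. Each stage's in/out counts are
#' recorded in an audit table.
#'
#' @param catalogue a validated SNP catalogue data.frame.
#' @param ancestry target ancestry tag (default `"European"`).
#' @param minSample minimum discovery sample size.
#' @param gwasAlpha genome-wide significance threshold (default `5e-8`).
#' @param minReplications minimum number of supporting studies
#'   (default 2).
#' @return list with `catalogue` (the surviving records) and `audit`
#'   (data.frame: `stage`, `n_in`, `n_excluded`, `n_out`).
#' @export
filterCatalogue <- function(catalogue, ancestry = "European",
                            minSample = 1000L, gwasAlpha = 5e-8,
                            minReplications = 2L) {
  validateCatalogue(catalogue)
  audit <- data.frame(stage = character(0), n_in = integer(0),
                      n_excluded = integer(0), n_out = integer(0))
  step <- function(cat, keep, stage) {
    nIn <- nrow(cat)
    out <- cat[keep, , drop = FALSE]
    audit <<- rbind(audit, data.frame(
      stage = stage, n_in = nIn, n_excluded = nIn - nrow(out),
      n_out = nrow(out)))
    out
  }
  cat1 <- step(catalogue,
               catalogue$study_sample_size >= minSample &
                 catalogue$p_value < gwasAlpha,
               "evidence")
  hasTag <- vapply(strsplit(cat1$ancestry, ";", fixed = TRUE),
                   function(tags) ancestry %in% trimws(tags), logical(1))
  if (!nrow(cat1)) hasTag <- logical(0)
  cat2 <- step(cat1, hasTag, "ancestry")
  cat3 <- step(cat2, cat2$n_replications >= minReplications, "replication")
  list(catalogue = cat3, audit = audit)
}

#' Evidence score of a SNP record
#'
#' A deterministic scalar combining study evidence:
#' `w_n log10(sample size) - w_p log10(p) + w_r replications`.
#' The score is strictly increasing in sample size and replication count
#' and strictly decreasing in p-value; only this monotonicity is
#' contractual, the weights are configuration.
#'
#' @param sampleSize,pValue,nReplications evidence fields (vectorised).
#' @param weights named numeric: `sample`, `pvalue`, `replication`
#'   (defaults all 1).
#' @return numeric score(s).
#' @examples
#' scoreSnp(20000, 1e-10, 3)  # log10(2e4) + 10 + 3 = 17.30103
#' @export
scoreSnp <- function(sampleSize, pValue, nReplications,
                     weights = c(sample = 1, pvalue = 1, replication = 1)) {
  if (anyNA(sampleSize) || anyNA(pValue) || anyNA(nReplications))
    stop("evidence fields must not be missing")
  if (any(sampleSize <= 0) || any(pValue <= 0) || any(pValue >= 1))
    stop("evidence fields out of domain")
  weights[["sample"]] * log10(sampleSize) -
    weights[["pvalue"]] * log10(pValue) +
    weights[["replication"]] * nReplications
}

#' Select one representative SNP per LD block
#'
#' Within each LD block, SNPs are ranked by [scoreSnp()] (ties broken by
#' larger sample size, then lexicographic rsid). The cohort-level
#' representative is the highest-ranked SNP that is genotyped in at least
#' `availabilityThreshold` of subjects; a subject missing the
#' representative's genotype falls back to the next-ranked SNP available
#' for that subject. Blocks with no genotyped SNP are unusable for every
#' subject; subjects with no genotype at any ranked SNP of a usable block
#' are flagged incomplete (they lack the full block coverage required for
#' a genetic score).
#'
#' @param catalogue filtered SNP catalogue (e.g. [filterCatalogue()]
#'   output).
#' @param dosage SNP-by-subject dosage matrix (or a [T2DCohort-class]).
#' @param availabilityThreshold minimum cohort genotyping fraction for a
#'   cohort-level representative (default 0.8).
#' @param weights score weights passed to [scoreSnp()].
#' @return a [BlockSelection-class] object.
#' @export
selectBlockRepresentatives <- function(catalogue, dosage,
                                       availabilityThreshold = 0.8,
                                       weights = c(sample = 1, pvalue = 1,
                                                   replication = 1)) {
  if (is(dosage, "T2DCohort")) dosage <- dosages(dosage)
  validateCatalogue(catalogue)
  if (anyNA(catalogue$ld_block) || any(!nzchar(catalogue$ld_block)))
    stop("every catalogue SNP must carry an LD block id")
  score <- scoreSnp(catalogue$study_sample_size, catalogue$p_value,
                    catalogue$n_replications, weights)
  ord <- order(catalogue$ld_block, -score, -catalogue$study_sample_size,
               catalogue$rsid)
  cat <- catalogue[ord, , drop = FALSE]
  ranking <- split(cat$rsid, cat$ld_block)

  subj <- colnames(dosage)
  nSubj <- length(subj)
  representative <- character(0)
  blocksUnavailable <- character(0)
  fallback <- data.frame(subject_id = character(0), block = character(0),
                         rsid = character(0))
  incomplete <- rep(FALSE, nSubj)

  for (blk in names(ranking)) {
    rsids <- ranking[[blk]]
    genotyped <- rsids[rsids %in% rownames(dosage)]
    avail <- vapply(genotyped,
                    function(r) mean(!is.na(dosage[r, ])), numeric(1))
    usable <- genotyped[avail >= availabilityThreshold]
    if (!length(genotyped) || !length(usable)) {
      blocksUnavailable <- c(blocksUnavailable, blk)
      next
    }
    rep <- usable[1]
    representative[blk] <- rep
    missing <- is.na(dosage[rep, ])
    if (any(missing)) {
      others <- setdiff(genotyped, rep)
      covered <- rep(FALSE, nSubj)
      covered[!missing] <- TRUE
      for (alt in others) {
        take <- !covered & missing & !is.na(dosage[alt, ])
        if (any(take)) {
          fallback <- rbind(fallback, data.frame(
            subject_id = subj[take], block = blk, rsid = alt))
          covered[take] <- TRUE
        }
      }
      incomplete <- incomplete | !covered
    }
  }
  new("BlockSelection", ranking = ranking,
      representative = representative, fallback = fallback,
      blocksUnavailable = blocksUnavailable,
      incompleteSubjects = subj[incomplete],
      availabilityThreshold = availabilityThreshold)
}

#' Per-genotype odds ratio under the log-additive allelic model
#'
#' The raw per-SNP odds ratio of a subject carrying `dosage` copies of
#' the risk allele is `allelicOR^dosage` (multiplicative allelic model).
#' With `normalize = TRUE` (the default throughout the pipeline) the raw
#' OR is divided by the Hardy-Weinberg population mean
#' `((1 - q) + q a)^2`, so the population-expected per-SNP OR is exactly
#' 1 and aggregate genetic ORs are expressed relative to the population
#' average (which is how tertile cutoffs can straddle 1).
#'
#' @param allelicOR per-allele odds ratio `a > 0`.
#' @param dosage risk-allele count in `{0, 1, 2}` (vectorised; `NA`
#'   propagates).
#' @param riskAlleleFreq risk-allele frequency `q` in `(0, 1)`; needed
#'   only when normalising.
#' @param normalize divide by the HWE population mean (default `TRUE`).
#' @return numeric odds ratio(s).
#' @examples
#' genotypeOR(2, 1, 0.5)          # 2 / 2.25 = 0.8889
#' genotypeOR(2, 1, normalize = FALSE)  # 2
#' @export
genotypeOR <- function(allelicOR, dosage, riskAlleleFreq = NA_real_,
                       normalize = TRUE) {
  if (any(allelicOR <= 0)) stop("allelicOR must be > 0")
  if (any(!is.na(dosage) & !(dosage %in% c(0, 1, 2))))
    stop("dosage must be 0, 1 or 2")
  raw <- allelicOR^dosage
  if (!normalize) return(raw)
  q <- riskAlleleFreq
  if (anyNA(q) || any(q <= 0 | q >= 1))
    stop("riskAlleleFreq in (0,1) is required for normalisation")
  raw / ((1 - q) + q * allelicOR)^2
}

#' Aggregate genetic odds ratio per subject
#'
#' Multiplies per-genotype odds ratios over the chosen representative SNP
#' of every usable LD block (per-subject fallbacks applied). Subjects
#' flagged incomplete by the selection receive `NA` — they lack the full
#' block coverage required for a genetic score and are excluded by the
#' cohort cascade.
#'
#' @param dosage SNP-by-subject dosage matrix (or a [T2DCohort-class]).
#' @param selection a [BlockSelection-class].
#' @param catalogue the SNP catalogue (source of allelic ORs and
#'   frequencies).
#' @param normalize HWE mean-centre each per-SNP OR (default `TRUE`).
#' @return named numeric vector of aggregate genetic ORs, `NA` for
#'   incomplete subjects.
#' @export
aggregateGeneticOR <- function(dosage, selection, catalogue,
                               normalize = TRUE) {
  if (is(dosage, "T2DCohort")) dosage <- dosages(dosage)
  stopifnot(is(selection, "BlockSelection"))
  validateCatalogue(catalogue)
  subj <- colnames(dosage)
  logSum <- numeric(length(subj))
  names(logSum) <- subj
  snpOf <- function(rsid) {
    i <- match(rsid, catalogue$rsid)
    if (is.na(i)) stop("rsid ", rsid, " absent from catalogue")
    i
  }
  for (blk in names(selection@representative)) {
    rep <- selection@representative[[blk]]
    i <- snpOf(rep)
    d <- dosage[rep, ]
    fb <- selection@fallback[selection@fallback$block == blk, , drop = FALSE]
    lor <- log(genotypeOR(catalogue$allelic_or[i], ifelse(is.na(d), 0, d),
                          catalogue$risk_allele_freq[i], normalize))
    lor[is.na(d)] <- NA_real_
    if (nrow(fb)) {
      for (alt in unique(fb$rsid)) {
        j <- snpOf(alt)
        sel <- fb$subject_id[fb$rsid == alt]
        k <- match(sel, subj)
        k <- k[!is.na(k)]   # selection may predate a cohort subset
        if (!length(k)) next
        dAlt <- dosage[alt, k]
        lor[k] <- log(genotypeOR(catalogue$allelic_or[j], dAlt,
                                 catalogue$risk_allele_freq[j], normalize))
      }
    }
    logSum <- logSum + lor
  }
  out <- exp(logSum)
  out[subj %in% selection@incompleteSubjects] <- NA_real_
  out
}

#' Read a SNP catalogue from delimited text or YAML
#'
#' @param path CSV/TSV file (columns as in [validateCatalogue()]) or a
#'   YAML file with a `snps:` list of records.
#' @return a validated catalogue data.frame.
#' @export
readSnpCatalogue <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    recs <- if (!is.null(y$snps)) y$snps else y
    catalogue <- do.call(rbind, lapply(recs, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    catalogue <- utils::read.delim(path, sep = sep,
                                   stringsAsFactors = FALSE)
  }
  validateCatalogue(catalogue)
  catalogue
}

#' Read a subjects-by-SNP dosage table
#'
#' Plain CSV with a `subject_id` column and one column per rsID; empty
#' cells or -1 encode missing genotypes.
#'
#' @param path CSV file path.
#' @return SNP-by-subject dosage matrix.
#' @export
readDosageMatrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!"subject_id" %in% colnames(df))
    stop("dosage table needs a subject_id column")
  m <- t(as.matrix(df[setdiff(colnames(df), "subject_id")]))
  colnames(m) <- as.character(df$subject_id)
  mode(m) <- "numeric"
  m[m < 0] <- NA_real_
  m
}

#' Read genotype dosages from a VCF
#'
#' Parses biallelic sites from a VCF and converts GT fields to dosages of
#' the catalogue's risk allele, matching alleles by REF/ALT letters:
#' when the risk allele is the ALT the dosage is the ALT-allele count,
#' when it is the REF the count is flipped (`2 - alt count`); `./.` maps
#' to missing. Sites whose REF/ALT pair does not contain the catalogue
#' risk allele are dropped with a warning.
#'
#' @param path VCF file (plain or bgzipped).
#' @param catalogue SNP catalogue supplying `rsid` and `risk_allele`.
#' @return SNP-by-subject dosage matrix for the catalogue SNPs present.
#' @export
readGenotypesVCF <- function(path, catalogue) {
  validateCatalogue(catalogue)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- fix$ID %in% catalogue$rsid
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  altCount <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/", fixed = FALSE),
                  function(a) sum(a == "1"), numeric(1)))
  }
  out <- matrix(NA_real_, nrow(fix), ncol(gt),
                dimnames = list(fix$ID, colnames(gt)))
  dropped <- character(0)
  for (i in seq_len(nrow(fix))) {
    risk <- catalogue$risk_allele[match(fix$ID[i], catalogue$rsid)]
    d <- altCount(gt[i, ])
    if (identical(risk, fix$ALT[i])) out[i, ] <- d
    else if (identical(risk, fix$REF[i])) out[i, ] <- 2 - d
    else dropped <- c(dropped, fix$ID[i])
  }
  if (length(dropped)) {
    warning("risk allele not among REF/ALT for: ",
            paste(dropped, collapse = ", "))
    out <- out[setdiff(rownames(out), dropped), , drop = FALSE]
  }
  out
}
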
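---
title: "Methods: multifactorial odds-ratio risk scoring and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multifactorial odds-ratio risk scoring and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2drisk)
```

# The risk model

## Environmental factors

Every environmental risk factor is a `RiskFactorModel`: a lookup from
the subject's value to an odds ratio, either over an exhaustive
category set or over contiguous half-open bins `[low, high)` of a
continuous measurement. The half-open convention means a value exactly
at a bin boundary falls in the *upper* bin; this is arbitrary but
deterministic and documented, which is what matters for reproducing a
score. The aggregate environmental OR is the plain product of the
per-factor ORs. Two refinements:

* **Medication overrides.** A subject on antihypertensive or
  lipid-lowering treatment carries the *maximal* OR of the
  corresponding factor regardless of the measured value: a treated
  blood pressure of 125 mmHg does not indicate low underlying risk.
  The override applies even when the measurement itself is missing.
* **Log-space accumulation in canonical order.** The product is
  accumulated as a sum of logs (robust for a dozen factors whose
  product can exceed 10^2), and the models are processed in sorted
  `factorId` order, so the result is bit-for-bit invariant under any
  permutation of the model list — floating-point summation is not
  otherwise associative.

Published effect sizes are not always ORs. Where a source reported a
relative risk or hazard ratio the configuration records that
(`sourceMeasure`, `sourcePrevalence`), and the engine uses the value
*as published* — it does not silently transform it, because a silent
transformation would make the configured numbers untraceable. Instead,
`checkApproximationValidity()` reports the worst-case relative error
of treating the measure as an OR: for unexposed-group prevalence
$p_0$, $\mathrm{RR} = \mathrm{OR} / (1 - p_0 + p_0\,\mathrm{OR})$, and
over the region $p_0 \le 0.1$, $\mathrm{OR} \le 2$ the error never
exceeds 10% (it attains 9.09% at the corner). `rrToOR()`/`orToRR()`
expose the exact conversion for users who want it.

A product of ORs taken from separately fitted (and partly correlated)
source models is an approximation — the engine deliberately applies the
multiplicative rule with no correlation correction, because no joint
model of the source studies exists to calibrate one. This is a known
limitation, not an implementation accident: correlated factors such as
BMI and waist circumference will to some degree double-count.

## The genetic score

The per-SNP model is the GWAS-standard log-additive one: dosage $d \in
\{0,1,2\}$ copies of the risk allele contribute $a^d$ at allelic OR
$a$. The catalogue publishes *allelic* ORs only, so a per-genotype
convention had to be chosen, and log-additivity is the convention
essentially all polygenic scores use.

Raw products of $a^d$ cannot fall below 1 unless some $a < 1$, yet
observed genetic-OR tertile cutoffs straddle 1 (e.g. a lower cutoff
near 0.75). That is only possible if per-SNP ORs are expressed
relative to the population average, so normalisation is on by default:
each $a^d$ is divided by its Hardy–Weinberg population mean
$\big((1-q) + qa\big)^2$ at risk-allele frequency $q$. The normalised
per-SNP OR then has population expectation exactly 1 (a tested
identity, to 1e-12), the aggregate genetic OR of an average subject is
~1, and tertile cutoffs land on either side of it. A flag disables the
centring for users who want raw products.

## LD-block representative selection

One SNP per LD block enters the score, to avoid double-counting
correlated markers. Within a block, SNPs are ranked by an evidence
score combining discovery sample size, p-value and replication count:

$$w_n \log_{10}(n) - w_p \log_{10}(p) + w_r \cdot \text{replications}$$

with all weights defaulting to 1. Only the monotonicity of the score
(increasing in $n$ and replications, decreasing in $p$) is
contractual; the weights are configuration, since no canonical formula
exists for evidence weighting. Ties break by larger sample size, then
lexicographic rsID — again arbitrary but deterministic.

The cohort-level representative of a block is the highest-ranked SNP
genotyped in at least 80% of subjects (`availabilityThreshold`, from
the typical per-block availability of array data). A subject whose
representative genotype failed falls back to the next-ranked SNP
available *for that subject*; a subject with no genotype at any ranked
SNP of a usable block is incomplete and excluded from the genetic
score entirely, because a missing block would silently shrink their
product toward 1 and bias the score. Blocks with no genotyped SNP at
all are unusable for everyone.

## Cohort assembly

The exclusion cascade removes, in order: prevalent baseline diabetes,
missing environmental data, censoring (status unknown at end of
follow-up), and incomplete genotype coverage. A subject failing
several criteria is *counted* at the first failing stage; the final
set is independent of stage order (each stage is a pure flag filter —
a tested invariant), so the order only fixes audit attribution. The
audit table is exact integer bookkeeping:
`n_before = n_excluded + n_after` at every stage.

Diabetes ascertainment is a pure disjunction over sources: a registry
flag, at least two HbA1c recordings ≥ 6.0% (Swedish Mono-S scale;
6.0% Mono-S corresponds to 7.0% NGSP, stored as a correspondence
rather than a conversion formula), fasting plasma glucose ≥ 7.0
mmol/L, fasting whole-blood glucose ≥ 6.1 mmol/L, a 2-h post-OGTT
glucose strictly greater than 11.0 mmol/L, self-reported physician
diagnosis, or antidiabetic medication. All cut-offs are inclusive
except the OGTT, which is printed as a strict inequality. Being a
disjunction, ascertainment is monotone: extra positive evidence can
never un-diagnose a subject.

# Evaluation statistics

**Stratification.** ERG1/ERG2 split at the median environmental OR
with ties (values exactly at the median) going to ERG1, which keeps
the two groups as balanced as the data allow; GRG1–3 split at type-7
tertile quantiles with values at a cutoff going to the lower group.
Both conventions are documented and deterministic; fewer than 6
subjects is an error (tertiles would be meaningless).

**AUC.** Implemented as the probability of concordance,
$(\text{wins} + 0.5\,\text{ties}) / (\text{cases} \times
\text{controls})$, via the rank-sum identity. The test suite holds it
against an exhaustive pair-enumeration oracle on hundreds of random
instances and against an independent ROC implementation.

**Bootstrap.** All uncertainty is percentile bootstrap over subjects
(B = 10,000 by default), and all p-values are two-sided sign-crossing
fractions $2\min(\#\{\theta^* \le 0\}, \#\{\theta^* \ge 0\})/B$,
clamped to $[1/B, 1]$ and flagged as a bound ("< 1/B") when no
resample crosses zero. The AUC comparison is *paired*: each resample
draws one subject set and recomputes both AUCs on it, which is what
makes a +0.01 AUC difference detectable at cohort scale; an
instrumentation hook exposes the resample indices so the pairing is
itself testable. Percentile CIs rather than BCa are the default
because the resampled statistics here (incidences, correlations, AUC
differences) are near-symmetric at these sample sizes; resamples that
lose one outcome class entirely are skipped.

**Correlations.** Pearson r is computed on the *raw* genetic OR
against the 0/1 case label (a log-OR option exists behind a flag).
With HWE-centred per-SNP ORs the raw genetic OR is approximately
log-normal with modest spread, so raw-vs-log makes little practical
difference; raw is the default because the score's natural scale is
the OR itself.

**Comparator point scores.** Published clinical scores
(FINDRISC-style, Framingham-Offspring-style) are consumed as point
tables (variable, bin, points). The shipped configurations are clearly
marked synthetic placeholders with the right variable structure;
users with access to the published coefficient tables should
transcribe them before drawing substantive comparisons.

# The synthetic cohort generator

The generator's defaults *are* the study conditions the analysis
assumes:

* environmental marginals matching the published cohort table — age
  N(57.1, 5.93), BMI N(25.6, 3.75), 37.9% male, smoking categories
  (42.9 / 33.6 / 4.4 / 19.0)%, alcohol N(5.15, 5.94) truncated at 0,
  SBP N(140, 18.3), DBP N(86.5, 9.24), triglycerides N(1.32, 0.69)
  truncated, HDL N(1.41, 0.37), physical activity (94.5 / 5.4 / 0.1)%,
  parental history (97.4 / 2.6 / 0)%;
* Hardy–Weinberg genotypes at the catalogue allele frequencies;
* an overall 15-year incidence calibrated to 402/3426 ≈ 11.7% by
  bisection on the reference incidence $p_{\mathrm{ref}}$ in
  $p = p_{\mathrm{ref}}\,\mathrm{OR} / (1 - p_{\mathrm{ref}} +
  p_{\mathrm{ref}}\,\mathrm{OR})$, applied to each subject's latent
  combined OR (environmental OR divided by its cohort geometric mean,
  times the centred genetic OR);
* exclusion-stage magnitudes matching the published cascade
  (267/6094 prevalent, 1287/6094 missing environmental, 497/4540
  censored, 617/4043 genotype-incomplete), assigned to disjoint
  subject sets in cascade order so a 6,094-subject pool reproduces the
  printed stage counts exactly; genotype dropout is a whole LD block,
  and two representative SNPs additionally lose 5 and 8 subjects'
  genotypes to exercise the per-subject fallback path.

Waist circumference (not in the published moments table) uses
N(84, 11) cm, a realistic value for a late-middle-aged mixed-sex
European cohort; medication prevalences default to 15%
antihypertensive and 8% lipid-lowering, plausible for a 1990s baseline
at these ages.

What the generator does **not** emulate: correlations between
environmental factors (marginals are independent by default, because
no covariance structure is published — an optional Gaussian-copula
hook exists for stress tests), registry-linkage realism, LD *within*
blocks (dosages are independent across SNPs), and time-to-event
structure (the endpoint is a fixed 15-year status, which is also all
the downstream analysis uses). Consequently, passing tests demonstrate
that the pipeline recovers structure *of the kind assumed by the
model*; they cannot certify behaviour under real-world factor
correlation or informative censoring.

A gene–environment attenuation flag (`gxeAttenuation`) can scale
latent genetic effects differentially by environmental stratum, to
emulate genetics mattering more at low environmental risk; it defaults
to off because no mechanism is claimed for that observation — it is
available for sensitivity experiments only.

## Fixture configurations

The per-factor OR curves and the SNP catalogue's
ORs/frequencies/evidence fields are synthetic-but-realistic package
fixtures (their sources publish only ranges or are unavailable as
data); the three allelic ORs that *are* printed in the literature the
catalogue mirrors (0.93, 0.85, 0.86) are used verbatim, as are the 19
representative rsIDs, genes, chromosomes and block-rank annotations.
The age curve (reference age 20) was calibrated once so that a default
synthetic cohort's median environmental OR lands near the published
magnitude of ~68 — age dominates the product because a 57-year-old is
decades past the reference age. No acceptance check compares against
this number; it anchors the fixture's scale.

# Numerical and design choices

* OR products in log space; canonical factor ordering for exact
  permutation invariance.
* Bisection for baseline calibration runs to bracket collapse
  (the null model recovers the target exactly).
* Degenerate inputs: constant OR vectors stratify everyone into the
  lowest group with a warning; empty factor lists score 1.0 with a
  warning (an error in strict mode); single-class label vectors are an
  error for AUC; constant vectors are an error for correlation.
* Missing data: missing factor values propagate as NA (callers decide
  exclusion; strict mode errors); dosage −1/empty/`./.` map to NA.
* Whether AUC-difference p-values should be one- or two-sided is not
  fixed by convention in the field; two-sided is the default, with an
  `alternative` argument.

# Problem sizes

The shipped tests run the full cascade at n = 6,094, marginal checks
at n = 8,000–10,000, bootstrap checks at B = 100–1,000, the
CI-coverage simulation at 60 replicates × B = 250, and the
signal-recovery and null-control simulations at 50 seeds ×
n = 3,426 × B = 500–1,000; the acceptance script uses B = 1,000.
These sizes give stable pass/fail behaviour for the properties tested
while keeping a full run in the low minutes; B = 10,000 remains the
analysis default for real use.

# Known limitations

* The multiplicative engine ignores correlation between source
  models (see above) and between SNPs across blocks.
* RR/HR values are used as published; the validity check reports, but
  does not correct, approximation error.
* The comparator point tables are placeholders pending transcription
  of the published coefficients.
* Family-history prevalence in the emulated cohort table is
  anomalously low (2.6% where 20–40% is typical); the generator
  reproduces the published marginal rather than imputing a more
  typical one, so family-history substitution analyses on synthetic
  data inherit that weakness.
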
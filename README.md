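# t2drisk

Multifactorial risk scoring for incident type 2 diabetes (T2D),
combining environmental risk factors with a polygenic score built from
linkage-disequilibrium (LD) block representative SNPs, and the
statistical machinery to ask whether the genetics actually improves
prediction — overall, and separately within environmental risk strata.

The package is aimed at biostatisticians and genetic epidemiologists who
want a tested, configurable implementation of a multiplicative
odds-ratio risk engine and its downstream evaluation (stratified
incidence, bootstrap AUC comparison), plus a synthetic cohort generator
that emulates the statistical structure of a prospective Swedish
population cohort so every pipeline stage can be exercised without
access to individual-level data.

## The model

Risk is quantified as an odds ratio (OR). For subject *i* with
environmental risk-factor values *x*<sub>i1</sub> … *x*<sub>iK</sub>,

- each factor *k* contributes OR<sub>k</sub>(*x*<sub>ik</sub>) from a
  configured categorical map or half-open continuous bins
  [low, high); subjects on blood-pressure or lipid-lowering medication
  receive the maximal OR of the corresponding factor regardless of the
  measured value;
- the aggregate environmental OR is the product
  OR<sup>env</sup><sub>i</sub> = ∏<sub>k</sub> OR<sub>k</sub>(*x*<sub>ik</sub>);
- each of 19 LD-block representative SNPs contributes
  *a*<sub>j</sub><sup>*d*<sub>ij</sub></sup> /
  ((1 − *q*<sub>j</sub>) + *q*<sub>j</sub>*a*<sub>j</sub>)², the
  log-additive per-genotype OR at allelic OR *a*<sub>j</sub> and dosage
  *d*<sub>ij</sub> ∈ {0, 1, 2}, centred by its Hardy–Weinberg
  population mean at risk-allele frequency *q*<sub>j</sub> so the
  population-expected per-SNP OR is 1;
- the aggregate genetic OR is the product over blocks, and the combined
  OR is OR<sup>env</sup> × OR<sup>gen</sup>.

Published relative risks and hazard ratios are treated as OR
approximations (valid to ≤10% relative error while the unexposed-group
prevalence is ≤0.1 and the OR ≤2; `rrToOR()` / `orToRR()` implement the
exact conversion and the validity check).

Downstream, the cohort is split at the median environmental OR
(ERG1/ERG2) and at genetic-OR tertiles (GRG1–3); the package computes
the 2×3 stratified 15-year incidence grid with percentile-bootstrap
CIs, Pearson correlations of the genetic OR with case status, and
paired-bootstrap comparisons of the environmental-only AUC against the
combined model (each resample recomputes both AUCs on the same
resampled subjects; two-sided sign-crossing p-values clamped to
[1/B, 1]).

## Worked example

```r
library(t2drisk)

cohort <- generateCohort(synthParams(nSubjects = 6094, seed = 1))
report <- runFullAnalysis(cohort, B = 1000, seed = 1)
print(report)
```

```
Multifactorial T2D risk analysis report
  subjects: 6094 input, 3426 analysed
  exclusion cascade:
                 stage n_before n_excluded n_after
         prevalent_t2d     6094        267    5827
 missing_environmental     5827       1287    4540
              censored     4540        497    4043
   incomplete_genotype     4043        617    3426
  SNP filter audit:
       stage n_in n_excluded n_out
    evidence  154          0   154
    ancestry  154        101    53
 replication   53         25    28
  median env OR 68.19; genetic tertile cutoffs 0.7997 / 1.088
  AUC env 0.7190 -> env+gen 0.7323 (delta +0.0134, p 0.028)
```

Reading the output: of a 6,094-subject pre-exclusion pool, subjects
with prevalent baseline diabetes, missing environmental data,
censoring, or incomplete genotype coverage are removed in sequence,
leaving 3,426 for analysis. The SNP catalogue shrinks from 154 records
to 28 usable SNPs across 24 LD blocks (19 of which are genotyped on
the array). The median environmental OR (~68, dominated by the age
factor, whose reference age is 20) splits the cohort into ERG1/ERG2;
the genetic tertile cutoffs straddle 1 because per-SNP ORs are
expressed relative to the population average. Adding the genetic OR to
the environmental model shifts the AUC from 0.719 to 0.732, and the
paired bootstrap calls that shift significant (p = 0.028 at
B = 1,000). `incidenceGrid(report$incidence)` holds the 2×3 incidence
table, `report$correlations` the per-stratum genetic-OR/case-status
correlations, and `report$auc_shift$erg1`/`$erg2` the within-stratum
AUC comparisons.

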
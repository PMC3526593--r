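# snpepi

Pathway-based genetic analysis of case-control studies: single-SNP logistic
association under genetic-model codings, marker-level quality control,
ReliefF/TuRF-filtered **Multifactor Dimensionality Reduction (MDR)**, and
entropy-based **Statistical Epistasis Networks (SEN)** — together with a
synthetic case-control cohort generator so that every stage can be exercised
and calibrated without access to individual-level study data.

The package is aimed at epidemiologists and statistical geneticists analysing
candidate-SNP panels (hundreds to a few thousand markers organised into
functional groups such as apoptosis, DNA repair, immune, hormone, metabolism),
where the scientific questions are (a) which individual SNPs shift disease
risk after covariate adjustment, and (b) which SNP pairs act epistatically —
including pairs with *no* marginal effects, which single-SNP scans cannot see.

## Methods at a glance

**Association.** For each SNP with dose coding `0/1/2` (wildtype het,
homozygous variant), three codings are fit by logistic regression with
adjustment for age group, gender and smoking: heterozygous vs wildtype,
homozygous variant vs wildtype, and dominant (carrier vs wildtype). The
report carries the Wald OR with 95% CI, a minimum-cell-size stability flag
(≥ 20 exposed cases *and* controls), and Benjamini–Hochberg FDR-adjusted
p-values computed within each functional group. SNP×covariate and SNP×SNP
interactions are tested by likelihood ratio, the latter with the
wildtype–wildtype joint genotype as referent.

**QC.** Call rate, minor allele frequency `min(p, 1-p)`, Hardy–Weinberg
equilibrium in controls (both the 1-df chi-square and a full-enumeration
exact conditional test), the genomic inflation factor
`λ = median(χ²) / 0.4549`, and Q-Q coordinates against uniform
order-statistic expectations.

**MDR.** Every k-way genotype combination is collapsed into one binary
attribute by labeling each joint-genotype cell high-risk when its training
case:control ratio reaches the overall ratio `T`. Models are scored by
cross-validated balanced accuracy `(sensitivity + specificity)/2`;
cross-validation consistency (CVC) counts the folds a combination wins;
significance comes from label-permutation of the *entire search*, so
model-selection optimism is part of the null. ReliefF weights (nearest-hit /
nearest-miss genotype differences) and the iterative TuRF wrapper filter
large panels down to a searchable candidate set.

**SEN.** Vertices are SNPs weighted by mutual information with the phenotype
(bits); edges are SNP pairs weighted by pairwise information gain
`IG(A;B;C) = I(A,B;C) − I(A;C) − I(B;C)`, retained when IG exceeds 0.011
bits *and* the per-pair permutation p-value clears the configured alpha.
A deterministic balanced XOR gives exactly 1 bit of IG, which anchors the
implementation.

**Simulator.** Disease status follows a logistic model over covariates
(gender, six age strata, smoking), SNP main effects on dominant / recessive /
per-dose codings, SNP×gender interactions, and 3×3 penetrance-table logit
offsets for epistasis; the intercept is solved numerically for a target
prevalence and the pool is sampled case-control style to exact counts.
`xor_penetrance()` provides the canonical epistasis-without-main-effects
pattern, exactly marginal-free at MAF `1 − 1/√2 ≈ 0.293`.

## Worked example

```r
library(snpepi)

spec <- simulation_spec(
  n_cases = 563, n_controls = 863, n_snps = 30,
  maf_overrides = c(snp_0029 = 0.3, snp_0030 = 0.3),
  epistasis_pairs = list(list(snp_a = "snp_0029", snp_b = "snp_0030",
                              penetrance = xor_penetrance(3))),
  rng_seed = 2024)
sim <- simulate_cohort(spec)

scan <- single_snp_scan(sim$genotypes, sim$subjects, sim$annotation)
head(scan[order(scan$p), ], 3)
#>    snp_id    coding    or ci_low ci_high      p fdr_adjusted_p
#>  snp_0023 hom_vs_wt 1.467  1.029   2.091 0.0342          0.103
#>  snp_0017 het_vs_wt 0.741  0.551   0.997 0.0476          0.143
#>  snp_0017  dominant 0.769  0.577   1.025 0.0734          0.220

st <- sim$subjects$status
mdr_permutation_test(sim$genotypes, st, colnames(sim$genotypes),
                     k_way = 2, cv_folds = 10, n_permutations = 200,
                     seed = 2024)
#> MDR 2-way model: snp_0029 x snp_0030
#>   training BA 0.6094 | testing BA 0.6061 | CVC 10/10
#>   permutation p = 0.004975

sen_analysis(sim$genotypes, sim$subjects,
             analysis_config(n_permutations = 200,
                             sen_permutation_alpha = 0.005,
                             rng_seed = 2024))
#> epistasis network: 2 vertices, 1 edges (IG > 0.011 bits, perm p < 0.005)
#>      snp_a    snp_b         ig      perm_p
#> 1 snp_0029 snp_0030 0.03507411 0.004975124
```

The single-SNP scan sees nothing notable (the injected pair has no marginal
effects — the smallest FDR-adjusted p is 0.10 on a noise SNP), while both
interaction methods identify the embedded pair: MDR with perfect
cross-validation consistency and a permutation p near its resolution limit,
SEN with an information-gain edge three times the 0.011-bit threshold. The
adjusted likelihood-ratio interaction test confirms it
(`snp_snp_interaction(...)` gives p = 8.4e-15).

A thin command-line front end over the same functions ships at
`inst/cli/snpepi.R` with subcommands `simulate`, `qc`, `assoc`, `mdr`,
`sen`.

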
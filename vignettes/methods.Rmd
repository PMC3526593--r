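---
title: "Models and design choices in snpepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in snpepi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

snpepi implements a pathway-based case-control analysis pipeline for
candidate-SNP panels: covariate-adjusted logistic association under genetic
codings, marker QC, ReliefF/TuRF-filtered Multifactor Dimensionality
Reduction (MDR), and entropy-based Statistical Epistasis Networks (SEN).
This vignette records the statistical models, the parameters that matter,
and the choices made where the methodology is genuinely open.

## Data model

Genotypes are minor-allele dose codes: 0 = wildtype homozygote,
1 = heterozygote, 2 = variant homozygote, `NA` = missing. This convention is
enforced once, at ingest (`genotype_matrix()`, `read_genotypes_tsv()`,
`read_plink_ped_map()`); every downstream module assumes it. For PED/MAP
input the minor allele is inferred from observed allele frequencies
(ties broken alphabetically for determinism), or can be supplied per SNP for
markers where the risk allele is the major one — the "wildtype" referent is
always the major-allele homozygote, which is the standard convention when a
study does not state how wildtype was assigned.

Missing genotypes are handled pairwise: each single-SNP model uses that
SNP's complete cases, each MDR combination and each SEN pair uses the
complete cases of exactly the SNPs involved. Missing smoking status drops a
subject from adjusted models only (complete-case, counts logged in
`n_used`).

## Association model

For each SNP, three codings are fit by logistic regression of case-control
status, adjusted for age group, gender and smoking as categorical
covariates: heterozygous vs wildtype (dose-2 subjects excluded), homozygous
variant vs wildtype (dose-1 excluded), and dominant (dose ≥ 1 vs 0). Age
enters as the six enrollment strata, not as a continuous covariate, because
the design it mirrors frequency-matched on those strata. Wald statistics
are reported per genotype term (matching the OR/CI presentation convention);
likelihood-ratio tests are reserved for interaction blocks, where they are
the stated standard.

Open readings resolved here:

* **Minimum cell size.** "At least 20 heterozygous or variant cases and
  controls" is read as *pooled*: the non-referent coding group must contain
  ≥ 20 cases and ≥ 20 controls. Results failing the rule are flagged
  (`min_cell_ok = FALSE`), never silently dropped.
* **FDR scope.** Benjamini–Hochberg adjustment runs within functional group
  (m = group size), separately per coding; `fdr_scope = "global"` exists for
  sensitivity analysis.
* **SNP×SNP models.** The default collapsing is dominant×dominant with
  wildtype–wildtype referent; subjects carrying a variant at exactly one SNP
  form their own coded group rather than being folded into either margin.
  The interaction LRT compares dominant main effects with and without their
  product (1 df). Degenerate joint-genotype patterns (fewer than three
  observed cells) make the product collinear; the group ORs are still
  reported with `interaction_p = NA` and a warning.

`fit_logistic()` wraps the IRLS fitter in `stats::glm.fit` and exposes
coefficients, observed-information covariance, the Bernoulli log-likelihood
(`-deviance/2`), and diagnostics: a singular design is an error naming the
collinear columns, and fitted probabilities within 1e-8 of 0/1 raise a
separation flag that marks the fit non-converged.

## QC

* MAF is `min(p, 1-p)` with `p` the variant-allele frequency.
* HWE is computed in controls only, the standard genotyping-QC practice.
  Because the test flavour behind published control-HWE p-values is often
  unstated, both tests are provided and reported side by side: the 1-df
  chi-square without continuity correction, and an exact conditional test
  that enumerates the full heterozygote-count distribution given the allele
  counts (log-gamma arithmetic; the p-value sums all configurations no more
  probable than the observed one, with a `1 + 1e-12` tolerance factor
  guarding float comparison). Monomorphic markers return p = 1 with a
  warning rather than an error, so dataset-wide QC never aborts.
* A marker fails QC iff MAF < 0.05 or call rate < 0.95. The MAF threshold is
  the stated exclusion rule of the emulated study; the call-rate threshold
  is configurable because only "low call rate" is stated.
* λ is the median-based estimator: median observed 1-df chi-square divided
  by `qchisq(0.5, 1) ≈ 0.4549`, with p-values converted through chi-square
  quantiles first. Median-based λ is robust to a handful of true signals.
  It is a diagnostic only — no genomic-control correction is applied
  downstream.

## MDR

Cells of the k-way joint-genotype table are labeled high-risk when the
training case:control ratio in the cell reaches the overall training ratio
T. Conventions the literature leaves open are fixed as: a cell exactly at T
is high; a cell with cases but no controls is high; an *empty* training
cell is low, so unseen test genotypes default to low risk. The T-rule is
provably the labeling that maximises balanced training accuracy (the test
suite checks it against exhaustive relabeling), so no search over labelings
is needed.

Cross-validation is stratified to preserve the case:control ratio, with
seeded fold assignment. Within each fold every combination is trained on
the other folds and the per-fold winner is the highest training balanced
accuracy (ties go to the lexicographically first combination, making runs
reproducible). CVC is the number of folds won; the reported model maximises
CVC with ties broken by mean testing balanced accuracy, then lexicographic
order. The permutation test permutes labels and re-runs the *entire*
search, taking the selected model's mean testing balanced accuracy as the
statistic each time, so the null distribution carries the same
model-selection optimism as the observed statistic; p uses the add-one
estimator `(1 + #[null ≥ obs]) / (1 + N)` and is therefore never below
`1/(N+1)`. An alternative null on CVC would be possible; testing balanced
accuracy was chosen because it is the quantity the selection rule ultimately
reports.

The implementation aggregates each combination's (class × fold × cell)
counts in one pass and derives all training tables by subtraction, so a
10-fold search costs one tabulation per combination; this is what keeps
100-permutation searches over dozens of SNPs in the second range.

**ReliefF / TuRF.** The pre-filter is standard ReliefF with per-SNP distance
`|dose_i − dose_j| / 2` and weight updates from the k nearest hits and
misses, plus TuRF, the iterative variant that repeatedly drops the worst
fraction and re-scores. Because the adaptation actually used in the
emulated analysis is not specified, both are provided with documented
defaults. The neighborhood size is the parameter that matters: with the
textbook k = 10 the filter is insensitive to weak epistasis in panels of a
hundred-plus SNPs, while k of roughly 5% of the cohort recovers an
XOR-style pair reliably; the test suite exercises the property at k = 40
on an 800-subject cohort. Filtering sensitivity also depends strongly on
the penetrance contrast — pairs with odds-ratio-2 scale epistasis are
detectable by exhaustive MDR search and by information gain at study scale,
but are below what instance-based weighting can rank reliably; the
ReliefF tests therefore use a stronger contrast, and ReliefF should be
viewed as a coarse pre-filter, not a detector.

## Statistical epistasis networks

Entropies are plug-in (maximum-likelihood) estimates in bits; zero-count
cells contribute nothing. No bias correction is applied because the
operating thresholds (0.011-bit edges, 0.01-bit vertex reference) are
meaningful for plug-in estimates at study scale; plug-in bias for a 9×2
table is on the order of `cells/(2 n ln 2)` and shrinks with n. Pairwise
information gain `IG(A;B;C) = I(A,B;C) − I(A;C) − I(B;C)` uses the 9-level
joint genotype; base 2 makes the deterministic balanced XOR exactly 1 bit,
which the tests assert without tolerance.

Permutation significance is per pair — each pair is compared against its
own label-permuted null, matching the stated per-pair testing — and an edge
must clear *both* the fixed IG threshold and the permutation alpha. Where
two nearby printed thresholds could apply to edges (0.01 vs 0.011), the
more specific 0.011 is the default; both knobs are exposed in
`analysis_config()`. Topology-based threshold selection (growing the giant
component) exists in the wider SEN literature but is deliberately omitted:
only fixed thresholds are stated for the analysis this package emulates.
An empty network is a valid result, not an error.

## The synthetic cohort generator

`simulate_cohort()` draws a population pool, assigns disease by a logistic
model, and samples cases and controls without replacement to exact counts.
Design choices:

* **Everything composes on the logit scale** — covariate effects, SNP main
  effects on their coding, gender-specific SNP effects, and 3×3
  penetrance-table offsets — so a logistic refit is well-specified and
  parameter recovery is interpretable (the acceptance suite checks 95% CI
  coverage ≈ 0.95 for a dominant OR-2 effect at study scale).
* **The intercept is solved numerically** (`uniroot`, tolerance 1e-10) for a
  target prevalence of 5%, then case-control sampling is applied, mimicking
  a rare-ish outcome sampled to a fixed design. Case-control sampling
  shifts the intercept only, so all ORs remain identifiable.
* **Default covariate structure** is calibrated to the genotyped margins of
  the emulated study: 60% male population with a male disease OR of 1.9
  (giving ≈ 62% male controls vs ≈ 76% male cases), smoking
  never/former/current ≈ 34/50/16 in controls with ORs 1/1.9/4.1, six age
  strata concentrated in the upper ages, ≈ 84.5% of cases non-invasive, and
  ≈ 1.5% missing smoking. These are calibration choices, not claims from
  any source: the downstream adjusted models should face realistic
  confounding.
* **Reference conditions** (`nh_study_spec()`): 563 cases / 863 controls,
  1500 SNPs with MAF uniform on [0.05, 0.5] in nine functional groups, a
  recessive-acting SNP whose homozygous-variant effect is gender-specific
  (male OR 2.13, female OR 1.56) at MAF 0.19, one marginal-free epistatic
  pair and one epistatic pair with main effects.
* **XOR calibration.** A dominant-coded XOR table with equal-MAF SNPs has
  exactly zero marginal effects only when the carrier frequency is 1/2,
  i.e. MAF `1 − 1/√2 ≈ 0.2929` (`xor_null_maf()`); with equal carrier
  frequencies elsewhere the two marginal-nullity constraints are singular
  and cannot be satisfied by any non-null table. The recovery analyses use
  MAF 0.3, essentially at the calibrated point, so the injected pair is
  invisible to single-SNP scans.
* SNPs are in linkage equilibrium by construction. Real panels have LD,
  batch structure, differential missingness and genotyping error; passing
  tests on this generator demonstrates correctness and calibration of the
  statistics, not robustness to those artefacts.
* A performance note: SNPs with no disease effect are conditionally
  independent of status, so they are drawn only for the sampled subjects —
  an exact shortcut that makes genome-scale null panels cheap.

## Problem sizes and numerical conventions

The test and acceptance suites run at these scales, chosen to balance
statistical resolution against desk-scale runtimes: null calibration of
both permutation tests over 100 datasets of 200/200 subjects × 10 SNPs at
100 permutations; epistasis recovery over 25 replicates of 1500/1500 × 20
SNPs; CI coverage over 200 replicates at 563/863; λ and Q-Q diagnostics on
a single 2000-SNP null panel; exact-HWE verification exhaustively for all
genotype triples with n ≤ 200. Binomial acceptance regions at the exact
null rejection probability (5/101 for 100-permutation tests at α = 0.05)
keep the stochastic checks honest.

Seeds control every random element (fold assignment, permutations,
simulation); identical seed and configuration give bit-identical output,
and output tables carry the configuration and seed as header comments.

## Limitations

* The package does not attempt to reproduce covariate-adjusted estimates,
  MDR statistics, or network figures published from subject-level data that
  was never deposited; only count-derived arithmetic from published tables
  is exactly reproducible, and the bundled fixtures carry those counts.
  One printed collapsed-row percentage (33.1 for 186/563) is internally
  inconsistent with its own counts by 0.1; the acceptance suite documents
  it rather than papering over it.
* No LD modelling, phasing, imputation, or VCF ingestion; array-style
  TSV and PED/MAP cover the intended inputs.
* No principal-components correction; λ and Q-Q are diagnostics only.
* ReliefF filtering is heuristic; its sensitivity depends on neighborhood
  size and effect strength as described above, and exhaustive MDR search
  remains the arbiter on the filtered set.
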
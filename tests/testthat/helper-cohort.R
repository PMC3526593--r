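# Shared fixture builders: small cohorts generated in code at test time.

# covariate model with no covariate-disease effects (pure genotype signal)
null_covariate_model <- function() {
  cm <- default_covariate_model()
  cm$or_male <- 1
  cm$or_age <- rep(1, 6)
  cm$or_smoking <- c(never = 1, former = 1, current = 1)
  cm$smoking_missing_rate <- 0
  cm
}

# cohort with no genotype effects
null_cohort <- function(n_cases, n_controls, n_snps, seed,
                        covariate_model = default_covariate_model(), ...) {
  simulate_cohort(simulation_spec(
    n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
    covariate_model = covariate_model, rng_seed = seed, ...))
}

# cohort with a dominant-coded XOR pair on the last two SNPs
xor_cohort <- function(n_cases, n_controls, n_snps, effect_size, seed,
                       maf = xor_null_maf(),
                       covariate_model = default_covariate_model()) {
  a <- sprintf("snp_%04d", n_snps - 1L)
  b <- sprintf("snp_%04d", n_snps)
  sim <- simulate_cohort(simulation_spec(
    n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
    covariate_model = covariate_model,
    maf_overrides = stats::setNames(c(maf, maf), c(a, b)),
    epistasis_pairs = list(list(snp_a = a, snp_b = b,
                                penetrance = xor_penetrance(effect_size))),
    rng_seed = seed))
  sim$pair <- c(a, b)
  sim
}

# deterministic balanced binary XOR dataset (doses 0/2), IG exactly 1 bit
deterministic_xor <- function(reps = 25) {
  a <- rep(c(0L, 0L, 2L, 2L), reps)
  b <- rep(c(0L, 2L, 0L, 2L), reps)
  list(a = a, b = b, status = as.integer(xor(a > 0, b > 0)))
}

status_of <- function(sim) {
  sim$subjects$status[match(rownames(sim$genotypes), sim$subjects$subject_id)]
}
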
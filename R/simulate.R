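#' Specify a synthetic case-control cohort
#'
#' Defines the generative model for a synthetic cohort: per-SNP minor allele
#' frequencies drawn uniformly (with optional per-SNP overrides), covariates
#' (gender, six age strata, smoking) with configurable marginal structure and
#' disease effects, SNP main effects on a chosen genetic coding, SNP-by-gender
#' interactions, and SNP-SNP epistasis injected as logit offsets from a
#' penetrance table. Disease status follows a logistic model; a population
#' pool is generated at the target prevalence and then sampled without
#' replacement to exactly `n_cases` cases and `n_controls` controls
#' (case-control sampling), which leaves all odds ratios on SNPs and
#' covariates identifiable.
#'
#' @param n_cases,n_controls Exact numbers of cases and controls to return.
#' @param n_snps Number of SNPs.
#' @param maf_range Range of the uniform minor-allele-frequency distribution.
#' @param maf_overrides Named numeric vector fixing the MAF of specific SNPs
#'   (names are SNP ids such as `"snp_0001"`).
#' @param covariate_model List with elements `p_male`, `age_probs` (length 6),
#'   `smoking_probs` (never/former/current), `or_male`, `or_age` (length 6,
#'   first element 1), `or_smoking` (length 3, first element 1),
#'   `stage_probs` (non-invasive/invasive/tis, cases only),
#'   `smoking_missing_rate`. Defaults are the study-calibrated values of
#'   [nh_study_spec()].
#' @param main_effects Data frame with columns `snp_id`, `coding`
#'   (`"dominant"`, `"recessive"` or `"per_dose"`), `or`.
#' @param gender_interactions Data frame with columns `snp_id`, `coding`,
#'   `or_male`, `or_female`.
#' @param epistasis_pairs List of lists with elements `snp_a`, `snp_b`,
#'   `penetrance` (3x3 risk-multiplier matrix indexed by dose, see
#'   [xor_penetrance()]).
#' @param missing_rate Independent per-entry genotype missingness rate.
#' @param prevalence Target population disease prevalence used to solve the
#'   logistic intercept numerically.
#' @param pool_multiplier Population pool size as a multiple of
#'   `n_cases + n_controls`.
#' @param rng_seed Integer seed; identical seed gives bit-identical cohorts.
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_cases, n_controls, n_snps,
                            maf_range = c(0.05, 0.5),
                            maf_overrides = NULL,
                            covariate_model = default_covariate_model(),
                            main_effects = NULL,
                            gender_interactions = NULL,
                            epistasis_pairs = list(),
                            missing_rate = 0,
                            prevalence = 0.05,
                            pool_multiplier = 20,
                            rng_seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_snps >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate < 1,
            prevalence > 0, prevalence < 1, pool_multiplier >= 2)
  cm <- covariate_model
  stopifnot(cm$p_male > 0, cm$p_male < 1,
            length(cm$age_probs) == 6, all(cm$age_probs > 0),
            length(cm$smoking_probs) == 3, all(cm$smoking_probs > 0),
            length(cm$or_age) == 6, all(cm$or_age > 0),
            length(cm$or_smoking) == 3, all(cm$or_smoking > 0),
            cm$or_male > 0, length(cm$stage_probs) == 3,
            cm$smoking_missing_rate >= 0, cm$smoking_missing_rate < 1)
  if (!is.null(main_effects)) {
    stopifnot(all(c("snp_id", "coding", "or") %in% names(main_effects)),
              all(main_effects$coding %in% c("dominant", "recessive", "per_dose")),
              all(main_effects$or > 0))
  }
  if (!is.null(gender_interactions)) {
    stopifnot(all(c("snp_id", "coding", "or_male", "or_female") %in%
                    names(gender_interactions)),
              all(gender_interactions$or_male > 0),
              all(gender_interactions$or_female > 0))
  }
  for (ep in epistasis_pairs) {
    stopifnot(is.matrix(ep$penetrance), all(dim(ep$penetrance) == c(3, 3)),
              all(is.finite(ep$penetrance)), all(ep$penetrance > 0))
  }
  spec <- list(n_cases = as.integer(n_cases),
               n_controls = as.integer(n_controls),
               n_snps = as.integer(n_snps),
               maf_range = maf_range, maf_overrides = maf_overrides,
               covariate_model = cm, main_effects = main_effects,
               gender_interactions = gender_interactions,
               epistasis_pairs = epistasis_pairs,
               missing_rate = missing_rate, prevalence = prevalence,
               pool_multiplier = pool_multiplier,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "simulation_spec"
  spec
}

#' Default covariate model for the synthetic cohort
#'
#' Marginal probabilities and disease odds ratios chosen so that a sampled
#' 863-control / 563-case cohort reproduces the covariate structure typical
#' of a male-predominant smoking-related cancer: about 62% male controls vs
#' 76% male cases, control smoking distribution about 34/50/16%
#' (never/former/current) with current smoking the strongest covariate
#' effect, age concentrated in the upper strata, and about 84.5% of cases
#' non-invasive at diagnosis.
#'
#' @return A list suitable for the `covariate_model` argument of
#'   [simulation_spec()].
#' @export
default_covariate_model <- function() {
  list(
    p_male = 0.60,
    age_probs = c(0.025, 0.075, 0.155, 0.25, 0.25, 0.245),
    smoking_probs = c(never = 0.34, former = 0.50, current = 0.16),
    or_male = 1.9,
    or_age = c(1, 1, 1.5, 1.8, 1.7, 1.6),
    or_smoking = c(never = 1, former = 1.9, current = 4.1),
    stage_probs = c(0.845, 0.098, 0.057),
    smoking_missing_rate = 0.015
  )
}

#' Study-scale simulation specification
#'
#' The reference conditions the pipeline is exercised under: 563 cases, 863
#' controls, 1500 SNPs with MAF uniform on [0.05, 0.5], the default covariate
#' model, one recessive-acting SNP whose homozygous-variant effect is
#' gender-specific (male OR 2.13, female OR 1.56, overall close to 1.9) at
#' MAF 0.19, one epistatic pair without marginal effects (dominant-coded XOR,
#' effect 2, at the MAF where carrier frequency is 1/2 so marginals vanish),
#' and one epistatic pair with marginal effects.
#'
#' @param rng_seed Integer seed.
#' @param n_snps Number of SNPs (default 1500).
#' @return A [simulation_spec()].
#' @export
nh_study_spec <- function(rng_seed = 1L, n_snps = 1500L) {
  with_mains <- outer(c(1, 1.3, 1.3), c(1, 1.3, 1.3)) *
    ifelse(outer(0:2, 0:2, function(i, j) i > 0 & j > 0), 2, 1)
  simulation_spec(
    n_cases = 563L, n_controls = 863L, n_snps = n_snps,
    maf_overrides = c(snp_0001 = 0.19,
                      snp_0003 = xor_null_maf(), snp_0004 = xor_null_maf(),
                      snp_0005 = 0.30, snp_0006 = 0.30),
    gender_interactions = data.frame(
      snp_id = "snp_0001", coding = "recessive",
      or_male = 2.13, or_female = 1.56, stringsAsFactors = FALSE),
    epistasis_pairs = list(
      list(snp_a = "snp_0003", snp_b = "snp_0004",
           penetrance = xor_penetrance(2)),
      list(snp_a = "snp_0005", snp_b = "snp_0006", penetrance = with_mains)),
    rng_seed = rng_seed
  )
}

#' Dominant-coded XOR penetrance table
#'
#' Risk-multiplier table assigning elevated risk to joint genotypes where
#' exactly one of the two SNPs carries a variant allele (dominant coding) --
#' the canonical pure-epistasis pattern with no marginal effects. Marginal
#' dose-disease association of each SNP alone is exactly null when the
#' dominant carrier frequency of both SNPs is 1/2, i.e. at
#' MAF = 1 - 1/sqrt(2) (about 0.293, see [xor_null_maf()]); away from that
#' frequency small marginal effects leak through.
#'
#' @param effect_size Risk multiplier for the discordant-carrier cells
#'   (>= 1); `effect_size = 1` gives the null table of all ones.
#' @return A 3x3 numeric matrix indexed by (dose_a, dose_b).
#' @export
xor_penetrance <- function(effect_size) {
  stopifnot(effect_size >= 1)
  xor_cell <- outer(0:2, 0:2, function(i, j) (i > 0) != (j > 0))
  tab <- ifelse(xor_cell, effect_size, 1)
  dimnames(tab) <- list(dose_a = 0:2, dose_b = 0:2)
  tab
}

#' MAF at which the dominant-XOR table has exactly null marginals
#'
#' @return `1 - 1/sqrt(2)`, the minor allele frequency giving dominant
#'   carrier frequency 1/2 under Hardy-Weinberg proportions.
#' @export
xor_null_maf <- function() 1 - sqrt(0.5)

# effect design column for one SNP under a genetic coding
coding_column <- function(dose, coding) {
  switch(coding,
         dominant = as.numeric(dose >= 1),
         recessive = as.numeric(dose == 2),
         per_dose = as.numeric(dose),
         stop("unknown coding: ", coding))
}

#' Simulate a case-control cohort
#'
#' Generates a population pool under the spec's logistic disease model,
#' solves the intercept so population prevalence matches `spec$prevalence`,
#' draws disease status, and samples exactly `n_cases` cases and
#' `n_controls` controls without replacement. Genotypes are drawn under
#' Hardy-Weinberg proportions at each SNP's MAF. SNPs with no effect on
#' disease are conditionally independent of status, so they are drawn only
#' for the sampled subjects (an exact shortcut that keeps large `n_snps`
#' cheap). SNPs are assigned round-robin to the nine functional groups.
#'
#' @param spec A [simulation_spec()].
#' @return List with elements `genotypes` ([genotype_matrix()]), `subjects`
#'   ([subject_table()]), `annotation` ([snp_annotation()]), and `maf`
#'   (the realised per-SNP MAF vector).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$rng_seed, {
    cm <- spec$covariate_model
    snp_ids <- sprintf("snp_%04d", seq_len(spec$n_snps))
    maf <- stats::runif(spec$n_snps, spec$maf_range[1], spec$maf_range[2])
    names(maf) <- snp_ids
    if (!is.null(spec$maf_overrides)) {
      unknown <- setdiff(names(spec$maf_overrides), snp_ids)
      if (length(unknown)) stop("maf_overrides for unknown SNPs: ",
                                paste(unknown, collapse = ", "))
      maf[names(spec$maf_overrides)] <- spec$maf_overrides
    }
    effect_snps <- unique(c(spec$main_effects$snp_id,
                            spec$gender_interactions$snp_id,
                            unlist(lapply(spec$epistasis_pairs,
                                          function(e) c(e$snp_a, e$snp_b)))))
    unknown <- setdiff(effect_snps, snp_ids)
    if (length(unknown)) stop("effects reference unknown SNPs: ",
                              paste(unknown, collapse = ", "))

    n_pool <- as.integer(ceiling(spec$pool_multiplier *
                                   (spec$n_cases + spec$n_controls)))
    male <- stats::rbinom(n_pool, 1, cm$p_male)
    age <- sample.int(6L, n_pool, replace = TRUE,
                      prob = cm$age_probs / sum(cm$age_probs))
    smoking <- sample.int(3L, n_pool, replace = TRUE,
                          prob = cm$smoking_probs / sum(cm$smoking_probs))

    pool_eff <- matrix(0L, n_pool, length(effect_snps),
                       dimnames = list(NULL, effect_snps))
    for (s in effect_snps) pool_eff[, s] <- stats::rbinom(n_pool, 2, maf[s])

    eta <- log(cm$or_male) * male + log(cm$or_age)[age] +
      log(cm$or_smoking)[smoking]
    if (!is.null(spec$main_effects)) {
      for (i in seq_len(nrow(spec$main_effects))) {
        me <- spec$main_effects[i, ]
        eta <- eta + log(me$or) *
          coding_column(pool_eff[, me$snp_id], me$coding)
      }
    }
    if (!is.null(spec$gender_interactions)) {
      for (i in seq_len(nrow(spec$gender_interactions))) {
        gi <- spec$gender_interactions[i, ]
        x <- coding_column(pool_eff[, gi$snp_id], gi$coding)
        eta <- eta + x * (log(gi$or_male) * male +
                            log(gi$or_female) * (1 - male))
      }
    }
    for (ep in spec$epistasis_pairs) {
      eta <- eta + log(ep$penetrance)[pool_eff[, ep$snp_a] +
                                        3L * pool_eff[, ep$snp_b] + 1L]
    }
    beta0 <- stats::uniroot(
      function(b) mean(stats::plogis(b + eta)) - spec$prevalence,
      lower = -40, upper = 20, tol = 1e-10)$root
    status <- stats::rbinom(n_pool, 1, stats::plogis(beta0 + eta))

    case_pool <- which(status == 1L)
    ctrl_pool <- which(status == 0L)
    if (length(case_pool) < spec$n_cases) {
      stop(sprintf(
        "simulated case pool (%d) smaller than requested n_cases (%d); increase pool_multiplier",
        length(case_pool), spec$n_cases))
    }
    if (length(ctrl_pool) < spec$n_controls) {
      stop(sprintf(
        "simulated control pool (%d) smaller than requested n_controls (%d); increase pool_multiplier",
        length(ctrl_pool), spec$n_controls))
    }
    sel <- c(sample(case_pool, spec$n_cases),
             sample(ctrl_pool, spec$n_controls))
    n_sel <- length(sel)
    subject_ids <- sprintf("subj_%05d", seq_len(n_sel))

    doses <- matrix(NA_integer_, n_sel, spec$n_snps,
                    dimnames = list(subject_ids, snp_ids))
    neutral <- setdiff(snp_ids, effect_snps)
    if (length(neutral)) {
      doses[, neutral] <- stats::rbinom(n_sel * length(neutral), 2,
                                        rep(maf[neutral], each = n_sel))
    }
    if (length(effect_snps)) doses[, effect_snps] <- pool_eff[sel, , drop = FALSE]

    stage <- rep("not-applicable", n_sel)
    is_case <- seq_len(n_sel) <= spec$n_cases
    stage[is_case] <- c("non-invasive", "invasive", "tis")[
      sample.int(3L, spec$n_cases, replace = TRUE,
                 prob = cm$stage_probs / sum(cm$stage_probs))]
    smk <- SMOKING_LEVELS[smoking[sel]]
    if (cm$smoking_missing_rate > 0) {
      smk[stats::runif(n_sel) < cm$smoking_missing_rate] <- NA
    }
    subjects <- subject_table(data.frame(
      subject_id = subject_ids,
      status = as.integer(is_case),
      age_group = AGE_LEVELS[age[sel]],
      gender = GENDER_LEVELS[male[sel] + 1L],
      smoking = smk,
      stage = stage,
      stringsAsFactors = FALSE))

    genotypes <- genotype_matrix(doses)
    if (spec$missing_rate > 0) {
      genotypes <- embed_missingness(genotypes, spec$missing_rate,
                                     seed = stats::runif(1, 0, 2^30))
    }
    annotation <- snp_annotation(data.frame(
      snp_id = snp_ids,
      rsid = sprintf("rs%07d", seq_len(spec$n_snps)),
      gene = sprintf("GENE%04d", (seq_len(spec$n_snps) - 1L) %/% 3L + 1L),
      functional_group = functional_groups()[
        (seq_len(spec$n_snps) - 1L) %% 9L + 1L],
      stringsAsFactors = FALSE))

    list(genotypes = genotypes, subjects = subjects,
         annotation = annotation, maf = maf)
  })
}

#' Set genotype entries missing at random
#'
#' @param genotypes A [genotype_matrix()].
#' @param rate Overall per-entry missingness rate in [0, 1).
#' @param seed Integer seed (same seed, same mask).
#' @param per_snp_rates Optional numeric vector (length `ncol`) of per-SNP
#'   rates, overriding `rate`, so that some SNPs can be pushed below the
#'   call-rate filter.
#' @return The genotype matrix with entries set to `NA`.
#' @export
embed_missingness <- function(genotypes, rate, seed, per_snp_rates = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0 && is.null(per_snp_rates)) return(genotypes)
  with_seed(seed, {
    r <- if (is.null(per_snp_rates)) rate else {
      stopifnot(length(per_snp_rates) == ncol(genotypes),
                all(per_snp_rates >= 0), all(per_snp_rates < 1))
      per_snp_rates
    }
    mask <- matrix(stats::runif(length(genotypes)) <
                     rep(r, each = nrow(genotypes)),
                   nrow = nrow(genotypes))
    genotypes[mask] <- NA_integer_
    genotypes
  })
}
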
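#' Minor allele frequency from genotype counts
#'
#' @param n_wildtype,n_het,n_hom_variant Genotype counts for one SNP in one
#'   subject stratum.
#' @return `min(p, 1 - p)` where `p` is the variant allele frequency
#'   `(2 * n_hom_variant + n_het) / (2 * total)`.
#' @export
maf <- function(n_wildtype, n_het, n_hom_variant) {
  total <- n_wildtype + n_het + n_hom_variant
  if (total <= 0) stop("cannot compute MAF from zero genotypes")
  p <- (2 * n_hom_variant + n_het) / (2 * total)
  min(p, 1 - p)
}

#' Hardy-Weinberg chi-square test
#'
#' One-degree-of-freedom goodness-of-fit chi-square comparing observed
#' genotype counts to Hardy-Weinberg expectations at the observed allele
#' frequency, without continuity correction.
#'
#' @inheritParams maf
#' @return List with `statistic` and `p_value`. A monomorphic SNP gives
#'   p = 1 with a warning (the test is undefined).
#' @export
hwe_chisq <- function(n_wildtype, n_het, n_hom_variant) {
  n <- n_wildtype + n_het + n_hom_variant
  if (n <= 0) stop("cannot test HWE with zero genotypes")
  p <- (2 * n_hom_variant + n_het) / (2 * n)
  if (p == 0 || p == 1) {
    warning("monomorphic SNP: HWE test undefined, returning p = 1")
    return(list(statistic = 0, p_value = 1))
  }
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  observed <- c(n_wildtype, n_het, n_hom_variant)
  stat <- sum((observed - expected)^2 / expected)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Exact Hardy-Weinberg test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the summed probability of all heterozygote counts whose conditional
#' probability does not exceed that of the observed configuration. The full
#' conditional distribution over heterozygote counts is enumerated (log-gamma
#' arithmetic, vectorised).
#'
#' @inheritParams maf
#' @return The exact p-value. Monomorphic SNPs return 1 with a warning.
#' @export
hwe_exact <- function(n_wildtype, n_het, n_hom_variant) {
  n <- n_wildtype + n_het + n_hom_variant
  if (n <= 0) stop("cannot test HWE with zero genotypes")
  n_minor <- 2 * min(n_wildtype, n_hom_variant) + n_het
  n_minor <- min(n_minor, 2 * n - n_minor)
  if (n_minor == 0) {
    warning("monomorphic SNP: HWE test undefined, returning p = 1")
    return(1)
  }
  probs <- hwe_het_distribution(n, n_minor)
  obs <- n_het
  # heterozygote count shares the parity of the minor allele count
  p_obs <- probs[(obs - n_minor %% 2) / 2 + 1]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# Conditional null distribution of the heterozygote count given n subjects
# and n_minor copies of the minor allele. Heterozygote counts run over
# n_minor %% 2, n_minor %% 2 + 2, ..., min(n_minor, 2n - n_minor).
# P(h) = C(n, h0, h, h2) 2^h / C(2n, n_minor), with h0/h2 the homozygote
# counts; computed in log space and normalised.
hwe_het_distribution <- function(n, n_minor) {
  n_major <- 2 * n - n_minor
  h <- seq.int(n_minor %% 2, min(n_minor, n_major), by = 2)
  hom_minor <- (n_minor - h) / 2
  hom_major <- n - h - hom_minor
  logp <- lgamma(n + 1) - lgamma(hom_major + 1) - lgamma(h + 1) -
    lgamma(hom_minor + 1) + h * log(2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p / sum(p)
}

#' Per-SNP call rate
#'
#' @param genotype_column Vector of dose codes with `NA` for missing calls.
#' @return Fraction of non-missing calls.
#' @export
call_rate <- function(genotype_column) {
  if (length(genotype_column) == 0) stop("empty genotype column")
  mean(!is.na(genotype_column))
}

#' Genomic inflation factor
#'
#' Median-based estimator: the median observed 1-df chi-square association
#' statistic divided by the median of the chi-square(1) distribution
#' (0.4549...). P-values are first converted to chi-square(1) quantiles.
#'
#' @param p_values Vector of association p-values (used if `statistics`
#'   missing).
#' @param statistics Vector of 1-df chi-square statistics.
#' @return Lambda. A warning is issued below 100 values (the estimator is
#'   noisy).
#' @export
genomic_inflation <- function(p_values = NULL, statistics = NULL) {
  if (is.null(statistics)) {
    if (is.null(p_values) || length(p_values) == 0) {
      stop("supply p_values or statistics")
    }
    statistics <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  }
  statistics <- statistics[is.finite(statistics)]
  if (length(statistics) == 0) stop("no finite statistics")
  if (length(statistics) < 100) {
    warning("genomic inflation estimated from fewer than 100 statistics")
  }
  stats::median(statistics) / stats::qchisq(0.5, df = 1)
}

#' Q-Q plot coordinates for p-values
#'
#' @param p_values Vector of p-values in (0, 1]; zeros are capped with a
#'   warning.
#' @param zero_cap Value substituted for p = 0 before taking logs.
#' @return Data frame with columns `expected` and `observed`, both on the
#'   -log10 scale, sorted so the smallest p-values come last. Expected
#'   quantiles are the uniform order statistics i/(n+1).
#' @export
qq_points <- function(p_values, zero_cap = 1e-30) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p <- p_values[!is.na(p_values)]
  if (any(p == 0)) {
    warning("p-values equal to 0 capped at ", zero_cap)
    p[p == 0] <- zero_cap
  }
  n <- length(p)
  data.frame(expected = -log10(seq_len(n) / (n + 1)),
             observed = sort(-log10(p), decreasing = TRUE))
}

#' Marker-level QC report
#'
#' Applies the marker exclusion rule -- a SNP fails iff its MAF or its call
#' rate falls below threshold -- and reports per-SNP diagnostics including
#' both Hardy-Weinberg tests computed in controls only.
#'
#' @param genotypes A [genotype_matrix()].
#' @param subjects A [subject_table()]; HWE uses controls only.
#' @param config An [analysis_config()].
#' @return Data frame (class `"qc_report"`) with one row per SNP: call rate,
#'   MAF, control genotype counts, HWE chi-square statistic/p and exact p,
#'   `pass` flag and `fail_reason`.
#' @export
qc_report <- function(genotypes, subjects, config = analysis_config()) {
  ctrl <- subjects$subject_id[subjects$status == 0L]
  ctrl <- intersect(ctrl, rownames(genotypes))
  if (length(ctrl) == 0) stop("no controls found for HWE testing")
  g_ctrl <- genotypes[ctrl, , drop = FALSE]
  res <- lapply(seq_len(ncol(genotypes)), function(j) {
    col <- genotypes[, j]
    cr <- call_rate(col)
    counts <- tabulate(col + 1L, nbins = 3L)
    m <- if (sum(counts) > 0) maf(counts[1], counts[2], counts[3]) else NA_real_
    cc <- tabulate(g_ctrl[, j] + 1L, nbins = 3L)
    if (sum(cc) > 0 && (cc[2] > 0 || (cc[1] > 0 && cc[3] > 0))) {
      ch <- hwe_chisq(cc[1], cc[2], cc[3])
      ex <- hwe_exact(cc[1], cc[2], cc[3])
    } else {
      ch <- list(statistic = 0, p_value = 1)
      ex <- 1
    }
    data.frame(snp_id = colnames(genotypes)[j], call_rate = cr, maf = m,
               ctrl_wildtype = cc[1], ctrl_het = cc[2], ctrl_hom = cc[3],
               hwe_chisq = ch$statistic, hwe_chisq_p = ch$p_value,
               hwe_exact_p = ex, stringsAsFactors = FALSE)
  })
  rpt <- do.call(rbind, res)
  fail_maf <- !is.na(rpt$maf) & rpt$maf < config$maf_threshold
  fail_cr <- rpt$call_rate < config$call_rate_threshold
  rpt$pass <- !(fail_maf | fail_cr)
  rpt$fail_reason <- ifelse(fail_maf & fail_cr, "maf;call_rate",
                            ifelse(fail_maf, "maf",
                                   ifelse(fail_cr, "call_rate", "")))
  class(rpt) <- c("qc_report", "data.frame")
  rpt
}
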
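test_that("IRLS slope on saturated 2x2 designs equals the log cross-product ratio", {
  fit_2x2 <- function(a, b, c_, d) {
    x <- c(rep(1, a + c_), rep(0, b + d))
    y <- c(rep(1, a), rep(0, c_), rep(1, b), rep(0, d))
    fit_logistic(cbind(intercept = 1, exposure = x), y)
  }
  set.seed(31)
  for (i in 1:20) {
    k <- sample(5:200, 4, replace = TRUE)
    fit <- fit_2x2(k[1], k[2], k[3], k[4])
    expect_equal(unname(fit$coefficients["exposure"]),
                 log(k[1] * k[4] / (k[2] * k[3])), tolerance = 1e-8)
  }
  # homozygous-variant vs wildtype counts for the hormone-pathway SNP:
  # 86/377 cases, 75/606 controls -> crude log-OR ln(1.843)
  fit <- fit_2x2(86, 377, 75, 606)
  expect_equal(unname(fit$coefficients["exposure"]),
               log((86 * 606) / (75 * 377)), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["exposure"]), 0.6115, tolerance = 1e-4)
})

test_that("singular designs error naming the column; separation is flagged", {
  x <- cbind(intercept = 1, a = c(1, 0, 1, 0), b = c(2, 0, 2, 0))
  expect_error(fit_logistic(x, c(1, 0, 1, 0)), "collinear.*b")
  sep <- fit_logistic(cbind(intercept = 1, x = c(0, 0, 1, 1, 0, 1)),
                      c(0, 0, 1, 1, 0, 1))
  expect_true(sep$separation)
  expect_false(sep$converged)
})

test_that("BH adjustment matches hand arithmetic and the min-over-tail oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_identical(bh_fdr(numeric(0)), numeric(0))

  oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      tail_vals <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
      q[o[i]] <- min(1, min(tail_vals))
    }
    q
  }
  set.seed(99)
  for (r in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle(p), tolerance = 1e-12)
  }
  # permutation invariance and monotonicity
  p <- runif(25)
  perm <- sample(25)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  q <- bh_fdr(p)
  expect_true(all(q[order(p)] == cummax(q[order(p)])))
  expect_true(all(q >= p))
})

test_that("likelihood ratio test is zero on identical models and chi-square under null", {
  x <- cbind(1, rbinom(200, 1, 0.5))
  y <- rbinom(200, 1, 0.4)
  f <- fit_logistic(x, y)
  t0 <- lrt(f, f, df = 1)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  set.seed(12)
  stats1 <- replicate(400, {
    y <- rbinom(250, 1, 0.4)
    x <- rbinom(250, 1, 0.5)
    full <- fit_logistic(cbind(i = 1, x = x), y)
    red <- fit_logistic(cbind(i = rep(1, 250)), y)
    lrt(full, red, df = 1)$statistic
  })
  expect_gt(suppressWarnings(
    ks.test(stats1, function(q) pchisq(q, 1))$p.value), 0.01)
})

test_that("adjusted scan flags unstable cells and controls type-I error", {
  set.seed(5)
  sim <- null_cohort(250, 250, 60, seed = 5,
                     covariate_model = null_covariate_model())
  # force a rare SNP: roughly 10 variant carriers overall
  g <- unclass(sim$genotypes)
  g[, 1] <- 0L
  carriers <- sample(nrow(g), 18)
  g[carriers, 1] <- 1L
  g <- genotype_matrix(g)
  res <- single_snp_scan(g, sim$subjects, sim$annotation,
                         codings = "dominant")
  expect_false(res$min_cell_ok[res$snp_id == "snp_0001"])
  expect_true(all(res$fdr_adjusted_p >= res$p, na.rm = TRUE))
  # null type-I on the remaining SNPs
  p <- res$p[res$snp_id != "snp_0001"]
  rej <- sum(p < 0.05, na.rm = TRUE)
  bounds <- qbinom(c(0.005, 0.995), sum(!is.na(p)), 0.05)
  expect_gte(rej, bounds[1])
  expect_lte(rej, bounds[2])
})

test_that("gender-stratified scan equals the overall scan on that gender subset", {
  sim <- null_cohort(150, 150, 12, seed = 77)
  res_strat <- single_snp_scan(sim$genotypes, sim$subjects, sim$annotation,
                               stratum = "male", codings = "dominant")
  males <- sim$subjects$subject_id[sim$subjects$gender == "male"]
  subj_m <- sim$subjects[sim$subjects$subject_id %in% males, ]
  class(subj_m) <- class(sim$subjects)
  res_sub <- single_snp_scan(sim$genotypes[males, ], subj_m, sim$annotation,
                             stratum = "overall", codings = "dominant")
  expect_equal(res_strat$or, res_sub$or, tolerance = 1e-10)
  expect_equal(res_strat$p, res_sub$p, tolerance = 1e-10)
})

test_that("a genotype effect identical in both genders gives a null interaction", {
  # mirror-image construction: the male and female blocks are identical,
  # so the interaction MLE is exactly zero
  block <- expand.grid(x = c(0L, 1L, 2L), y = c(0L, 1L))
  block <- block[rep(seq_len(nrow(block)), times = c(30, 20, 10, 15, 20, 25)), ]
  n <- nrow(block)
  df <- data.frame(
    subject_id = sprintf("s%04d", seq_len(2 * n)),
    status = rep(block$y, 2),
    gender = rep(c("male", "female"), each = n))
  subj <- subject_table(df)
  g <- genotype_matrix(matrix(rep(block$x, 2), ncol = 1,
                              dimnames = list(df$subject_id, "snpX")))
  res <- snp_covariate_interaction(g, subj, "snpX", "gender",
                                   coding = "dominant")
  expect_lt(res$lrt_statistic, 1e-6)
  expect_equal(res$stratum_or$or[1], res$stratum_or$or[2], tolerance = 1e-6)
})

test_that("joint-genotype models reproduce crude cross-product ratios", {
  # collapsed two-SNP counts: referent 689 controls / 488 cases,
  # doubly-exposed 149 controls / 85 cases -> crude OR 0.805
  n <- c(ref_ctrl = 689, ref_case = 488, exp_ctrl = 149, exp_case = 85)
  da <- c(rep(0L, n[1] + n[2]), rep(1L, n[3] + n[4]))
  db <- da
  y <- c(rep(0L, n[1]), rep(1L, n[2]), rep(0L, n[3]), rep(1L, n[4]))
  ids <- sprintf("s%05d", seq_along(y))
  g <- genotype_matrix(cbind(snpA = da, snpB = db),
                       subject_ids = ids, snp_ids = c("snpA", "snpB"))
  subj <- subject_table(data.frame(subject_id = ids, status = y))
  expect_warning(
    res <- snp_snp_interaction(g, subj, "snpA", "snpB", collapsing = "dom_dom"),
    "not estimable")
  expect_true(is.na(res$interaction_p))
  or_both <- res$group_or$or[res$group_or$group == "both_carrier"]
  expect_equal(or_both, (85 * 689) / (149 * 488), tolerance = 1e-6)
  expect_equal(or_both, 0.805, tolerance = 1e-3)

  # collapsing everything into one group is not estimable
  expect_error(snp_snp_interaction(g, subj, "snpA", "snpB",
                                   collapsing = function(cell) rep("all", length(cell))),
               "single group")
})

test_that("the interaction LRT detects an epistatic pair at scale", {
  hits <- 0L
  for (r in 1:8) {
    sim <- xor_cohort(750, 750, 6, effect_size = 2, seed = 900 + r, maf = 0.3)
    res <- snp_snp_interaction(sim$genotypes, sim$subjects,
                               sim$pair[1], sim$pair[2])
    hits <- hits + (res$interaction_p < 0.05)
  }
  expect_gte(hits, 6)
})
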
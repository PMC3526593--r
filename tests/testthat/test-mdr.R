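test_that("cell labeling follows the threshold rule including ties and empties", {
  # T = 1: 10 cases / 20 controls is low; 5 / 2 is high
  expect_identical(mdr_classify_cells(c(10, 5), c(20, 2), T = 1),
                   c(FALSE, TRUE))
  # exactly at threshold -> high
  expect_true(mdr_classify_cells(10, 10, T = 1))
  # empty cell -> low; cases with zero controls -> high
  expect_identical(mdr_classify_cells(c(0, 3), c(0, 0), T = 1),
                   c(FALSE, TRUE))
  # scale invariance: duplicating every subject changes nothing
  set.seed(40)
  cases <- rpois(9, 6); ctrls <- rpois(9, 8)
  expect_identical(mdr_classify_cells(cases, ctrls, 0.7),
                   mdr_classify_cells(2 * cases, 2 * ctrls, 0.7))
})

test_that("threshold labeling attains the brute-force optimal training accuracy", {
  # oracle: enumerate all 2^9 labelings of a 3x3 table and maximise
  # balanced training accuracy; the T-rule must attain that maximum
  set.seed(41)
  for (r in 1:25) {
    cases <- rpois(9, 4)
    ctrls <- rpois(9, 5)
    if (sum(cases) == 0 || sum(ctrls) == 0) next
    T <- sum(cases) / sum(ctrls)
    ours <- mdr_classify_cells(cases, ctrls, T)
    ba <- function(high) {
      (sum(cases[high]) / sum(cases) + sum(ctrls[!high]) / sum(ctrls)) / 2
    }
    best <- max(vapply(0:(2^9 - 1), function(mask) {
      ba(as.logical(bitwAnd(bitwShiftR(mask, 0:8), 1L)))
    }, numeric(1)))
    expect_equal(ba(ours), best, tolerance = 1e-12)
  }
})

test_that("balanced accuracy arithmetic and degenerate inputs", {
  status <- rep(c(1L, 0L), c(10, 20))
  expect_equal(balanced_accuracy(status == 1L, status), 1)
  expect_equal(balanced_accuracy(rep(TRUE, 30), status), 0.5)
  # sens 0.8, spec 0.6 -> 0.7
  pred <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 8), rep(FALSE, 12))
  expect_equal(balanced_accuracy(pred, status), 0.7)
  expect_error(balanced_accuracy(rep(TRUE, 5), rep(1L, 5)), "both classes")
})

test_that("a perfectly predictive SNP wins every fold with testing BA 1", {
  set.seed(42)
  n <- 200
  status <- rep(c(1L, 0L), each = n / 2)
  g <- cbind(perfect = ifelse(status == 1L, 2L, 0L),
             noise1 = rbinom(n, 2, 0.3), noise2 = rbinom(n, 2, 0.4))
  rownames(g) <- sprintf("s%03d", 1:n)
  m <- mdr_cross_validate(g, status, colnames(g), k_way = 1, cv_folds = 10,
                          seed = 2)
  expect_identical(m$snps, "perfect")
  expect_identical(m$cvc, 10L)
  expect_equal(m$testing_ba, 1)
  expect_equal(m$training_ba, 1)
  expect_identical(unname(m$cell_labels[c("0", "2")]), c("low", "high"))
})

test_that("selection optimism on pure-noise data is bounded", {
  vals <- vapply(1:30, function(r) {
    sim <- null_cohort(500, 500, 10, seed = 600 + r)
    mdr_cross_validate(sim$genotypes, status_of(sim),
                       colnames(sim$genotypes), 2, 10, seed = r)$testing_ba
  }, numeric(1))
  expect_gte(mean(vals), 0.5)
  expect_lte(mean(vals), 0.56)
})

test_that("missing genotypes drop subjects per combination only", {
  set.seed(50)
  n <- 120
  status <- rep(c(1L, 0L), each = n / 2)
  g <- cbind(a = rbinom(n, 2, 0.3), b = rbinom(n, 2, 0.3),
             c = rbinom(n, 2, 0.3))
  g[1:5, "a"] <- NA
  rownames(g) <- sprintf("s%03d", 1:n)
  prep <- snpepi:::mdr_prepare_combos(g, c("a", "b", "c"), 2)
  # pair (a,b) loses the 5 subjects; pair (b,c) keeps all
  expect_length(prep[[1]]$keep, n - 5)
  expect_length(prep[[3]]$keep, n)
})

test_that("permutation p is seeded, bounded, and large for weak models", {
  sim <- null_cohort(100, 100, 6, seed = 71)
  st <- status_of(sim)
  m1 <- mdr_permutation_test(sim$genotypes, st, colnames(sim$genotypes),
                             k_way = 2, cv_folds = 5, n_permutations = 60,
                             seed = 13)
  m2 <- mdr_permutation_test(sim$genotypes, st, colnames(sim$genotypes),
                             k_way = 2, cv_folds = 5, n_permutations = 60,
                             seed = 13)
  expect_identical(m1$permutation_p, m2$permutation_p)
  expect_gte(m1$permutation_p, 1 / 61)
  expect_lte(m1$permutation_p, 1)
  null_stats <- attr(m1, "null_testing_ba")
  if (m1$testing_ba < median(null_stats)) {
    expect_gt(m1$permutation_p, 0.5)
  }
})

test_that("label permutation centres testing BA at one half", {
  sim <- null_cohort(150, 150, 2, seed = 81)
  st <- status_of(sim)
  g <- sim$genotypes
  set.seed(5)
  vals <- replicate(220, {
    mdr_cross_validate(g, sample(st), colnames(g), k_way = 2, cv_folds = 5,
                       seed = 1)$testing_ba
  })
  # single candidate combination: no selection optimism, so the mean is 0.5
  expect_lt(abs(mean(vals) - 0.5), 0.02)
})

test_that("the MDR two-level variable has OR > 1 for high vs low by construction", {
  for (r in 1:5) {
    sim <- null_cohort(120, 150, 4, seed = 90 + r)
    st <- status_of(sim)
    m <- mdr_cross_validate(sim$genotypes, st, colnames(sim$genotypes), 2,
                            cv_folds = 5, seed = r)
    z <- unclass(sim$genotypes)[, m$snps]
    cell <- sprintf("%d/%d", z[, 1], z[, 2])
    pred <- m$cell_labels[cell] == "high"
    keep <- !is.na(pred)
    tab <- table(pred[keep], st[keep])
    if (all(dim(tab) == 2) && all(tab > 0)) {
      or <- (tab["TRUE", "1"] * tab["FALSE", "0"]) /
        (tab["TRUE", "0"] * tab["FALSE", "1"])
      expect_gt(or, 1)
    }
  }
})
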
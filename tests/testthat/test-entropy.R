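# independent entropy routines used as oracles
h_counts <- function(tab) {
  p <- tab[tab > 0] / sum(tab)
  -sum(p * log2(p))
}
h_of <- function(...) h_counts(table(...))

test_that("mutual information anchors: independence, determinism, plug-in formula", {
  # exact independence: counts form an outer product
  x <- rep(c(0, 1), times = c(40, 60))
  y <- c(rep(c(0, 1), times = c(16, 24)), rep(c(0, 1), times = c(24, 36)))
  expect_equal(mutual_information(x, y), 0)
  # perfectly dependent uniform binary -> 1 bit
  expect_equal(mutual_information(rep(0:1, 50), rep(0:1, 50)), 1)
  # plug-in formula oracle on the counts table [[30,10],[10,30]]
  x2 <- rep(c(0, 0, 1, 1), times = c(30, 10, 10, 30))
  y2 <- rep(c(0, 1, 0, 1), times = c(30, 10, 10, 30))
  pxy <- matrix(c(30, 10, 10, 30), 2) / 80
  oracle <- sum(pxy * log2(pxy / outer(rowSums(pxy), colSums(pxy))))
  expect_equal(mutual_information(x2, y2), oracle, tolerance = 1e-12)
  expect_error(mutual_information(1:3, 1:4), "length")
})

test_that("information gain is 1 bit for deterministic balanced XOR", {
  d <- deterministic_xor()
  expect_equal(mutual_information(d$a, d$status), 0)
  expect_equal(mutual_information(d$b, d$status), 0)
  expect_equal(information_gain(d$a, d$b, d$status), 1)
})

test_that("information gain equals the entropy-decomposition oracle", {
  set.seed(60)
  for (r in 1:100) {
    n <- sample(30:120, 1)
    a <- rbinom(n, 2, runif(1, 0.1, 0.5))
    b <- rbinom(n, 2, runif(1, 0.1, 0.5))
    cl <- rbinom(n, 1, 0.5)
    z <- paste(a, b)
    oracle <- (h_of(z) + h_of(cl) - h_of(z, cl)) -
      (h_of(a) + h_of(cl) - h_of(a, cl)) -
      (h_of(b) + h_of(cl) - h_of(b, cl))
    expect_equal(information_gain(a, b, cl), oracle, tolerance = 1e-10)
    expect_equal(information_gain(b, a, cl), information_gain(a, b, cl))
  }
})

test_that("mutual information respects its entropy bounds", {
  set.seed(61)
  for (r in 1:50) {
    n <- sample(20:100, 1)
    x <- sample(0:2, n, replace = TRUE)
    y <- rbinom(n, 1, 0.4)
    mi <- mutual_information(x, y)
    expect_gte(mi, 0)
    expect_lte(mi, min(h_of(x), h_of(y)) + 1e-12)
  }
})

test_that("the pairwise IG matrix is symmetric and consistent with single pairs", {
  sim <- null_cohort(80, 80, 5, seed = 55)
  st <- status_of(sim)
  m <- pairwise_ig_matrix(sim$genotypes, st)
  expect_true(isSymmetric(m))
  expect_true(all(is.na(diag(m))))
  expect_equal(m[1, 2],
               information_gain(sim$genotypes[, 1], sim$genotypes[, 2], st))
  # permuting SNP order permutes the matrix consistently
  perm <- c(3, 1, 5, 2, 4)
  m2 <- pairwise_ig_matrix(sim$genotypes[, perm], st)
  expect_equal(m2, m[perm, perm])
})

test_that("per-pair permutation p-values are seeded and near 1 for null pairs", {
  sim <- null_cohort(100, 100, 4, seed = 65)
  st <- status_of(sim)
  r1 <- permutation_null_ig(sim$genotypes, st, n_permutations = 80, seed = 4)
  r2 <- permutation_null_ig(sim$genotypes, st, n_permutations = 80, seed = 4)
  expect_identical(r1$p, r2$p)
  expect_true(all(r1$p >= 1 / 81, na.rm = TRUE))
  # a pair whose observed IG sits at the bottom of its null has p near 1
  low <- which(r1$observed == min(r1$observed, na.rm = TRUE), arr.ind = TRUE)[1, ]
  obs <- r1$observed[low[1], low[2]]
  nulls <- r1$null[, paste(sort(rownames(r1$observed)[low]), collapse = "|")]
  expect_equal(r1$p[low[1], low[2]],
               (1 + sum(nulls >= obs)) / 81, tolerance = 1e-12)
})

test_that("network assembly honours thresholds, degeneracy and monotonicity", {
  sim <- xor_cohort(400, 400, 8, effect_size = 3, seed = 66)
  st <- status_of(sim)
  perm <- permutation_null_ig(sim$genotypes, st, n_permutations = 150, seed = 2)
  mi <- vapply(seq_len(8), function(j) {
    mutual_information(sim$genotypes[, j], st)
  }, numeric(1))
  names(mi) <- colnames(sim$genotypes)

  # impossible IG threshold -> empty network (valid, not an error)
  cfg_hi <- analysis_config(ig_edge_threshold = 2, sen_permutation_alpha = 1)
  net0 <- build_network(perm$observed, mi, perm$p, cfg_hi)
  expect_identical(nrow(net0$edges), 0L)
  expect_equal(igraph::vcount(net0$graph), 0)

  # degenerate config (zero threshold, alpha 1) keeps every pair whose
  # plug-in IG is positive, which is every pair on finite continuous-ish data
  cfg_all <- analysis_config(ig_edge_threshold = 0, sen_permutation_alpha = 1)
  netc <- build_network(perm$observed, mi, perm$p, cfg_all)
  ut <- upper.tri(perm$observed)
  expect_identical(nrow(netc$edges),
                   sum(perm$observed[ut] > 0 & perm$p[ut] < 1))
  expect_gte(nrow(netc$edges), choose(8, 2) - 2)

  # raising the IG threshold never adds an edge
  cfg_a <- analysis_config(ig_edge_threshold = 0.005, sen_permutation_alpha = 0.5)
  cfg_b <- analysis_config(ig_edge_threshold = 0.02, sen_permutation_alpha = 0.5)
  ea <- build_network(perm$observed, mi, perm$p, cfg_a)$edges
  eb <- build_network(perm$observed, mi, perm$p, cfg_b)$edges
  key <- function(e) paste(e$snp_a, e$snp_b)
  expect_true(all(key(eb) %in% key(ea)))

  # every retained edge satisfies both criteria
  cfg <- analysis_config(ig_edge_threshold = 0.011, sen_permutation_alpha = 0.05)
  net <- build_network(perm$observed, mi, perm$p, cfg)
  if (nrow(net$edges)) {
    expect_true(all(net$edges$ig > cfg$ig_edge_threshold))
    expect_true(all(net$edges$perm_p < cfg$sen_permutation_alpha))
    expect_setequal(igraph::V(net$graph)$name,
                    unique(c(net$edges$snp_a, net$edges$snp_b)))
  }
})

test_that("the end-to-end network run exports valid GraphML", {
  sim <- xor_cohort(300, 300, 6, effect_size = 4, seed = 67)
  cfg <- analysis_config(n_permutations = 120, sen_permutation_alpha = 0.05,
                         rng_seed = 3)
  net <- sen_analysis(sim$genotypes, sim$subjects, cfg)
  expect_s3_class(net, "epistasis_network")
  expect_named(net$mi, colnames(sim$genotypes))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_identical(igraph::vcount(g), igraph::vcount(net$graph))
})
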
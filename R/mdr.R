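#' Label multilocus genotype cells high or low risk
#'
#' The MDR constructive-induction step: each joint-genotype cell is labeled
#' high-risk when its case:control ratio reaches the training-set threshold
#' `T` (the overall training case:control ratio), regardless of cell
#' frequency. Cells with cases but no controls are high; cells with no
#' training subjects are low, so unseen test genotypes default to low risk;
#' a cell exactly at the threshold is high.
#'
#' @param cell_cases,cell_controls Integer vectors of per-cell case and
#'   control counts (parallel over cells).
#' @param T Threshold ratio (training cases / training controls), > 0.
#' @return Logical vector: `TRUE` = high risk.
#' @export
mdr_classify_cells <- function(cell_cases, cell_controls, T) {
  stopifnot(length(cell_cases) == length(cell_controls), T > 0)
  cell_cases >= T * cell_controls & (cell_cases + cell_controls) > 0
}

#' Balanced accuracy of a high/low risk prediction
#'
#' @param predicted_high Logical vector; `TRUE` predicts case.
#' @param status Binary 0/1 vector.
#' @return `(sensitivity + specificity) / 2`; 0.5 is chance level for any
#'   constant prediction, robust to case:control imbalance.
#' @export
balanced_accuracy <- function(predicted_high, status) {
  if (length(predicted_high) != length(status)) stop("length mismatch")
  if (!all(c(0, 1) %in% status)) stop("both classes must be present in status")
  sens <- mean(predicted_high[status == 1])
  spec <- mean(!predicted_high[status == 0])
  (sens + spec) / 2
}

# Stratified fold assignment preserving the case:control ratio.
stratified_folds <- function(status, cv_folds) {
  if (min(sum(status == 1), sum(status == 0)) < cv_folds) {
    stop("too few subjects in a class for ", cv_folds, "-fold stratified CV")
  }
  folds <- integer(length(status))
  for (s in c(0L, 1L)) {
    idx <- sample(which(status == s))
    folds[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }
  folds
}

# Precompute, for each k-way SNP combination, the complete-case subject
# index and the joint genotype cell code (0-based).
mdr_prepare_combos <- function(genotypes, candidate_snps, k_way) {
  X <- unclass(genotypes)[, candidate_snps, drop = FALSE]
  combos <- utils::combn(length(candidate_snps), k_way)
  n_combo <- ncol(combos)
  if (n_combo > 1e6) stop("more than 1e6 SNP combinations; reduce the candidate set")
  prep <- vector("list", n_combo)
  for (c_i in seq_len(n_combo)) {
    cols <- combos[, c_i]
    sub <- X[, cols, drop = FALSE]
    keep <- which(rowSums(is.na(sub)) == 0L)
    z <- as.integer(sub[keep, 1])
    if (k_way > 1) {
      for (j in 2:k_way) z <- z * 3L + as.integer(sub[keep, j])
    }
    prep[[c_i]] <- list(snps = candidate_snps[cols], keep = keep, z = z,
                        ncell = 3L^k_way)
  }
  prep
}

# Per-fold training and testing balanced accuracy of one combination.
# Counts are aggregated once as a (class x fold x cell) table; training
# counts for fold f are totals minus fold-f counts, so each combination
# costs one pass over its subjects regardless of the number of folds.
mdr_eval_combo <- function(prep, status, folds, cv_folds) {
  s <- status[prep$keep]
  f <- folds[prep$keep]
  ncell <- prep$ncell
  idx <- (1L + s) + 2L * ((f - 1L) + cv_folds * prep$z)
  a <- array(tabulate(idx, nbins = 2L * cv_folds * ncell),
             dim = c(2L, cv_folds, ncell))
  A_ctrl <- matrix(a[1L, , ], cv_folds, ncell)
  A_case <- matrix(a[2L, , ], cv_folds, ncell)
  tot_case <- colSums(A_case)
  tot_ctrl <- colSums(A_ctrl)
  tr_case <- matrix(tot_case, cv_folds, ncell, byrow = TRUE) - A_case
  tr_ctrl <- matrix(tot_ctrl, cv_folds, ncell, byrow = TRUE) - A_ctrl
  tr_case_tot <- rowSums(tr_case)
  tr_ctrl_tot <- rowSums(tr_ctrl)
  Tf <- tr_case_tot / tr_ctrl_tot
  high <- tr_case >= Tf * tr_ctrl & (tr_case + tr_ctrl) > 0
  train_ba <- (rowSums(tr_case * high) / tr_case_tot +
                 rowSums(tr_ctrl * !high) / tr_ctrl_tot) / 2
  te_case_tot <- rowSums(A_case)
  te_ctrl_tot <- rowSums(A_ctrl)
  test_ba <- (rowSums(A_case * high) / ifelse(te_case_tot > 0, te_case_tot, NA) +
                rowSums(A_ctrl * !high) / ifelse(te_ctrl_tot > 0, te_ctrl_tot, NA)) / 2
  list(train_ba = train_ba, test_ba = test_ba)
}

# One full cross-validated exhaustive search; returns selection summaries.
mdr_search <- function(prep, status, folds, cv_folds) {
  n_combo <- length(prep)
  train_ba <- matrix(NA_real_, n_combo, cv_folds)
  test_ba <- matrix(NA_real_, n_combo, cv_folds)
  for (i in seq_len(n_combo)) {
    ev <- mdr_eval_combo(prep[[i]], status, folds, cv_folds)
    train_ba[i, ] <- ev$train_ba
    test_ba[i, ] <- ev$test_ba
  }
  # per-fold winner by training BA; ties resolved to the lexicographically
  # first combination (combn enumerates combinations in lexicographic order)
  fold_best <- apply(train_ba, 2, which.max)
  cvc <- tabulate(fold_best, nbins = n_combo)
  mean_test <- rowMeans(test_ba, na.rm = TRUE)
  best <- order(-cvc, -mean_test, seq_len(n_combo))[1]
  list(best = best, cvc = cvc, mean_test = mean_test,
       train_ba = train_ba, test_ba = test_ba, fold_best = fold_best)
}

#' Exhaustive cross-validated MDR search
#'
#' Enumerates every `k_way` combination of the candidate SNPs. Within each
#' stratified fold, every combination is trained on the remaining folds
#' (cells labeled by [mdr_classify_cells()] at the training case:control
#' ratio) and the per-fold winner is the combination with the highest
#' training balanced accuracy. A combination's cross-validation consistency
#' (CVC) is the number of folds it wins; the reported model maximises CVC,
#' with ties broken by mean testing balanced accuracy and then lexicographic
#' SNP order. Subjects missing a genotype in a combination are excluded for
#' that combination only.
#'
#' @param genotypes Matrix of dose codes (`NA` = missing).
#' @param status Binary 0/1 vector aligned with `genotypes` rows.
#' @param candidate_snps Character vector of SNP ids to search over.
#' @param k_way Interaction order(s); a vector returns the best model per
#'   order plus the overall best.
#' @param cv_folds Number of stratified folds.
#' @param seed Integer seed controlling fold assignment.
#' @return For scalar `k_way`, an object of class `"mdr_model"`: list with
#'   `snps`, `k_way`, `cell_labels` (full-data high/low per joint genotype),
#'   `threshold`, `training_ba` (full-data), `testing_ba` (mean over folds),
#'   `fold_test_ba`, `cvc`, `cv_folds`, `seed`. For vector `k_way`, a list
#'   with one model per order and `best_overall`.
#' @export
mdr_cross_validate <- function(genotypes, status, candidate_snps,
                               k_way = 2L, cv_folds = 10L, seed = 1L) {
  if (length(k_way) > 1) {
    models <- lapply(k_way, function(k) {
      mdr_cross_validate(genotypes, status, candidate_snps, k, cv_folds, seed)
    })
    names(models) <- paste0("k", k_way)
    pick <- order(-vapply(models, `[[`, 0L, "cvc"),
                  -vapply(models, `[[`, 0, "testing_ba"))[1]
    return(list(per_k = models, best_overall = models[[pick]]))
  }
  stopifnot(cv_folds >= 2, k_way >= 1)
  prep <- mdr_prepare_combos(genotypes, candidate_snps, k_way)
  folds <- with_seed(seed, stratified_folds(status, cv_folds))
  sr <- mdr_search(prep, status, folds, cv_folds)
  best_prep <- prep[[sr$best]]

  s <- status[best_prep$keep]
  cnt_case <- tabulate(best_prep$z[s == 1] + 1L, nbins = best_prep$ncell)
  cnt_ctrl <- tabulate(best_prep$z[s == 0] + 1L, nbins = best_prep$ncell)
  threshold <- sum(s == 1) / sum(s == 0)
  labels <- mdr_classify_cells(cnt_case, cnt_ctrl, threshold)
  # cell code packs doses most-significant-first: code = ((d1*3)+d2)*3+...
  cell_codes <- seq_len(best_prep$ncell) - 1L
  names(labels) <- vapply(cell_codes, function(cc) {
    paste(vapply(seq_len(k_way),
                 function(j) (cc %/% 3^(k_way - j)) %% 3, numeric(1)),
          collapse = "/")
  }, character(1))
  pred_full <- labels[best_prep$z + 1L]
  model <- list(
    snps = best_prep$snps, k_way = as.integer(k_way),
    cell_labels = ifelse(labels, "high", "low"),
    threshold = threshold,
    training_ba = balanced_accuracy(pred_full, s),
    testing_ba = sr$mean_test[sr$best],
    fold_test_ba = sr$test_ba[sr$best, ],
    cvc = sr$cvc[sr$best],
    cv_folds = as.integer(cv_folds),
    seed = as.integer(seed),
    permutation_p = NA_real_)
  class(model) <- "mdr_model"
  model
}

#' @export
print.mdr_model <- function(x, ...) {
  cat(sprintf("MDR %d-way model: %s\n", x$k_way, paste(x$snps, collapse = " x ")))
  cat(sprintf("  training BA %.4f | testing BA %.4f | CVC %d/%d\n",
              x$training_ba, x$testing_ba, x$cvc, x$cv_folds))
  if (!is.na(x$permutation_p)) {
    cat(sprintf("  permutation p = %.4g\n", x$permutation_p))
  }
  invisible(x)
}

#' Permutation test for the MDR search
#'
#' Re-runs the entire cross-validated exhaustive search on
#' `n_permutations` label-permuted datasets and compares the observed
#' selected model's mean testing balanced accuracy against the null
#' distribution of the same statistic (the permuted searches apply the
#' identical selection rule, so model-selection optimism is part of the
#' null). The add-one estimator
#' `p = (1 + #[null >= observed]) / (1 + n_permutations)` is used.
#'
#' @inheritParams mdr_cross_validate
#' @param n_permutations Number of label permutations (>= 100 recommended).
#' @return The observed `"mdr_model"` with `permutation_p` filled in and
#'   attribute `null_testing_ba` (the null sample).
#' @export
mdr_permutation_test <- function(genotypes, status, candidate_snps,
                                 k_way = 2L, cv_folds = 10L,
                                 n_permutations = 1000L, seed = 1L) {
  prep <- mdr_prepare_combos(genotypes, candidate_snps, k_way)
  with_seed(seed, {
    folds <- stratified_folds(status, cv_folds)
    sr <- mdr_search(prep, status, folds, cv_folds)
    observed_stat <- sr$mean_test[sr$best]
    null_stats <- vapply(seq_len(n_permutations), function(p_i) {
      perm <- sample(status)
      pf <- stratified_folds(perm, cv_folds)
      ps <- mdr_search(prep, perm, pf, cv_folds)
      ps$mean_test[ps$best]
    }, numeric(1))
    pval <- (1 + sum(null_stats >= observed_stat)) / (1 + n_permutations)
    model <- mdr_cross_validate(genotypes, status, candidate_snps, k_way,
                                cv_folds, seed = seed)
    model$permutation_p <- pval
    attr(model, "null_testing_ba") <- null_stats
    model
  })
}
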
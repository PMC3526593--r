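#' ReliefF relevance weights for SNPs
#'
#' Instance-based feature weighting tuned to detect epistatic (non-additive)
#' signal: for every subject, the k nearest subjects of the same class
#' (hits) and of the other class (misses) are located under the
#' genotype-mismatch distance (per-SNP distance `|dose_i - dose_j| / 2`,
#' summed over SNPs), and each SNP's weight is decreased by its mean
#' hit-difference and increased by its mean miss-difference. Weights are
#' accumulated over all subjects (or a sampled subset) and normalised, so a
#' SNP whose genotype separates the classes locally -- even with no marginal
#' effect -- accumulates positive weight. Only the ordering of the weights
#' is a downstream contract.
#'
#' @param genotypes Matrix of dose codes without missing values (apply
#'   complete-case filtering or imputation upstream).
#' @param status Binary 0/1 vector.
#' @param k_neighbors Number of nearest hits and misses (default 10).
#' @param sample_size Optional number of subjects to score (default all);
#'   sampled without replacement under the seed.
#' @param seed Integer seed (used for subject sampling).
#' @return Named numeric vector of per-SNP weights.
#' @export
relieff_weights <- function(genotypes, status, k_neighbors = 10L,
                            sample_size = NULL, seed = 1L) {
  X <- unclass(genotypes)
  if (anyNA(X)) stop("missing genotypes are not allowed in relieff_weights")
  if (length(status) != nrow(X)) stop("status length must match subjects")
  k <- as.integer(k_neighbors)
  if (k < 1L) stop("k_neighbors must be >= 1")
  cls <- table(factor(status, levels = c(0, 1)))
  if (any(cls < k + 1L)) {
    stop(sprintf("each class needs more than k_neighbors = %d members (have %d/%d)",
                 k, cls[1], cls[2]))
  }
  n <- nrow(X)
  targets <- with_seed(seed, {
    if (is.null(sample_size) || sample_size >= n) seq_len(n)
    else sort(sample.int(n, sample_size))
  })
  D <- as.matrix(stats::dist(X, method = "manhattan")) / 2
  W <- numeric(ncol(X))
  for (i in targets) {
    d <- D[i, ]
    same <- status == status[i]
    same[i] <- FALSE
    hit_idx <- which(same)[order(d[same], which(same))[seq_len(k)]]
    miss_idx <- which(!same)[order(d[!same], which(!same))[seq_len(k)]]
    xi <- X[i, ]
    hit_diff <- colMeans(abs(X[hit_idx, , drop = FALSE] -
                               rep(xi, each = k))) / 2
    miss_diff <- colMeans(abs(X[miss_idx, , drop = FALSE] -
                                rep(xi, each = k))) / 2
    W <- W - hit_diff + miss_diff
  }
  W <- W / length(targets)
  names(W) <- colnames(X)
  W
}

#' TuRF: iterative ReliefF filtering
#'
#' Tuned ReliefF: repeatedly recompute ReliefF weights and discard the
#' lowest-weighted `drop_fraction` of the remaining SNPs until
#' `target_count` survive. Removing noise SNPs sharpens the neighbourhoods
#' the next ReliefF pass sees, which protects weak interacting SNPs from
#' being swamped.
#'
#' @inheritParams relieff_weights
#' @param drop_fraction Fraction of remaining SNPs removed per iteration
#'   (0 < f < 1).
#' @param target_count Number of SNPs to retain.
#' @return Character vector of retained SNP ids ranked by final ReliefF
#'   weight (best first), with attributes `weights` (final weights) and
#'   `removal_order` (SNPs in the order they were dropped).
#' @export
turf_select <- function(genotypes, status, drop_fraction = 0.1,
                        target_count, k_neighbors = 10L, seed = 1L) {
  stopifnot(drop_fraction > 0, drop_fraction < 1)
  snps <- colnames(genotypes)
  if (is.null(snps)) snps <- as.character(seq_len(ncol(genotypes)))
  if (target_count >= length(snps)) {
    warning("target_count >= number of SNPs; returning all SNPs ranked by ReliefF")
    w <- relieff_weights(genotypes, status, k_neighbors, seed = seed)
    out <- snps[order(-w)]
    attr(out, "weights") <- w[order(-w)]
    attr(out, "removal_order") <- character(0)
    return(out)
  }
  current <- snps
  removed <- character(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- relieff_weights(genotypes[, current, drop = FALSE], status,
                         k_neighbors, seed = seed + iter)
    if (length(current) <= target_count) break
    n_drop <- min(max(1L, floor(drop_fraction * length(current))),
                  length(current) - target_count)
    # stable ordering: ties broken by current position
    drop <- current[order(w, seq_along(w))[seq_len(n_drop)]]
    removed <- c(removed, drop)
    current <- setdiff(current, drop)
  }
  out <- current[order(-w)]
  attr(out, "weights") <- w[order(-w)]
  attr(out, "removal_order") <- removed
  out
}
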
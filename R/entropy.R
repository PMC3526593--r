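# Plug-in mutual information (bits) from a joint count table.
mi_from_counts <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  pp <- outer(px, py)
  nz <- pxy > 0
  sum(pxy[nz] * log2(pxy[nz] / pp[nz]))
}

#' Plug-in mutual information between two discrete variables
#'
#' Maximum-likelihood (plug-in) estimate
#' `I(X;Y) = sum p(x,y) log2 [ p(x,y) / (p(x) p(y)) ]` in bits; zero-count
#' cells contribute nothing. Pairs with a missing value in either variable
#' are dropped.
#'
#' @param x,y Discrete vectors of equal length.
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  keep <- !is.na(x) & !is.na(y)
  mi_from_counts(table(x[keep], y[keep]))
}

#' Pairwise information gain of two SNPs about the phenotype
#'
#' `IG(A;B;C) = I(A,B;C) - I(A;C) - I(B;C)`, where the joint variable (A,B)
#' is the 9-level joint genotype and C the class. Positive values indicate
#' synergy: the pair carries information about the phenotype beyond its
#' marginal effects. All terms are plug-in estimates in bits, computed on
#' the pair's complete cases.
#'
#' @param snp_a,snp_b Dose vectors (0/1/2, `NA` = missing).
#' @param status Binary class vector.
#' @return Information gain in bits.
#' @export
information_gain <- function(snp_a, snp_b, status) {
  if (length(snp_a) != length(snp_b) || length(snp_a) != length(status)) {
    stop("snp_a, snp_b and status must have the same length")
  }
  keep <- !is.na(snp_a) & !is.na(snp_b) & !is.na(status)
  a <- as.integer(snp_a[keep])
  b <- as.integer(snp_b[keep])
  cl <- as.integer(status[keep])
  z <- 3L * a + b
  ig_terms(a, b, z, cl)
}

# shared fast path: all inputs complete, a/b in 0..2, z = 3a+b, cl in 0/1
ig_terms <- function(a, b, z, cl) {
  mi_z <- mi_from_counts(counts2(z, 9L, cl))
  mi_a <- mi_from_counts(counts2(a, 3L, cl))
  mi_b <- mi_from_counts(counts2(b, 3L, cl))
  mi_z - mi_a - mi_b
}

counts2 <- function(codes, ncodes, cl) {
  matrix(tabulate(1L + codes + ncodes * cl, nbins = 2L * ncodes),
         nrow = ncodes)
}

#' Pairwise information-gain matrix
#'
#' @param genotypes Matrix of dose codes.
#' @param status Binary class vector.
#' @return Symmetric matrix of IG values (bits) over all unordered SNP
#'   pairs; diagonal `NA`. Complete cases are taken per pair.
#' @export
pairwise_ig_matrix <- function(genotypes, status) {
  X <- unclass(genotypes)
  m <- ncol(X)
  if (m < 2) stop("need at least two SNPs")
  out <- matrix(NA_real_, m, m, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      out[i, j] <- out[j, i] <- information_gain(X[, i], X[, j], status)
    }
  }
  out
}

#' Permutation null for pairwise information gain
#'
#' Permutes the class labels `n_permutations` times, recomputing the full
#' pairwise IG matrix each time, and assigns each pair a p-value against its
#' own null distribution with the add-one estimator
#' `p = (1 + #[null >= observed]) / (1 + n_permutations)`.
#'
#' @inheritParams pairwise_ig_matrix
#' @param n_permutations Number of permutations.
#' @param seed Integer seed.
#' @return List with `observed` (IG matrix), `p` (matrix of per-pair
#'   permutation p-values), and `null` (n_permutations x n_pairs matrix of
#'   null IG values, pairs named `"a|b"`).
#' @export
permutation_null_ig <- function(genotypes, status, n_permutations = 1000L,
                                seed = 1L) {
  X <- unclass(genotypes)
  m <- ncol(X)
  pairs <- utils::combn(m, 2)
  n_pair <- ncol(pairs)
  # precompute per-pair complete-case indices and joint codes
  prep <- lapply(seq_len(n_pair), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    keep <- which(!is.na(X[, i]) & !is.na(X[, j]) & !is.na(status))
    a <- as.integer(X[keep, i]); b <- as.integer(X[keep, j])
    list(keep = keep, a = a, b = b, z = 3L * a + b)
  })
  observed_vec <- vapply(prep, function(pr) {
    ig_terms(pr$a, pr$b, pr$z, as.integer(status[pr$keep]))
  }, numeric(1))
  null_mat <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p_i) {
      perm <- sample(status)
      vapply(prep, function(pr) {
        ig_terms(pr$a, pr$b, pr$z, as.integer(perm[pr$keep]))
      }, numeric(1))
    }, numeric(n_pair))
  })
  null_mat <- matrix(null_mat, nrow = n_pair)
  pvals <- (1 + rowSums(null_mat >= observed_vec)) / (1 + n_permutations)
  snp_ids <- colnames(X)
  if (is.null(snp_ids)) snp_ids <- as.character(seq_len(m))
  pair_names <- paste(snp_ids[pairs[1, ]], snp_ids[pairs[2, ]], sep = "|")
  observed <- matrix(NA_real_, m, m, dimnames = list(snp_ids, snp_ids))
  pmat <- observed
  for (k in seq_len(n_pair)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    observed[i, j] <- observed[j, i] <- observed_vec[k]
    pmat[i, j] <- pmat[j, i] <- pvals[k]
  }
  null_t <- t(null_mat)
  colnames(null_t) <- pair_names
  list(observed = observed, p = pmat, null = null_t)
}

#' Assemble a statistical epistasis network
#'
#' Builds the SNP interaction graph: edges are SNP pairs whose pairwise
#' information gain exceeds `config$ig_edge_threshold` (bits) AND whose
#' permutation p-value is below `config$sen_permutation_alpha`; vertices are
#' the endpoint SNPs, weighted by their mutual information with the
#' phenotype (vertex attribute `mi`, edge attributes `ig` and `perm_p`).
#' An empty network (no surviving edge) is a valid result, not an error.
#'
#' @param ig_matrix Symmetric pairwise IG matrix.
#' @param mi_vector Named per-SNP mutual information with the phenotype.
#' @param per_pair_p Symmetric matrix of per-pair permutation p-values.
#' @param config An [analysis_config()].
#' @return List of class `"epistasis_network"`: `graph` (igraph object),
#'   `edges` (ranked data frame: snp_a, snp_b, ig, perm_p), `thresholds`,
#'   `seed`.
#' @export
build_network <- function(ig_matrix, mi_vector, per_pair_p,
                          config = analysis_config()) {
  stopifnot(nrow(ig_matrix) == ncol(ig_matrix),
            all(dim(per_pair_p) == dim(ig_matrix)))
  snp_ids <- rownames(ig_matrix)
  if (is.null(snp_ids)) snp_ids <- as.character(seq_len(nrow(ig_matrix)))
  ut <- upper.tri(ig_matrix)
  idx <- which(ut & ig_matrix > config$ig_edge_threshold &
                 per_pair_p < config$sen_permutation_alpha,
               arr.ind = TRUE)
  edges <- data.frame(
    snp_a = snp_ids[idx[, 1]], snp_b = snp_ids[idx[, 2]],
    ig = ig_matrix[idx], perm_p = per_pair_p[idx],
    stringsAsFactors = FALSE)
  edges <- edges[order(-edges$ig), , drop = FALSE]
  rownames(edges) <- NULL
  vertices <- unique(c(edges$snp_a, edges$snp_b))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = if (length(vertices)) {
      data.frame(name = vertices,
                 mi = as.numeric(mi_vector[vertices]),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(name = character(0), mi = numeric(0))
    })
  g <- igraph::set_graph_attr(g, "ig_edge_threshold", config$ig_edge_threshold)
  g <- igraph::set_graph_attr(g, "mi_vertex_threshold", config$mi_vertex_threshold)
  g <- igraph::set_graph_attr(g, "permutation_alpha", config$sen_permutation_alpha)
  g <- igraph::set_graph_attr(g, "rng_seed", config$rng_seed)
  out <- list(graph = g, edges = edges,
              thresholds = list(ig_edge = config$ig_edge_threshold,
                                mi_vertex = config$mi_vertex_threshold,
                                permutation_alpha = config$sen_permutation_alpha),
              seed = config$rng_seed)
  class(out) <- "epistasis_network"
  out
}

#' @export
print.epistasis_network <- function(x, ...) {
  cat(sprintf("epistasis network: %d vertices, %d edges (IG > %g bits, perm p < %g)\n",
              igraph::vcount(x$graph), nrow(x$edges),
              x$thresholds$ig_edge, x$thresholds$permutation_alpha))
  if (nrow(x$edges)) print(utils::head(x$edges, 10))
  invisible(x)
}

#' End-to-end statistical epistasis network analysis
#'
#' Computes per-SNP mutual information with case-control status, the
#' pairwise IG matrix, per-pair permutation p-values, and assembles the
#' thresholded network.
#'
#' @param genotypes A [genotype_matrix()] (or dose matrix).
#' @param subjects A [subject_table()] aligned with `genotypes` rows.
#' @param config An [analysis_config()]; `n_permutations`,
#'   `ig_edge_threshold`, `sen_permutation_alpha` and `rng_seed` are used.
#' @param snp_ids Optional subset of SNPs to analyse.
#' @return An `"epistasis_network"` with the extra elements `mi` (per-SNP
#'   MI vector) and `permutation` (the [permutation_null_ig()] result).
#' @export
sen_analysis <- function(genotypes, subjects, config = analysis_config(),
                         snp_ids = NULL) {
  subjects <- subjects[match(rownames(genotypes), subjects$subject_id), ]
  X <- if (is.null(snp_ids)) genotypes else genotypes[, snp_ids, drop = FALSE]
  status <- subjects$status
  mi <- vapply(seq_len(ncol(X)), function(j) {
    mutual_information(X[, j], status)
  }, numeric(1))
  names(mi) <- colnames(X)
  perm <- permutation_null_ig(X, status, config$n_permutations,
                              seed = config$rng_seed)
  net <- build_network(perm$observed, mi, perm$p, config)
  net$mi <- mi
  net$permutation <- perm
  net
}

#' Export a network as GraphML
#'
#' @param network An `"epistasis_network"`.
#' @param path Output file path.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' Export the ranked edge list as TSV
#'
#' @param network An `"epistasis_network"`.
#' @param path Output file path.
#' @param header_comments Optional `#`-prefixed provenance lines.
#' @export
write_network_edges_tsv <- function(network, path, header_comments = NULL) {
  write_table_tsv(network$edges, path, header_comments)
}
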
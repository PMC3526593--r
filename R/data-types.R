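#' Functional groups used to organise candidate SNPs
#'
#' The nine carcinogenesis-process groups used to partition candidate SNPs
#' for within-group analysis and FDR control.
#'
#' @return Character vector of the nine group labels.
#' @export
functional_groups <- function() {
  c("apoptosis", "dna_repair", "immune", "hormone", "metabolism",
    "neural", "proliferation", "telomere", "transport_signaling")
}

AGE_LEVELS <- c("25-34", "35-44", "45-54", "55-64", "65-69", "70-74")
GENDER_LEVELS <- c("female", "male")
SMOKING_LEVELS <- c("never", "former", "current")
STAGE_LEVELS <- c("non-invasive", "invasive", "tis", "not-applicable")

#' Construct a validated genotype matrix
#'
#' A genotype matrix stores minor-allele dose codes for each subject (rows)
#' and SNP (columns): 0 = wildtype homozygote, 1 = heterozygote,
#' 2 = variant homozygote, `NA` = missing call. The dose-coding convention is
#' enforced here, at the ingest boundary, and assumed by every downstream
#' module.
#'
#' @param doses Numeric or integer matrix of dose codes.
#' @param subject_ids Optional character vector of subject identifiers
#'   (defaults to `rownames(doses)`).
#' @param snp_ids Optional character vector of SNP identifiers (defaults to
#'   `colnames(doses)`).
#' @return An integer matrix of class `"genotype_matrix"` with unique
#'   dimnames.
#' @export
genotype_matrix <- function(doses, subject_ids = rownames(doses),
                            snp_ids = colnames(doses)) {
  if (!is.matrix(doses)) stop("'doses' must be a matrix")
  if (is.null(subject_ids) || is.null(snp_ids)) {
    stop("subject and SNP identifiers are required (dimnames or arguments)")
  }
  subject_ids <- as.character(subject_ids)
  snp_ids <- as.character(snp_ids)
  if (length(subject_ids) != nrow(doses)) {
    stop("length of subject_ids does not match nrow(doses)")
  }
  if (length(snp_ids) != ncol(doses)) {
    stop("length of snp_ids does not match ncol(doses)")
  }
  if (anyDuplicated(subject_ids)) {
    stop("duplicate subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  }
  if (anyDuplicated(snp_ids)) {
    stop("duplicate SNP ids: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  }
  bad <- !is.na(doses) & !(doses %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "invalid dose '%s' at subject '%s', SNP '%s' (must be 0, 1, 2 or missing)",
      format(doses[idx[1], idx[2]]), subject_ids[idx[1]], snp_ids[idx[2]]))
  }
  storage.mode(doses) <- "integer"
  dimnames(doses) <- list(subject_ids, snp_ids)
  class(doses) <- c("genotype_matrix", class(matrix()))
  doses
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Construct a validated subject table
#'
#' @param df Data frame with columns `subject_id`, `status` (1 = case,
#'   0 = control) and optionally `age_group`, `gender`, `smoking`, `stage`.
#'   Factor levels follow the study design: six age strata
#'   (25-34 ... 70-74), gender female/male, smoking never/former/current,
#'   stage non-invasive/invasive/tis/not-applicable. Smoking may be missing
#'   for a small fraction of subjects; stage must be `"not-applicable"` for
#'   all controls.
#' @return The validated data frame with class `"subject_table"`.
#' @export
subject_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("subject_id", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) stop("duplicate subject ids in subject table")
  if (anyNA(df$status)) stop("'status' must never be missing")
  if (!all(df$status %in% c(0L, 1L))) stop("'status' must be 0 (control) or 1 (case)")
  df$status <- as.integer(df$status)
  if (!is.null(df$age_group)) df$age_group <- factor(df$age_group, levels = AGE_LEVELS)
  if (!is.null(df$gender)) df$gender <- factor(df$gender, levels = GENDER_LEVELS)
  if (!is.null(df$smoking)) df$smoking <- factor(df$smoking, levels = SMOKING_LEVELS)
  if (!is.null(df$stage)) {
    df$stage <- factor(df$stage, levels = STAGE_LEVELS)
    ctrl_stage <- df$stage[df$status == 0L]
    if (any(is.na(ctrl_stage)) || any(ctrl_stage != "not-applicable")) {
      stop("stage must be 'not-applicable' for all controls")
    }
  }
  class(df) <- c("subject_table", "data.frame")
  df
}

#' Construct a validated SNP annotation table
#'
#' @param df Data frame with columns `snp_id`, `functional_group` and
#'   optionally `rsid`, `gene`. Functional group must be one of
#'   [functional_groups()].
#' @return The validated data frame with class `"snp_annotation"`.
#' @export
snp_annotation <- function(df) {
  stopifnot(is.data.frame(df))
  miss <- setdiff(c("snp_id", "functional_group"), names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  df$snp_id <- as.character(df$snp_id)
  if (anyDuplicated(df$snp_id)) stop("duplicate snp ids in annotation")
  bad <- !df$functional_group %in% functional_groups()
  if (any(bad)) {
    stop("unknown functional group(s): ",
         paste(unique(df$functional_group[bad]), collapse = ", "))
  }
  df$functional_group <- factor(as.character(df$functional_group),
                                levels = functional_groups())
  if (is.null(df$rsid)) df$rsid <- NA_character_
  if (is.null(df$gene)) df$gene <- NA_character_
  class(df) <- c("snp_annotation", "data.frame")
  df
}

#' Analysis configuration
#'
#' Collects the thresholds and tuning parameters used across the pipeline.
#' Defaults reflect the study design this package emulates: markers are
#' excluded below 5% minor allele frequency or 95% call rate; associations
#' are reported at FDR-adjusted p < 0.25 within functional group with
#' pointwise significance declared at p < 0.001; unstable estimates are
#' suppressed unless at least 20 cases and 20 controls carry the non-referent
#' genotype; MDR uses 10-fold cross-validation and 1000 permutations; network
#' edges require information gain > 0.011 bits and permutation p < 0.001,
#' with vertices weighted by mutual information (reported against a 0.01-bit
#' reference threshold).
#'
#' @param maf_threshold Minimum minor allele frequency.
#' @param call_rate_threshold Minimum per-SNP call rate.
#' @param fdr_report_threshold FDR-adjusted p-value reporting cutoff.
#' @param pointwise_significance Pointwise significance level.
#' @param min_cell_size Minimum cases and controls in the non-referent
#'   genotype group for a stable estimate.
#' @param cv_folds Number of MDR cross-validation folds.
#' @param n_permutations Number of permutations for MDR / network testing.
#' @param ig_edge_threshold Information-gain threshold (bits) for network
#'   edges.
#' @param mi_vertex_threshold Mutual-information reference threshold (bits)
#'   for network vertices.
#' @param sen_permutation_alpha Permutation significance level for network
#'   edges.
#' @param rng_seed Integer seed recorded in every output.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(maf_threshold = 0.05,
                            call_rate_threshold = 0.95,
                            fdr_report_threshold = 0.25,
                            pointwise_significance = 0.001,
                            min_cell_size = 20L,
                            cv_folds = 10L,
                            n_permutations = 1000L,
                            ig_edge_threshold = 0.011,
                            mi_vertex_threshold = 0.01,
                            sen_permutation_alpha = 0.001,
                            rng_seed = 1L) {
  cfg <- list(
    maf_threshold = maf_threshold,
    call_rate_threshold = call_rate_threshold,
    fdr_report_threshold = fdr_report_threshold,
    pointwise_significance = pointwise_significance,
    min_cell_size = as.integer(min_cell_size),
    cv_folds = as.integer(cv_folds),
    n_permutations = as.integer(n_permutations),
    ig_edge_threshold = ig_edge_threshold,
    mi_vertex_threshold = mi_vertex_threshold,
    sen_permutation_alpha = sen_permutation_alpha,
    rng_seed = as.integer(rng_seed)
  )
  with(cfg, {
    stopifnot(maf_threshold >= 0, maf_threshold <= 0.5,
              call_rate_threshold >= 0, call_rate_threshold <= 1,
              fdr_report_threshold > 0, fdr_report_threshold <= 1,
              pointwise_significance > 0, pointwise_significance <= 1,
              min_cell_size >= 0, cv_folds >= 2, n_permutations >= 1,
              ig_edge_threshold >= 0, mi_vertex_threshold >= 0,
              sen_permutation_alpha > 0, sen_permutation_alpha <= 1)
  })
  class(cfg) <- "analysis_config"
  cfg
}

# Run code with a private, seeded RNG stream; the caller's RNG state is
# restored on exit so library code never perturbs user randomness.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Round half away from zero (spreadsheet-style), used when comparing against
# percentages printed to a fixed number of decimals.
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + sqrt(.Machine$double.eps)) / s
}
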
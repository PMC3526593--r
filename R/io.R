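#' Read a genotype dose matrix from TSV
#'
#' Expects a tab-delimited file whose first row holds SNP ids, first column
#' holds subject ids, and body holds dose codes in `{0, 1, 2, missing_token}`.
#'
#' @param path File path.
#' @param missing_token Token representing a missing call (default `"NA"`).
#' @return A [genotype_matrix()].
#' @export
read_genotypes_tsv <- function(path, missing_token = "NA") {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#", quote = "",
                           na.strings = character(0))
  if (ncol(raw) < 2) stop("genotype TSV must have a subject-id column and at least one SNP")
  subject_ids <- raw[[1]]
  snp_ids <- colnames(raw)[-1]
  body <- as.matrix(raw[, -1, drop = FALSE])
  is_missing <- body == missing_token
  ok <- is_missing | body %in% c("0", "1", "2")
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed genotype token '%s' at row %d (subject '%s'), column '%s'",
                 body[idx[1], idx[2]], idx[1], subject_ids[idx[1]], snp_ids[idx[2]]))
  }
  body[is_missing] <- NA
  doses <- matrix(as.integer(body), nrow = nrow(body))
  genotype_matrix(doses, subject_ids = subject_ids, snp_ids = snp_ids)
}

#' Write a genotype dose matrix to TSV
#'
#' Inverse of [read_genotypes_tsv()]; round-trips exactly.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @param missing_token Token written for missing calls.
#' @param header_comments Optional character vector written as `#`-prefixed
#'   provenance lines (config, seed).
#' @export
write_genotypes_tsv <- function(genotypes, path, missing_token = "NA",
                                header_comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_comments)) {
    writeLines(paste0("# ", header_comments), con)
  }
  writeLines(paste(c("subject_id", colnames(genotypes)), collapse = "\t"), con)
  body <- matrix(as.character(genotypes), nrow = nrow(genotypes))
  body[is.na(body)] <- missing_token
  writeLines(paste(rownames(genotypes),
                   apply(body, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Read subject covariates/phenotype from TSV
#'
#' @param path Tab-delimited file with named columns `subject_id`, `status`
#'   and optionally `age_group`, `gender`, `smoking`, `stage`; empty fields
#'   and `"NA"` are treated as missing.
#' @return A [subject_table()].
#' @export
read_subjects_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "", na.strings = c("NA", ""))
  subject_table(df)
}

#' Read SNP annotation from TSV
#'
#' @param path Tab-delimited file with named columns `snp_id`,
#'   `functional_group` and optionally `rsid`, `gene`.
#' @return A [snp_annotation()].
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "", na.strings = c("NA", ""))
  snp_annotation(df)
}

#' Write a subject table or annotation table to TSV
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param header_comments Optional `#`-prefixed provenance lines.
#' @export
write_table_tsv <- function(df, path, header_comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_comments)) writeLines(paste0("# ", header_comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read genotypes from PLINK PED/MAP files
#'
#' Parses whitespace-delimited PED (six leading columns, then two allele
#' columns per SNP; allele `0` = missing) and a 4-column MAP. Doses are
#' counts of the minor allele per SNP; the `"0 0"` allele pair maps to
#' missing.
#'
#' @param ped_path PED file path.
#' @param map_path MAP file path.
#' @param minor_allele_policy Either `"observed"` (minor allele inferred from
#'   observed allele frequencies in the file; ties broken alphabetically) or
#'   a named character vector giving the minor allele per SNP id.
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `map` (data frame: chrom, snp_id, cm, pos, minor_allele). Monomorphic
#'   SNPs under the observed policy get dose 0 everywhere, with a warning.
#' @export
read_plink_ped_map <- function(ped_path, map_path,
                               minor_allele_policy = "observed") {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"))
  if (anyDuplicated(map$snp_id)) stop("duplicate SNP ids in MAP file")
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  n_allele_cols <- ncol(ped) - 6L
  if (n_allele_cols != 2L * nrow(map)) {
    stop(sprintf("PED/MAP SNP-count mismatch: PED has %d allele columns for %d MAP SNPs",
                 n_allele_cols, nrow(map)))
  }
  subject_ids <- ped[[2]]
  n <- nrow(ped)
  m <- nrow(map)
  doses <- matrix(NA_integer_, n, m)
  minor <- character(m)
  monomorphic <- character(0)
  for (j in seq_len(m)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    missing <- a1 == "0" | a2 == "0"
    alleles <- c(a1[!missing], a2[!missing])
    if (identical(minor_allele_policy, "observed")) {
      tab <- sort(table(alleles))
      if (length(tab) == 0L || length(tab) == 1L) {
        minor[j] <- NA_character_
        monomorphic <- c(monomorphic, map$snp_id[j])
        doses[!missing, j] <- 0L
        next
      }
      if (length(tab) > 2L) {
        stop(sprintf("SNP '%s' has more than two alleles: %s", map$snp_id[j],
                     paste(names(tab), collapse = ", ")))
      }
      # ties on frequency broken alphabetically for determinism
      cand <- names(tab)[tab == min(tab)]
      minor[j] <- sort(cand)[1]
    } else {
      if (is.null(names(minor_allele_policy)) ||
          !map$snp_id[j] %in% names(minor_allele_policy)) {
        stop(sprintf("no minor allele supplied for SNP '%s'", map$snp_id[j]))
      }
      minor[j] <- minor_allele_policy[[map$snp_id[j]]]
    }
    doses[, j] <- (a1 == minor[j]) + (a2 == minor[j])
    doses[missing, j] <- NA_integer_
  }
  if (length(monomorphic)) {
    warning("monomorphic SNP(s) set to dose 0 for all subjects: ",
            paste(monomorphic, collapse = ", "))
  }
  map$minor_allele <- minor
  list(genotypes = genotype_matrix(doses, subject_ids = subject_ids,
                                   snp_ids = map$snp_id),
       map = map)
}

#' Cross-validate genotype, subject and annotation inputs
#'
#' The pipeline refuses to run association on unvalidated data; this is the
#' gate. It reports subjects lacking covariates, SNPs lacking annotation, and
#' per-variable missingness counts.
#'
#' @param genotypes A [genotype_matrix()].
#' @param subjects A [subject_table()].
#' @param annotation A [snp_annotation()].
#' @return A list of class `"validation_report"` with elements
#'   `subjects_without_covariates`, `snps_without_annotation`,
#'   `missingness` (named counts), `n_common_subjects`, and `ok` (TRUE when
#'   no issue was found).
#' @export
validate_dataset <- function(genotypes, subjects, annotation) {
  common <- intersect(rownames(genotypes), subjects$subject_id)
  if (length(common) == 0L) {
    stop("no subject ids shared between genotype matrix and subject table")
  }
  missing_subj <- setdiff(rownames(genotypes), subjects$subject_id)
  missing_snp <- setdiff(colnames(genotypes), annotation$snp_id)
  miss_geno <- colSums(is.na(genotypes))
  covar_miss <- vapply(
    intersect(c("age_group", "gender", "smoking"), names(subjects)),
    function(v) sum(is.na(subjects[[v]])), integer(1))
  rpt <- list(
    subjects_without_covariates = missing_subj,
    snps_without_annotation = missing_snp,
    missingness = list(genotype_per_snp = miss_geno, covariates = covar_miss),
    n_common_subjects = length(common),
    ok = length(missing_subj) == 0L && length(missing_snp) == 0L
  )
  class(rpt) <- "validation_report"
  rpt
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation report:", if (x$ok) "OK" else "ISSUES FOUND", "\n")
  cat("  common subjects:", x$n_common_subjects, "\n")
  if (length(x$subjects_without_covariates)) {
    cat("  subjects without covariates:",
        paste(utils::head(x$subjects_without_covariates, 10), collapse = ", "), "\n")
  }
  if (length(x$snps_without_annotation)) {
    cat("  SNPs without annotation:",
        paste(utils::head(x$snps_without_annotation, 10), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Provenance header lines for output tables
#'
#' Every output table carries the package version, full configuration and
#' seed as `#`-prefixed comment lines.
#'
#' @param config An [analysis_config()].
#' @return Character vector of header lines (without the `#` prefix).
#' @export
provenance_header <- function(config) {
  vals <- unlist(unclass(config))
  c(sprintf("snpepi %s", as.character(utils::packageVersion("snpepi"))),
    paste0("config: ", paste(names(vals), vals, sep = "=", collapse = " ")))
}
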
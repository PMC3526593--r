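#' Published summary counts bundled with the package
#'
#' The package ships the published summary tables of the New Hampshire
#' bladder-cancer case-control study it emulates (population
#' characteristics; genotype counts for the HSD3B2 hormone-pathway SNP in
#' the New Hampshire population and its proxy in the Texas replication
#' population; the case-control counts behind the reported MDR and
#' epistasis-network SNP pairs). Individual-level data were never deposited,
#' so these count tables are the only exactly reproducible quantities; they
#' serve as oracles for arithmetic-level checks (percentages, crude odds
#' ratios, Hardy-Weinberg statistics).
#'
#' @return A data frame.
#' @name published_counts
NULL

#' @describeIn published_counts Study population characteristics (long
#'   format: variable, level, column, n, printed percentage, column total).
#' @export
published_study_characteristics <- function() {
  utils::read.table(
    system.file("extdata", "nh_study_characteristics.tsv", package = "snpepi"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE, quote = "",
    colClasses = c(printed_pct = "character"))
}

#' @describeIn published_counts Genotype counts and printed percentages for
#'   the HSD3B2 SNP (New Hampshire) and its Texas proxy.
#' @export
published_genotype_counts <- function() {
  utils::read.table(
    system.file("extdata", "published_genotype_counts.tsv", package = "snpepi"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE, quote = "",
    colClasses = c(controls_pct = "character", cases_pct = "character"))
}

#' @describeIn published_counts Collapsed two-SNP case-control counts behind
#'   the reported MDR and epistasis-network interactions.
#' @export
published_pair_counts <- function() {
  utils::read.table(
    system.file("extdata", "published_pair_counts.tsv", package = "snpepi"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE, quote = "")
}

# decimals used by a printed percentage string ("70.2" -> 1, "0.42" -> 2)
printed_decimals <- function(s) {
  has_dot <- grepl(".", s, fixed = TRUE)
  ifelse(has_dot, nchar(sub("^[^.]*\\.", "", s)), 0L)
}

#' Recompute printed percentages from their counts
#'
#' For each row, recomputes `100 * n / total`, rounds half-up to the number
#' of decimals the source table printed, and flags agreement. This is the
#' arithmetic consistency check run by the acceptance suite.
#'
#' @param n Counts.
#' @param total Column totals (denominators).
#' @param printed Printed percentages, as character (so the printed
#'   precision is preserved).
#' @return Data frame with `recomputed`, `printed`, `match` and the signed
#'   difference at printed precision.
#' @export
recompute_percentages <- function(n, total, printed) {
  dec <- printed_decimals(printed)
  recomputed <- round_half_up(100 * n / total, dec)
  printed_num <- as.numeric(printed)
  data.frame(recomputed = recomputed, printed = printed_num,
             match = abs(recomputed - printed_num) < 1e-9,
             diff = recomputed - printed_num)
}
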
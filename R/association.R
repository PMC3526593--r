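GENETIC_CODINGS <- c("het_vs_wt", "hom_vs_wt", "dominant")

# Subjects used and indicator variable for a genetic coding.
# het_vs_wt compares dose 1 vs 0 (dose-2 subjects excluded); hom_vs_wt
# compares dose 2 vs 0 (dose-1 subjects excluded); dominant compares
# dose >= 1 vs 0 on all genotyped subjects.
coding_indicator <- function(dose, scheme) {
  switch(scheme,
         het_vs_wt = list(keep = !is.na(dose) & dose %in% c(0L, 1L),
                          x = as.numeric(dose == 1L)),
         hom_vs_wt = list(keep = !is.na(dose) & dose %in% c(0L, 2L),
                          x = as.numeric(dose == 2L)),
         dominant = list(keep = !is.na(dose),
                         x = as.numeric(dose >= 1L)),
         stop("unknown genetic coding: ", scheme))
}

#' Fit a logistic regression by maximum likelihood
#'
#' Thin wrapper around the iteratively reweighted least squares fitter in
#' `stats::glm.fit`, exposing the quantities the pipeline needs: the
#' coefficient vector on the log-odds scale, its covariance matrix from the
#' observed information, the log-likelihood, and convergence/separation
#' diagnostics. A singular design is an error naming the collinear columns;
#' (quasi-)perfect separation is flagged, not silently returned.
#'
#' @param design_matrix Numeric design matrix including an intercept column.
#' @param outcome Binary 0/1 response.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance.
#' @return List of class `"logistic_fit"`: `coefficients`, `vcov`,
#'   `log_likelihood`, `n_used`, `converged`, `separation`.
#' @export
fit_logistic <- function(design_matrix, outcome, max_iter = 100, tol = 1e-10) {
  design_matrix <- as.matrix(design_matrix)
  if (is.null(colnames(design_matrix))) {
    colnames(design_matrix) <- paste0("x", seq_len(ncol(design_matrix)))
  }
  if (length(outcome) != nrow(design_matrix)) {
    stop("outcome length does not match design matrix rows")
  }
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  dq <- qr(design_matrix)
  if (dq$rank < ncol(design_matrix)) {
    aliased <- colnames(design_matrix)[dq$pivot[(dq$rank + 1):ncol(design_matrix)]]
    stop("singular design matrix; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm.fit(
    design_matrix, outcome, family = stats::binomial(),
    control = stats::glm.control(epsilon = tol, maxit = max_iter)))
  mu <- fit$fitted.values
  eps <- 1e-8
  separation <- any(mu < eps | mu > 1 - eps)
  # for a Bernoulli response the saturated log-likelihood is 0
  ll <- -fit$deviance / 2
  p <- ncol(design_matrix)
  R <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  vc <- chol2inv(R)
  piv <- fit$qr$pivot[seq_len(p)]
  vc <- vc[order(piv), order(piv), drop = FALSE]
  dimnames(vc) <- list(colnames(design_matrix), colnames(design_matrix))
  out <- list(coefficients = stats::coef(fit), vcov = vc,
              log_likelihood = ll, n_used = nrow(design_matrix),
              converged = fit$converged && !separation,
              separation = separation)
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(coef = x$coefficients, se = se,
                    or = exp(x$coefficients),
                    ci_low = exp(x$coefficients - 1.96 * se),
                    ci_high = exp(x$coefficients + 1.96 * se))
  print(tab)
  cat(sprintf("logLik %.3f on n = %d%s\n", x$log_likelihood, x$n_used,
              if (x$separation) " [separation detected]" else ""))
  invisible(x)
}

# Wald summary for one coefficient of a logistic_fit
wald_summary <- function(fit, term) {
  b <- fit$coefficients[term]
  se <- sqrt(fit$vcov[term, term])
  list(or = exp(b), ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
       p = 2 * stats::pnorm(-abs(b / se)))
}

#' Likelihood ratio test between nested logistic fits
#'
#' @param full_fit,reduced_fit [fit_logistic()] results on identical subject
#'   sets, `reduced_fit` nested in `full_fit`.
#' @param df Degrees of freedom (default: difference in parameter counts).
#' @return List with `statistic` and `p_value` from chi-square(`df`).
#' @export
lrt <- function(full_fit, reduced_fit, df = NULL) {
  if (is.null(df)) {
    df <- length(full_fit$coefficients) - length(reduced_fit$coefficients)
  }
  stat <- 2 * (full_fit$log_likelihood - reduced_fit$log_likelihood)
  if (stat < -1e-6) {
    stop("negative LRT statistic: models are not nested or fit on different data")
  }
  stat <- max(stat, 0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, returned in input order: sort ascending,
#' q_i = min over j >= i of p_j * m / j, capped at 1.
#'
#' @param p_values Numeric vector of p-values in [0, 1] (NAs preserved).
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

# Covariate design: age strata and smoking as categorical, gender binary.
# Unused factor levels are dropped per model so designs stay full rank.
covariate_frame <- function(subjects, include_gender = TRUE) {
  df <- data.frame(row.names = subjects$subject_id)
  if (!is.null(subjects$age_group)) df$age_group <- subjects$age_group
  if (include_gender && !is.null(subjects$gender)) df$gender <- subjects$gender
  if (!is.null(subjects$smoking)) df$smoking <- subjects$smoking
  df
}

build_design <- function(x, covars) {
  df <- droplevels(covars)
  keep_var <- vapply(df, function(v) length(unique(v)) > 1, logical(1))
  df <- df[, keep_var, drop = FALSE]
  df$.x <- x
  mm <- stats::model.matrix(~ ., data = df)
  mm
}

# Subject rows for a stratum. Gender strata restrict both groups; stage
# strata keep all controls and restrict cases.
stratum_subjects <- function(subjects, stratum) {
  switch(stratum,
         overall = rep(TRUE, nrow(subjects)),
         male = subjects$gender == "male",
         female = subjects$gender == "female",
         invasive_vs_controls =
           subjects$status == 0L |
           (!is.na(subjects$stage) & subjects$stage == "invasive"),
         noninvasive_vs_controls =
           subjects$status == 0L |
           (!is.na(subjects$stage) & subjects$stage == "non-invasive"),
         stop("unknown stratum: ", stratum))
}

#' Per-SNP logistic association scan
#'
#' For each SNP and each genetic coding (heterozygous vs wildtype,
#' homozygous variant vs wildtype, dominant), fits a logistic model of
#' case-control status on the genotype indicator adjusted for age group,
#' gender and smoking status (gender omitted in gender strata), using
#' complete cases for smoking. Reports the Wald OR, 95% CI and p-value for
#' the genotype term, a minimum-cell-size stability flag (at least
#' `min_cell_size` cases and controls in the non-referent genotype group),
#' and Benjamini-Hochberg FDR-adjusted p-values computed within each
#' functional group (separately per coding).
#'
#' @param genotypes A [genotype_matrix()].
#' @param subjects A [subject_table()].
#' @param annotation A [snp_annotation()] covering every SNP.
#' @param config An [analysis_config()].
#' @param stratum One of `"overall"`, `"male"`, `"female"`,
#'   `"invasive_vs_controls"`, `"noninvasive_vs_controls"`.
#' @param codings Genetic codings to run (default all three).
#' @param fdr_scope `"group"` (default, within functional group) or
#'   `"global"` for a sensitivity analysis across all SNPs.
#' @return Data frame with one row per SNP x coding: counts, OR, CI, p,
#'   FDR-adjusted p, `min_cell_ok`, `n_used`.
#' @export
single_snp_scan <- function(genotypes, subjects, annotation,
                            config = analysis_config(),
                            stratum = "overall",
                            codings = GENETIC_CODINGS,
                            fdr_scope = c("group", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  vr <- validate_dataset(genotypes, subjects, annotation)
  if (!vr$ok) {
    stop("dataset failed validation; see validate_dataset() report")
  }
  subjects <- subjects[match(rownames(genotypes), subjects$subject_id), ]
  keep_stratum <- stratum_subjects(subjects, stratum)
  include_gender <- !stratum %in% c("male", "female")
  sub <- subjects[keep_stratum, , drop = FALSE]
  gmat <- genotypes[keep_stratum, , drop = FALSE]
  covars <- covariate_frame(sub, include_gender = include_gender)
  cc <- stats::complete.cases(covars)
  group <- annotation$functional_group[match(colnames(gmat), annotation$snp_id)]

  rows <- vector("list", ncol(gmat) * length(codings))
  k <- 0L
  for (j in seq_len(ncol(gmat))) {
    dose <- gmat[, j]
    for (scheme in codings) {
      ind <- coding_indicator(dose, scheme)
      keep <- ind$keep & cc
      x <- ind$x[keep]
      y <- sub$status[keep]
      n_case_exp <- sum(x == 1 & y == 1)
      n_ctrl_exp <- sum(x == 1 & y == 0)
      min_ok <- n_case_exp >= config$min_cell_size &&
        n_ctrl_exp >= config$min_cell_size
      est <- list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  p = NA_real_)
      n_used <- sum(keep)
      if (length(unique(x)) > 1 && length(unique(y)) > 1) {
        mm <- build_design(x, covars[keep, , drop = FALSE])
        fit <- tryCatch(fit_logistic(mm, y), error = function(e) NULL)
        if (!is.null(fit)) est <- wald_summary(fit, ".x")
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        snp_id = colnames(gmat)[j], coding = scheme, stratum = stratum,
        functional_group = as.character(group[j]),
        n_case_exposed = n_case_exp, n_ctrl_exposed = n_ctrl_exp,
        or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
        p = est$p, min_cell_ok = min_ok, n_used = n_used,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$fdr_adjusted_p <- NA_real_
  fdr_unit <- if (fdr_scope == "group") {
    interaction(res$functional_group, res$coding, drop = TRUE)
  } else {
    factor(res$coding)
  }
  for (u in levels(fdr_unit)) {
    i <- which(fdr_unit == u)
    res$fdr_adjusted_p[i] <- bh_fdr(res$p[i])
  }
  res
}

#' SNP-by-covariate interaction test
#'
#' Likelihood ratio test comparing the adjusted logistic model with and
#' without SNP-by-covariate product terms, plus covariate-stratum-specific
#' genotype ORs.
#'
#' @param genotypes A [genotype_matrix()].
#' @param subjects A [subject_table()].
#' @param snp_id SNP to test.
#' @param covariate Name of a factor column of `subjects` (e.g. `"gender"`).
#' @param coding Genetic coding scheme.
#' @param config An [analysis_config()].
#' @return List with `interaction_p`, `lrt_statistic`, `df`, and
#'   `stratum_or` (data frame of per-level genotype ORs with
#'   minimum-cell-size flags).
#' @export
snp_covariate_interaction <- function(genotypes, subjects, snp_id, covariate,
                                      coding = "dominant",
                                      config = analysis_config()) {
  subjects <- subjects[match(rownames(genotypes), subjects$subject_id), ]
  dose <- genotypes[, snp_id]
  ind <- coding_indicator(dose, coding)
  covars <- covariate_frame(subjects, include_gender = covariate != "gender")
  z <- subjects[[covariate]]
  if (is.null(z)) stop("no such covariate: ", covariate)
  keep <- ind$keep & stats::complete.cases(covars) & !is.na(z)
  x <- ind$x[keep]
  y <- subjects$status[keep]
  z <- droplevels(factor(z[keep]))
  cv <- covars[keep, , drop = FALSE]

  base <- build_design(x, cv)
  zmm <- stats::model.matrix(~ z)[, -1, drop = FALSE]
  colnames(zmm) <- paste0(".z", seq_len(ncol(zmm)))
  red_mm <- cbind(base, zmm)
  int_mm <- zmm * x
  colnames(int_mm) <- paste0(".xz", seq_len(ncol(int_mm)))
  full_mm <- cbind(red_mm, int_mm)
  reduced <- fit_logistic(red_mm, y)
  full <- fit_logistic(full_mm, y)
  test <- lrt(full, reduced, df = ncol(int_mm))

  strata <- lapply(levels(z), function(lv) {
    i <- z == lv
    n_case_exp <- sum(x[i] == 1 & y[i] == 1)
    n_ctrl_exp <- sum(x[i] == 1 & y[i] == 0)
    est <- list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_)
    if (length(unique(x[i])) > 1 && length(unique(y[i])) > 1) {
      mm <- build_design(x[i], cv[i, , drop = FALSE])
      fit <- tryCatch(fit_logistic(mm, y[i]), error = function(e) NULL)
      if (!is.null(fit)) est <- wald_summary(fit, ".x")
    }
    data.frame(level = lv, or = est$or, ci_low = est$ci_low,
               ci_high = est$ci_high, p = est$p,
               n_case_exposed = n_case_exp, n_ctrl_exposed = n_ctrl_exp,
               min_cell_ok = n_case_exp >= config$min_cell_size &&
                 n_ctrl_exp >= config$min_cell_size,
               stringsAsFactors = FALSE)
  })
  list(interaction_p = test$p_value, lrt_statistic = test$statistic,
       df = ncol(int_mm), stratum_or = do.call(rbind, strata))
}

#' SNP-SNP interaction model
#'
#' Adjusted logistic model on a collapsed joint-genotype exposure with the
#' doubly-wildtype group as referent, plus a likelihood-ratio interaction
#' test comparing models with and without the interaction term(s).
#'
#' Collapsing schemes: `"dom_dom"` codes carriers at both SNPs against
#' doubly-wildtype (subjects carrying a variant at exactly one SNP form a
#' third, separately coded group); `"full"` codes all nine joint genotype
#' cells with wildtype-wildtype as referent; a custom scheme is a function
#' mapping the 9-level joint dose index (`3 * dose_a + dose_b`, 0-8) to group
#' labels whose first sorted level is the referent.
#'
#' @param genotypes A [genotype_matrix()].
#' @param subjects A [subject_table()].
#' @param snp_a,snp_b SNP ids.
#' @param collapsing `"dom_dom"`, `"full"`, or a function (see Details).
#' @param config An [analysis_config()].
#' @return List with `group_or` (per-group adjusted ORs vs referent,
#'   counts), `interaction_p`, `lrt_statistic`, `df`, `n_used`.
#' @export
snp_snp_interaction <- function(genotypes, subjects, snp_a, snp_b,
                                collapsing = "dom_dom",
                                config = analysis_config()) {
  subjects <- subjects[match(rownames(genotypes), subjects$subject_id), ]
  da <- genotypes[, snp_a]
  db <- genotypes[, snp_b]
  covars <- covariate_frame(subjects)
  keep <- !is.na(da) & !is.na(db) & stats::complete.cases(covars)
  da <- da[keep]; db <- db[keep]
  y <- subjects$status[keep]
  cv <- covars[keep, , drop = FALSE]
  cell <- 3L * da + db

  grp <- if (is.function(collapsing)) {
    factor(collapsing(cell))
  } else if (collapsing == "dom_dom") {
    factor(ifelse(da >= 1 & db >= 1, "both_carrier",
                  ifelse(da == 0 & db == 0, "wt_wt", "one_carrier")),
           levels = c("wt_wt", "one_carrier", "both_carrier"))
  } else if (collapsing == "full") {
    factor(sprintf("a%d_b%d", da, db),
           levels = sprintf("a%d_b%d", rep(0:2, each = 3), rep(0:2, 3)))
  } else {
    stop("unknown collapsing scheme")
  }
  grp <- droplevels(grp)
  if (nlevels(grp) < 2) stop("collapsing produced a single group; no estimable effect")
  if (sum(grp == levels(grp)[1]) == 0) stop("referent group is empty")

  base_cv <- droplevels(cv)
  keep_var <- vapply(base_cv, function(v) length(unique(v)) > 1, logical(1))
  base_cv <- base_cv[, keep_var, drop = FALSE]
  df_full <- cbind(base_cv, .grp = grp)
  full_mm <- stats::model.matrix(~ ., data = df_full)
  fit_grp <- fit_logistic(full_mm, y)

  # interaction LRT: dominant main effects with vs without their product
  # degenerate joint-genotype patterns (e.g. only two observed cells) make
  # the interaction term collinear with the mains; the group ORs are still
  # reported but no interaction test is possible
  xa <- as.numeric(da >= 1); xb <- as.numeric(db >= 1)
  test <- tryCatch({
    main_mm <- stats::model.matrix(~ ., data = cbind(base_cv, .xa = xa, .xb = xb))
    int_mm <- cbind(main_mm, .xab = xa * xb)
    lrt(fit_logistic(int_mm, y), fit_logistic(main_mm, y), df = 1)
  }, error = function(e) {
    warning("interaction term not estimable: ", conditionMessage(e))
    list(statistic = NA_real_, p_value = NA_real_)
  })

  terms <- paste0(".grp", levels(grp)[-1])
  group_or <- do.call(rbind, lapply(seq_along(terms), function(i) {
    est <- wald_summary(fit_grp, terms[i])
    lv <- levels(grp)[i + 1]
    data.frame(group = lv, or = est$or, ci_low = est$ci_low,
               ci_high = est$ci_high, p = est$p,
               n_cases = sum(grp == lv & y == 1),
               n_controls = sum(grp == lv & y == 0),
               stringsAsFactors = FALSE)
  }))
  group_or <- rbind(
    data.frame(group = levels(grp)[1], or = 1, ci_low = NA, ci_high = NA,
               p = NA, n_cases = sum(grp == levels(grp)[1] & y == 1),
               n_controls = sum(grp == levels(grp)[1] & y == 0),
               stringsAsFactors = FALSE),
    group_or)
  list(group_or = group_or, interaction_p = test$p_value,
       lrt_statistic = test$statistic, df = 1L, n_used = sum(keep))
}
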
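# Per-SNP additive and SNP-by-injury interaction regression.
#
# Model, per SNP x:
#   additive:    y ~ x + IG + age + sex + PC1..PCk
#   interaction: y ~ x + IG*x + IG + age + sex + PC1..PCk
# Ethnicity is deliberately NOT a GWAS covariate (it is one in the PRS
# models); the phenotype is assumed site-adjusted upstream.
#
# Implementation: covariates are projected out once (QR), then each
# SNP needs only a 1x1 (additive) or 2x2 (interaction) solve. This is
# algebraically identical to the full OLS fit, including t-based
# p-values on the correct residual degrees of freedom; SNPs with
# missing dosages fall back to a per-SNP complete-case lm fit.

gwas_covariates <- function(cohort, n_pcs = 20) {
  cohort <- as_cohort_table(cohort, n_pcs = n_pcs)
  pcs <- if (n_pcs > 0)
    as.matrix(cohort[, pc_cols(cohort, n_pcs), drop = FALSE]) else NULL
  C <- cbind(intercept = 1, injury = cohort$injury, age = cohort$age,
             sex = cohort$sex, pcs)
  if (qr(C)$rank < ncol(C))
    stop_gx("covariate matrix is rank deficient")
  C
}

align_geno_cohort <- function(geno, cohort) {
  idx <- match(cohort$sample_id, rownames(geno$dosage))
  if (anyNA(idx))
    stop_gx("cohort sample ids missing from genotypes: %s",
            paste(head(cohort$sample_id[is.na(idx)], 5), collapse = ", "))
  geno$dosage <- geno$dosage[idx, , drop = FALSE]
  geno
}

#' Filter SNPs by minor allele frequency
#'
#' MAF is computed from non-missing dosages as `min(f, 1-f)` with
#' `f = mean(dosage)/2`; SNPs with MAF below `threshold` (default the
#' conventional 0.05 common-variant floor) are dropped.
#'
#' @param geno a [genotype_matrix()].
#' @param threshold MAF threshold in \[0, 0.5\].
#' @return the filtered [genotype_matrix()].
#' @export
maf_filter <- function(geno, threshold = 0.05) {
  assert_fraction(threshold, "threshold", 0, 0.5)
  maf <- compute_maf(geno$dosage)
  keep <- which(!is.na(maf) & maf >= threshold)
  if (length(keep) == 0) warn_gx("maf_filter removed every SNP")
  geno_subset(geno, geno$snp_info$id[keep])
}

new_sumstats <- function(info, model, covar_fit) {
  out <- info[, c("id", "chrom", "pos", "ref", "alt", "maf")]
  rownames(out) <- NULL
  attr(out, "model") <- model
  attr(out, "covar_coefs") <- covar_fit
  out
}

#' Additive per-SNP GWAS
#'
#' One OLS fit per SNP of phenotype on dosage plus injury, age, sex and
#' the top `n_pcs` genetic PCs, on the complete cases for that SNP.
#' Two-sided t-test p-values. SNPs whose dosage is constant after
#' missing-data drop are reported as `NA` with a reason code rather
#' than failing the run.
#'
#' @param geno a [genotype_matrix()].
#' @param cohort a cohort table aligned by `sample_id`.
#' @param n_pcs number of PC covariates (default 20).
#' @return a summary-statistics data.frame with `beta_add`, `se_add`,
#'   `p_add`, `n_used`, `note`; model metadata in attributes.
#' @export
fit_additive_gwas <- function(geno, cohort, n_pcs = 20) {
  geno <- align_geno_cohort(geno, cohort)
  C <- gwas_covariates(cohort, n_pcs)
  y <- as.numeric(cohort$phenotype)
  n <- length(y)
  if (n < ncol(C) + 11)
    stop_gx("need at least %d complete cases", ncol(C) + 11)
  X <- geno$dosage
  qrC <- qr(C)
  ry <- qr.resid(qrC, y)
  res <- data.frame(n_used = rep(n, ncol(X)), beta_add = NA_real_,
                    se_add = NA_real_, p_add = NA_real_, note = "")
  has_na <- colSums(is.na(X)) > 0
  df <- n - ncol(C) - 1
  if (any(!has_na)) {
    Xc <- X[, !has_na, drop = FALSE]
    RX <- Xc - qr.fitted(qrC, Xc)
    sxx <- colSums(RX * RX)
    ok <- sxx > n * 1e-12
    beta <- ifelse(ok, colSums(RX * ry) / sxx, NA_real_)
    rss <- pmax(sum(ry * ry) - beta^2 * sxx, 0)
    se <- sqrt(rss / df / sxx)
    tt <- beta / se
    idx <- which(!has_na)
    res$beta_add[idx] <- beta
    res$se_add[idx] <- se
    res$p_add[idx] <- 2 * pt(-abs(tt), df)
    res$note[idx[!ok]] <- "constant_dosage"
  }
  for (j in which(has_na)) {
    cc <- !is.na(X[, j])
    res$n_used[j] <- sum(cc)
    fit <- safe_snp_lm(y[cc], cbind(X[cc, j], C[cc, -1, drop = FALSE]))
    if (is.null(fit)) { res$note[j] <- "constant_dosage"; next }
    res$beta_add[j] <- fit$beta[1]
    res$se_add[j] <- fit$se[1]
    res$p_add[j] <- fit$p[1]
  }
  covar_fit <- summary(lm(y ~ C - 1))$coefficients
  out <- cbind(new_sumstats(geno$snp_info, "additive", covar_fit), res)
  attr(out, "model") <- "additive"
  attr(out, "covar_coefs") <- covar_fit
  out
}

#' SNP-by-injury interaction GWAS
#'
#' Adds the `IG * x` term to the additive model; reports the SNP main
#' effect (`beta_main`) and the interaction effect (`beta_int`) with
#' their SEs and two-sided t-test p-values.
#'
#' @inheritParams fit_additive_gwas
#' @return a summary-statistics data.frame with `beta_main/se_main/
#'   p_main`, `beta_int/se_int/p_int`, `n_used`, `note`.
#' @export
fit_interaction_gwas <- function(geno, cohort, n_pcs = 20) {
  geno <- align_geno_cohort(geno, cohort)
  if (length(unique(cohort$injury)) < 2)
    stop_gx("both injury groups must be non-empty for the interaction model")
  C <- gwas_covariates(cohort, n_pcs)
  y <- as.numeric(cohort$phenotype)
  ig <- cohort$injury
  n <- length(y)
  X <- geno$dosage
  qrC <- qr(C)
  ry <- qr.resid(qrC, y)
  df <- n - ncol(C) - 2
  res <- data.frame(n_used = rep(n, ncol(X)), beta_main = NA_real_,
                    se_main = NA_real_, p_main = NA_real_,
                    beta_int = NA_real_, se_int = NA_real_,
                    p_int = NA_real_, note = "")
  has_na <- colSums(is.na(X)) > 0
  if (any(!has_na)) {
    idx <- which(!has_na)
    Xc <- X[, idx, drop = FALSE]
    XI <- Xc * ig
    RX <- Xc - qr.fitted(qrC, Xc)
    RI <- XI - qr.fitted(qrC, XI)
    a11 <- colSums(RX * RX); a12 <- colSums(RX * RI)
    a22 <- colSums(RI * RI)
    b1 <- colSums(RX * ry); b2 <- colSums(RI * ry)
    det <- a11 * a22 - a12^2
    ok <- det > n * 1e-12 & a11 > n * 1e-12
    bm <- (a22 * b1 - a12 * b2) / det
    bi <- (a11 * b2 - a12 * b1) / det
    rss <- pmax(sum(ry * ry) - (bm * b1 + bi * b2), 0)
    s2 <- rss / df
    se_m <- sqrt(s2 * a22 / det)
    se_i <- sqrt(s2 * a11 / det)
    res$beta_main[idx] <- ifelse(ok, bm, NA)
    res$se_main[idx] <- ifelse(ok, se_m, NA)
    res$p_main[idx] <- ifelse(ok, 2 * pt(-abs(bm / se_m), df), NA)
    res$beta_int[idx] <- ifelse(ok, bi, NA)
    res$se_int[idx] <- ifelse(ok, se_i, NA)
    res$p_int[idx] <- ifelse(ok, 2 * pt(-abs(bi / se_i), df), NA)
    res$note[idx[!ok]] <- "degenerate_design"
  }
  for (j in which(has_na)) {
    cc <- !is.na(X[, j])
    res$n_used[j] <- sum(cc)
    if (length(unique(ig[cc])) < 2) { res$note[j] <- "single_group"; next }
    fit <- safe_snp_lm(y[cc], cbind(X[cc, j], X[cc, j] * ig[cc],
                                    C[cc, -1, drop = FALSE]))
    if (is.null(fit)) { res$note[j] <- "degenerate_design"; next }
    res$beta_main[j] <- fit$beta[1]; res$se_main[j] <- fit$se[1]
    res$p_main[j] <- fit$p[1]
    res$beta_int[j] <- fit$beta[2]; res$se_int[j] <- fit$se[2]
    res$p_int[j] <- fit$p[2]
  }
  covar_fit <- summary(lm(y ~ C - 1))$coefficients
  out <- cbind(new_sumstats(geno$snp_info, "interaction", covar_fit), res)
  attr(out, "model") <- "interaction"
  attr(out, "covar_coefs") <- covar_fit
  out
}

# Full lm fit for SNPs with missing dosages; returns NULL on a
# degenerate design (constant SNP after the missing-drop).
safe_snp_lm <- function(y, M) {
  M <- cbind(1, M)
  qx <- qr(M)
  if (qx$rank < ncol(M)) return(NULL)
  fit <- lm.fit(M, y)
  df <- length(y) - ncol(M)
  if (df <= 0) return(NULL)
  s2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(s2 * diag(XtXinv))
  tt <- fit$coefficients / se
  # drop the intercept slot; caller indexes the SNP terms from 1
  list(beta = fit$coefficients[-1], se = se[-1],
       p = (2 * pt(-abs(tt), df))[-1])
}

#' Genomic-control inflation factor
#'
#' `lambda_GC = median(qchisq(1 - p, df = 1)) / 0.4549364`, the ratio
#' of the observed median association chi-square to its null median.
#' Values near 1 indicate a calibrated GWAS. QQ-plot coordinates
#' (expected vs observed -log10 p) are returned alongside.
#'
#' @param pvals p-values in (0, 1\].
#' @return list with `lambda` and a `qq` data.frame.
#' @export
genomic_control_lambda <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0) stop_gx("no p-values supplied")
  if (any(pvals <= 0 | pvals > 1)) stop_gx("p-values must lie in (0,1]")
  lambda <- median(qchisq(pvals, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1)
  obs <- -log10(sort(pvals))
  expd <- -log10(ppoints(length(pvals)))
  list(lambda = lambda, qq = data.frame(expected = expd, observed = obs))
}

#' Cross-study effect-size correlation
#'
#' Intersects two summary tables by SNP id and reports the Pearson
#' correlation of effect sizes. When both tables carry effect/other
#' alleles, alleles are harmonised: matching pairs kept, swapped pairs
#' flip the external beta's sign, strand-ambiguous (A/T, C/G) and
#' mismatching pairs are dropped. Without allele columns the match is
#' by id with a warning.
#'
#' @param a summary statistics from [fit_additive_gwas()] (or any table
#'   with `id`, `beta_add`/`beta` and optional `ref`/`alt`).
#' @param b external summary table with `id`, `beta`, optional
#'   `effect_allele`/`other_allele`.
#' @return list with `r`, `n_overlap`, `pairs` (per-SNP table),
#'   `n_flipped`, `n_dropped`.
#' @export
effect_size_correlation <- function(a, b) {
  beta_a <- a$beta_add %||% a$beta
  da <- data.frame(id = a$id, beta_a = beta_a,
                   ref = a$ref %||% NA, alt = a$alt %||% NA)
  db <- data.frame(id = b$id, beta_b = b$beta,
                   ea = b$effect_allele %||% NA,
                   oa = b$other_allele %||% NA)
  m <- merge(da, db, by = "id")
  n_flipped <- 0L; n_dropped <- 0L
  if (!all(is.na(m$ea)) && !all(is.na(m$ref))) {
    ambiguous <- function(x, y) paste0(x, y) %in% c("AT", "TA", "CG", "GC")
    amb <- ambiguous(m$ref, m$alt) | ambiguous(m$oa, m$ea)
    same <- m$alt == m$ea & m$ref == m$oa
    swap <- m$alt == m$oa & m$ref == m$ea
    n_flipped <- sum(swap & !amb, na.rm = TRUE)
    m$beta_b[swap] <- -m$beta_b[swap]
    keep <- (same | swap) & !amb
    n_dropped <- sum(!keep, na.rm = TRUE)
    m <- m[keep, , drop = FALSE]
  } else {
    warn_gx("no allele columns; matching by id only")
  }
  m <- m[complete.cases(m[, c("beta_a", "beta_b")]), , drop = FALSE]
  if (nrow(m) < 10)
    stop_gx("only %d overlapping SNPs; need at least 10", nrow(m))
  list(r = cor(m$beta_a, m$beta_b), n_overlap = nrow(m),
       pairs = m[, c("id", "beta_a", "beta_b")],
       n_flipped = n_flipped, n_dropped = n_dropped)
}

#' Compare related vs unrelated trait correlations
#'
#' Wilcoxon rank-sum test that effect-size correlations with related
#' traits exceed those with unrelated traits; both the two-sided and
#' the one-sided ("greater") p-values are reported. Exact enumeration
#' is used when there are no ties.
#'
#' @param related_r,unrelated_r numeric vectors of correlations.
#' @return list with `p_two_sided`, `p_greater`, and the test objects.
#' @export
compare_trait_correlations <- function(related_r, unrelated_r) {
  if (length(related_r) == 0 || length(unrelated_r) == 0)
    stop_gx("both groups must be non-empty")
  exact <- !anyDuplicated(c(related_r, unrelated_r))
  w2 <- suppressWarnings(wilcox.test(related_r, unrelated_r,
                                     alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  w1 <- suppressWarnings(wilcox.test(related_r, unrelated_r,
                                     alternative = "greater",
                                     exact = exact, correct = TRUE))
  list(p_two_sided = w2$p.value, p_greater = w1$p.value,
       test_two_sided = w2, test_greater = w1)
}
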
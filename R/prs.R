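# Pathway-based polygenic risk scores and phenotype model comparison.
#
#   PRS_add = sum_{a in A}  beta_a^add X_a
#   PRS_int = sum_{a in A\I} beta_a^add X_a
#           + sum_{i in I}   (beta_i^int X_i + IG * beta_gi^int X_i)
#
# A = SNPs selected from the additive GWAS, I = SNPs selected from the
# interaction GWAS; the interaction score depends on each sample's
# injury indicator IG.

#' Select top pathway SNPs from an enrichment table
#'
#' For every set with `fdr <= fdr_max`, its mapped SNPs are ranked by
#' the GWAS p-value (interaction p when the stats come from the
#' interaction model; ties broken by position then id) and the top
#' `top_k` taken; the union over sets is deduplicated, keeping each
#' SNP's best (lowest-rank) provenance. Effect sizes from `stats` are
#' attached as the PRS weights.
#'
#' @param enrich an enrichment table from [msea_run()].
#' @param mgmap SNP-to-gene map used for the enrichment run.
#' @param sets the gene-set collection used for the run.
#' @param stats summary statistics (additive or interaction model).
#' @param top_k SNPs per significant set (default 20).
#' @param fdr_max significance cut (default 0.05).
#' @return data.frame of class `snp_selection`: `snp`, `pathway`,
#'   `rank`, `p` plus weight columns (`beta_add` or
#'   `beta_main`/`beta_int`); attribute `model` records the source.
#' @export
select_pathway_snps <- function(enrich, mgmap, sets, stats, top_k = 20,
                                fdr_max = 0.05) {
  if (top_k < 1) stop_gx("top_k must be >= 1")
  if (!"fdr" %in% names(enrich)) stop_gx("enrichment table lacks 'fdr'")
  model <- attr(stats, "model") %||%
    (if ("p_int" %in% names(stats)) "interaction" else "additive")
  p_col <- if (model == "interaction") "p_int" else "p_add"
  sig <- enrich$set[enrich$fdr <= fdr_max]
  if (length(sig) == 0) {
    warn_gx("no significant sets at FDR <= %g; empty selection", fdr_max)
    return(empty_selection(model))
  }
  pv <- stats[[p_col]][match(mgmap$snp, stats$id)]
  pos <- stats$pos[match(mgmap$snp, stats$id)]
  picks <- lapply(sig, function(nm) {
    rows <- which(mgmap$gene %in% sets[[nm]] & !is.na(pv))
    rows <- rows[!duplicated(mgmap$snp[rows])]
    if (length(rows) == 0) return(NULL)
    ord <- rows[order_p_pos_id(pv[rows], pos[rows], mgmap$snp[rows])]
    take <- ord[seq_len(min(top_k, length(ord)))]
    data.frame(snp = mgmap$snp[take], pathway = nm,
               rank = seq_along(take), p = pv[take],
               stringsAsFactors = FALSE)
  })
  sel <- do.call(rbind, picks)
  if (is.null(sel) || nrow(sel) == 0) return(empty_selection(model))
  sel <- sel[order(sel$rank, sel$p), , drop = FALSE]
  sel <- sel[!duplicated(sel$snp), , drop = FALSE]
  si <- match(sel$snp, stats$id)
  if (model == "interaction") {
    sel$beta_main <- stats$beta_main[si]
    sel$beta_int <- stats$beta_int[si]
  } else {
    sel$beta_add <- stats$beta_add[si]
  }
  rownames(sel) <- NULL
  attr(sel, "model") <- model
  class(sel) <- c("snp_selection", "data.frame")
  sel
}

empty_selection <- function(model) {
  cols <- data.frame(snp = character(), pathway = character(),
                     rank = integer(), p = numeric())
  if (model == "interaction") {
    cols$beta_main <- numeric(); cols$beta_int <- numeric()
  } else cols$beta_add <- numeric()
  attr(cols, "model") <- model
  class(cols) <- c("snp_selection", "data.frame")
  cols
}

#' Keep SNPs associated in the injured group only
#'
#' Per candidate SNP, fits phenotype ~ dosage + age + sex + PCs
#' separately within the mTBI and the orthopedic-injury samples,
#' applies BH across candidates within each group, and retains SNPs
#' with mTBI FDR <= `fdr_max` and OI FDR > `fdr_max`.
#'
#' @param sel a `snp_selection`.
#' @param geno a [genotype_matrix()] covering the selection.
#' @param cohort the cohort table.
#' @param fdr_max per-group FDR threshold (default 0.05).
#' @param n_pcs PC covariates in the within-group fits (default 20).
#' @return the filtered `snp_selection`, with `p_mtbi`, `fdr_mtbi`,
#'   `p_oi`, `fdr_oi` columns attached.
#' @export
injury_specific_filter <- function(sel, geno, cohort, fdr_max = 0.05,
                                   n_pcs = 20) {
  if (nrow(sel) == 0) return(sel)
  geno <- align_geno_cohort(geno, cohort)
  miss <- setdiff(sel$snp, geno$snp_info$id)
  if (length(miss)) stop_gx("selection SNPs absent from genotypes: %s",
                            paste(head(miss, 5), collapse = ", "))
  pcs <- as.matrix(cohort[, pc_cols(cohort, n_pcs), drop = FALSE])
  covs <- cbind(age = cohort$age, sex = cohort$sex, pcs)
  group_p <- function(rows) {
    if (length(rows) < ncol(covs) + 3)
      stop_gx("injury group too small (%d) for the per-group fits",
              length(rows))
    vapply(sel$snp, function(s) {
      x <- geno$dosage[rows, match(s, geno$snp_info$id)]
      cc <- !is.na(x)
      fit <- safe_snp_lm(cohort$phenotype[rows][cc],
                         cbind(x[cc], covs[rows, , drop = FALSE][cc, ]))
      if (is.null(fit)) NA_real_ else fit$p[1]
    }, numeric(1))
  }
  p_mtbi <- group_p(which(cohort$injury == 1))
  p_oi <- group_p(which(cohort$injury == 0))
  fdr_mtbi <- bh_fdr(p_mtbi)
  fdr_oi <- bh_fdr(p_oi)
  keep <- !is.na(fdr_mtbi) & fdr_mtbi <= fdr_max &
    (is.na(fdr_oi) | fdr_oi > fdr_max)
  out <- sel[keep, , drop = FALSE]
  out$p_mtbi <- p_mtbi[keep]; out$fdr_mtbi <- fdr_mtbi[keep]
  out$p_oi <- p_oi[keep]; out$fdr_oi <- fdr_oi[keep]
  rownames(out) <- NULL
  attr(out, "model") <- attr(sel, "model")
  class(out) <- c("snp_selection", "data.frame")
  out
}

#' Compute per-sample polygenic risk scores
#'
#' Evaluates the additive or interaction PRS formulas exactly. In
#' interaction mode, `sel` must be a list with components `A` (an
#' additive-model selection) and `I` (an interaction-model selection);
#' SNPs in `A` but not `I` contribute their additive weights, SNPs in
#' `I` contribute `beta_main X + IG beta_int X`. Missing dosages are
#' mean-imputed to `2 * MAF` (PRS only; GWAS fits never impute).
#'
#' @param sel a `snp_selection` (additive mode) or `list(A = , I = )`
#'   (interaction mode).
#' @param geno a [genotype_matrix()] holding every selected SNP.
#' @param cohort the cohort table (supplies IG).
#' @param mode `"additive"` or `"interaction"`.
#' @return data.frame with `sample_id` and `prs`.
#' @export
compute_prs <- function(sel, geno, cohort,
                        mode = c("additive", "interaction")) {
  mode <- match.arg(mode)
  geno <- align_geno_cohort(geno, cohort)
  dosage_of <- function(ids) {
    miss <- setdiff(ids, geno$snp_info$id)
    if (length(miss)) stop_gx("SNPs absent from genotypes: %s",
                              paste(head(miss, 10), collapse = ", "))
    j <- match(ids, geno$snp_info$id)
    X <- geno$dosage[, j, drop = FALSE]
    for (k in seq_along(j)) {
      na <- is.na(X[, k])
      # mean imputation: 2 x alternate-allele frequency (PRS only;
      # GWAS fits never impute)
      if (any(na)) X[na, k] <- mean(X[!na, k])
    }
    X
  }
  if (mode == "additive") {
    A <- if (is.list(sel) && !is.data.frame(sel)) sel$A else sel
    score <- if (nrow(A) == 0) rep(0, nrow(cohort)) else
      drop(dosage_of(A$snp) %*% A$beta_add)
  } else {
    if (!is.list(sel) || is.data.frame(sel) ||
        is.null(sel$A) || is.null(sel$I))
      stop_gx("interaction mode needs sel = list(A = <additive selection>, I = <interaction selection>)")
    A <- sel$A; I <- sel$I
    a_only <- A[!A$snp %in% I$snp, , drop = FALSE]
    score <- rep(0, nrow(cohort))
    if (nrow(a_only) > 0)
      score <- score + drop(dosage_of(a_only$snp) %*% a_only$beta_add)
    if (nrow(I) > 0) {
      XI <- dosage_of(I$snp)
      score <- score + drop(XI %*% I$beta_main) +
        cohort$injury * drop(XI %*% I$beta_int)
    }
  }
  data.frame(sample_id = cohort$sample_id, prs = score,
             stringsAsFactors = FALSE)
}

prs_model_frame <- function(cohort, prs_add = NULL, prs_int = NULL) {
  d <- data.frame(phenotype = cohort$phenotype, injury = cohort$injury,
                  age = cohort$age, sex = cohort$sex,
                  ethnicity = factor(cohort$ethnicity))
  # dummy-code with the largest category (White) as reference
  if ("White" %in% levels(d$ethnicity))
    d$ethnicity <- stats::relevel(d$ethnicity, ref = "White")
  if (!is.null(prs_add))
    d$prs_add <- prs_add$prs[match(cohort$sample_id, prs_add$sample_id)]
  if (!is.null(prs_int))
    d$prs_int <- prs_int$prs[match(cohort$sample_id, prs_int$sample_id)]
  d
}

#' Fit and compare the null / additive / interaction phenotype models
#'
#' Null: `phenotype ~ injury + age + sex + ethnicity`; the additive and
#' interaction models add the respective PRS. Reports R-squared,
#' log-likelihood and AIC per model, likelihood-ratio tests for the two
#' nested pairs (statistic floored at 0), and the additive-vs-
#' interaction AIC difference with the >= 10-point significance
#' convention for non-nested models.
#'
#' @param prs_add,prs_int PRS data.frames from [compute_prs()].
#' @param cohort the cohort table.
#' @return list of class `model_report` with `fits`, `table` (per-model
#'   R2 / logLik / AIC), `coefficients` (with 95% CIs), `lrt`, and
#'   `delta_aic`.
#' @export
fit_phenotype_models <- function(prs_add, prs_int, cohort) {
  d <- prs_model_frame(cohort, prs_add, prs_int)
  if (sum(complete.cases(d)) < 50) stop_gx("need >= 50 complete cases")
  forms <- list(
    null = phenotype ~ injury + age + sex + ethnicity,
    additive = phenotype ~ prs_add + injury + age + sex + ethnicity,
    interaction = phenotype ~ prs_int + injury + age + sex + ethnicity)
  # a constant PRS (e.g. identically 0 from an empty selection) carries
  # no information: that model degenerates to the null model exactly
  if (sd(d$prs_add) == 0) forms$additive <- forms$null
  if (sd(d$prs_int) == 0) forms$interaction <- forms$null
  fits <- lapply(forms, function(f) {
    fit <- lm(f, data = d)
    if (any(is.na(coef(fit)))) {
      bad <- names(coef(fit))[is.na(coef(fit))]
      stop_gx("rank-deficient design; collinear terms: %s",
              paste(bad, collapse = ", "))
    }
    fit
  })
  tab <- data.frame(
    model = names(fits),
    r_squared = vapply(fits, function(f) summary(f)$r.squared, 0),
    log_lik = vapply(fits, function(f) as.numeric(logLik(f)), 0),
    aic = vapply(fits, AIC, 0), row.names = NULL)
  coefs <- lapply(fits, function(f) {
    ci <- confint(f)
    data.frame(term = names(coef(f)), estimate = coef(f),
               lo95 = ci[, 1], hi95 = ci[, 2], row.names = NULL)
  })
  lrt_row <- function(m) {
    stat <- max(0, 2 * (tab$log_lik[tab$model == m] -
                          tab$log_lik[tab$model == "null"]))
    data.frame(comparison = paste0("null_vs_", m), statistic = stat,
               df = 1, p = pchisq(stat, df = 1, lower.tail = FALSE))
  }
  lrt <- rbind(lrt_row("additive"), lrt_row("interaction"))
  delta <- tab$aic[tab$model == "additive"] -
    tab$aic[tab$model == "interaction"]
  structure(list(fits = fits, table = tab, coefficients = coefs,
                 lrt = lrt,
                 delta_aic = data.frame(
                   comparison = "additive_minus_interaction",
                   delta_aic = delta, significant = abs(delta) >= 10)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report>\n")
  print(x$table)
  print(x$lrt)
  cat(sprintf("AIC(additive) - AIC(interaction) = %.2f (>=10 rule: %s)\n",
              x$delta_aic$delta_aic, x$delta_aic$significant))
  invisible(x)
}

#' Stratified k-fold cross-validation of the three models
#'
#' Folds are stratified by injury group (round-robin within each
#' group after a seeded shuffle, so group counts differ by at most one
#' across folds). Per fold the three models are refit on the training
#' split; training and validation R-squared are recorded and compared
#' with a two-sided paired t-test per model.
#'
#' @param prs_add,prs_int PRS data.frames from [compute_prs()].
#' @param cohort the cohort table.
#' @param n_folds folds (default 5).
#' @param seed shuffle seed.
#' @return list with `folds` (per fold x model R2 table) and `t_tests`
#'   (per model paired train-vs-validation test).
#' @export
cross_validate <- function(prs_add, prs_int, cohort, n_folds = 5,
                           seed = 1) {
  d <- prs_model_frame(cohort, prs_add, prs_int)
  for (grp in c(0, 1))
    if (sum(d$injury == grp) < n_folds)
      stop_gx("injury group %d has fewer samples than folds", grp)
  fold <- integer(nrow(d))
  with_seed(child_seed(seed, "cv"), {
    for (grp in c(0, 1)) {
      idx <- sample(which(d$injury == grp))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  forms <- list(
    null = phenotype ~ injury + age + sex + ethnicity,
    additive = phenotype ~ prs_add + injury + age + sex + ethnicity,
    interaction = phenotype ~ prs_int + injury + age + sex + ethnicity)
  if (sd(d$prs_add) == 0) forms$additive <- forms$null
  if (sd(d$prs_int) == 0) forms$interaction <- forms$null
  rows <- list()
  for (k in seq_len(n_folds)) {
    train <- d[fold != k, , drop = FALSE]
    valid <- d[fold == k, , drop = FALSE]
    if (length(unique(valid$injury)) < 2 ||
        length(unique(train$injury)) < 2)
      stop_gx("fold %d has a single injury class", k)
    for (m in names(forms)) {
      fit <- lm(forms[[m]], data = train)
      r2_train <- summary(fit)$r.squared
      pred <- predict(fit, newdata = valid)
      r2_valid <- 1 - sum((valid$phenotype - pred)^2) /
        sum((valid$phenotype - mean(valid$phenotype))^2)
      rows[[length(rows) + 1]] <- data.frame(
        fold = k, model = m, r2_train = r2_train, r2_valid = r2_valid)
    }
  }
  folds <- do.call(rbind, rows)
  tt <- do.call(rbind, lapply(names(forms), function(m) {
    sub <- folds[folds$model == m, ]
    ts <- t.test(sub$r2_train, sub$r2_valid, paired = TRUE)
    data.frame(model = m, mean_train = mean(sub$r2_train),
               mean_valid = mean(sub$r2_valid), p = ts$p.value)
  }))
  list(folds = folds, t_tests = tt, fold_assignment = fold)
}
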
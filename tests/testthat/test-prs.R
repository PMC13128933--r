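# Pathway SNP selection, injury-specific filter, PRS formulas, model
# comparison, cross-validation.

# build a deterministic enrichment/map/stats scaffold
prs_world <- function(n_sets = 2, snps_per_set = 25, fdr = 0.01,
                      seed = 1) {
  set.seed(seed)
  sets <- list()
  mg <- NULL
  stats <- NULL
  for (s in seq_len(n_sets)) {
    genes <- sprintf("S%dG%02d", s, seq_len(5))
    ids <- sprintf("S%dsnp%02d", s, seq_len(snps_per_set))
    sets[[paste0("set", s)]] <- genes
    mg <- rbind(mg, data.frame(snp = ids,
                               gene = rep(genes, length.out = length(ids))))
    stats <- rbind(stats, data.frame(
      id = ids, pos = seq_along(ids) * 100 + s,
      beta_main = rnorm(length(ids)), beta_int = rnorm(length(ids)),
      p_int = runif(length(ids))))
  }
  attr(stats, "model") <- "interaction"
  enrich <- data.frame(set = names(sets), fdr = fdr)
  list(sets = gene_set_collection(sets), mgmap = mg, stats = stats,
       enrich = enrich)
}

test_that("selection: top-k per significant set, dedup, small sets", {
  w <- prs_world()
  sel <- select_pathway_snps(w$enrich, w$mgmap, w$sets, w$stats,
                             top_k = 20, fdr_max = 0.05)
  expect_equal(nrow(sel), 40)            # disjoint sets: 2 x 20
  expect_true(all(table(sel$pathway) == 20))
  expect_true(all(sel$rank <= 20))
  # per set, selected SNPs are exactly the 20 smallest p
  for (s in 1:2) {
    ids <- w$stats$id[grepl(paste0("^S", s), w$stats$id)]
    pv <- w$stats$p_int[match(ids, w$stats$id)]
    best <- ids[order(pv)][1:20]
    expect_setequal_chr(sel$snp[sel$pathway == paste0("set", s)], best)
  }
  # a set with 5 mapped SNPs yields all 5
  w5 <- prs_world(n_sets = 1, snps_per_set = 5)
  sel5 <- select_pathway_snps(w5$enrich, w5$mgmap, w5$sets, w5$stats,
                              top_k = 20)
  expect_equal(nrow(sel5), 5)
  # shared best SNP across two sets -> union is 2k - 1
  w2 <- prs_world()
  shared <- w2$stats$id[which.min(w2$stats$p_int)]
  other_set <- if (grepl("^S1", shared)) "set2" else "set1"
  w2$mgmap <- rbind(w2$mgmap,
                    data.frame(snp = shared,
                               gene = w2$sets[[other_set]][1]))
  w2$stats$p_int[w2$stats$id == shared] <- 1e-12
  sel2 <- select_pathway_snps(w2$enrich, w2$mgmap, w2$sets, w2$stats,
                              top_k = 20)
  expect_equal(nrow(sel2), 39)
  # no significant sets -> empty selection with warning
  w$enrich$fdr <- 0.5
  expect_warning(empty <- select_pathway_snps(w$enrich, w$mgmap, w$sets,
                                              w$stats, fdr_max = 0.05),
                 "no significant")
  expect_equal(nrow(empty), 0)
})

test_that("compute_prs matches a double-loop oracle to 1e-10", {
  set.seed(5)
  n <- 10; p <- 6
  dosage <- matrix(rbinom(n * p, 2, 0.4), n, p)
  g <- make_geno(dosage)
  co <- make_cohort(n, n_pcs = 0, seed = 2)
  rownames(g$dosage) <- co$sample_id
  A <- data.frame(snp = g$snp_info$id[1:4], beta_add = rnorm(4))
  I <- data.frame(snp = g$snp_info$id[3:5], beta_main = rnorm(3),
                  beta_int = rnorm(3))
  prs_a <- compute_prs(A, g, co, "additive")
  prs_i <- compute_prs(list(A = A, I = I), g, co, "interaction")
  for (i in seq_len(n)) {
    sa <- 0
    for (k in seq_len(nrow(A)))
      sa <- sa + A$beta_add[k] * dosage[i, match(A$snp[k], g$snp_info$id)]
    expect_equal(prs_a$prs[i], sa, tolerance = 1e-10)
    si <- 0
    for (k in seq_len(nrow(A)))           # A \ I additive part
      if (!A$snp[k] %in% I$snp)
        si <- si + A$beta_add[k] * dosage[i, match(A$snp[k], g$snp_info$id)]
    for (k in seq_len(nrow(I))) {
      x <- dosage[i, match(I$snp[k], g$snp_info$id)]
      si <- si + I$beta_main[k] * x + co$injury[i] * I$beta_int[k] * x
    }
    expect_equal(prs_i$prs[i], si, tolerance = 1e-10)
  }
})

test_that("printed-formula fixed points: single-SNP values and I = empty", {
  g <- make_geno(cbind(snp = c(2, 2)))
  co <- make_cohort(2, injury = c(1, 0), n_pcs = 0)
  rownames(g$dosage) <- co$sample_id
  I <- data.frame(snp = "s001", beta_main = 0.5, beta_int = 0.3)
  A0 <- data.frame(snp = character(), beta_add = numeric())
  prs <- compute_prs(list(A = A0, I = I), g, co, "interaction")
  expect_equal(prs$prs, c(0.5 * 2 + 1 * 0.3 * 2, 0.5 * 2))  # 1.6 and 1.0
  # I empty reduces the interaction PRS to the additive PRS
  A <- data.frame(snp = "s001", beta_add = 0.7)
  I0 <- data.frame(snp = character(), beta_main = numeric(),
                   beta_int = numeric())
  expect_equal(compute_prs(list(A = A, I = I0), g, co, "interaction")$prs,
               compute_prs(A, g, co, "additive")$prs)
  # missing dosages are imputed to 2 * MAF in PRS scoring
  gm <- make_geno(cbind(snp = c(2, 2, 0, NA)))
  com <- make_cohort(4, n_pcs = 0)
  rownames(gm$dosage) <- com$sample_id
  prs_m <- compute_prs(data.frame(snp = "s001", beta_add = 1), gm, com,
                       "additive")
  expect_equal(prs_m$prs[4], mean(c(2, 2, 0)))  # 2 x alt-allele freq
  # absent SNP -> error listing the id
  expect_error(compute_prs(data.frame(snp = "nope", beta_add = 1), gm,
                           com, "additive"), "nope")
})

test_that("injury-specific filter keeps mTBI-only effects", {
  retained_specific <- 0L; retained_shared <- 0L
  reps <- 12
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    n <- 600
    ig <- rep(c(1, 0), c(300, 300))
    x_spec <- rbinom(n, 2, 0.3)   # effect in mTBI only
    x_shared <- rbinom(n, 2, 0.3) # equal effect in both groups
    co <- make_cohort(n, injury = ig, n_pcs = 2, seed = r)
    co$phenotype <- 0.6 * x_spec * ig + 0.6 * x_shared +
      rnorm(n, 0, 1)
    g <- make_geno(cbind(a = x_spec, b = x_shared))
    rownames(g$dosage) <- co$sample_id
    sel <- data.frame(snp = c("s001", "s002"), pathway = "pw",
                      rank = 1:2, p = c(1e-4, 1e-4),
                      beta_main = c(0, 0.6), beta_int = c(0.6, 0))
    class(sel) <- c("snp_selection", "data.frame")
    attr(sel, "model") <- "interaction"
    out <- injury_specific_filter(sel, g, co, fdr_max = 0.05, n_pcs = 2)
    retained_specific <- retained_specific + ("s001" %in% out$snp)
    retained_shared <- retained_shared + ("s002" %in% out$snp)
  }
  expect_gte(retained_specific, reps - 2)
  expect_lte(retained_shared, 2)
  # empty candidate list passes through
  empty <- gxepath:::empty_selection("interaction")
  expect_equal(nrow(injury_specific_filter(empty, NULL, NULL)), 0)
})

test_that("model comparison: PRS = 0 degenerates, LRT definition holds", {
  set.seed(61)
  co <- make_cohort(200, n_pcs = 0, seed = 9)
  zero <- data.frame(sample_id = co$sample_id, prs = 0)
  some <- data.frame(sample_id = co$sample_id, prs = rnorm(200))
  # identically-zero PRS degenerates the additive model to the null one
  rep0 <- fit_phenotype_models(zero, some, co)
  expect_equal(rep0$table$r_squared[2], rep0$table$r_squared[1],
               tolerance = 1e-10)
  expect_equal(rep0$lrt$p[1], 1)
  rep_ <- fit_phenotype_models(some, some, co)
  expect_equal(rep_$table$model, c("null", "additive", "interaction"))
  expect_true(all(rep_$table$r_squared >= 0 & rep_$table$r_squared <= 1))
  # nested LRT statistic equals 2 * (ll_full - ll_null), chi2(1) p
  ll <- rep_$table$log_lik
  expect_equal(rep_$lrt$statistic[1], max(0, 2 * (ll[2] - ll[1])),
               tolerance = 1e-10)
  expect_equal(rep_$lrt$p[1],
               pchisq(rep_$lrt$statistic[1], 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # a PRS with no effect leaves R^2 essentially at the null value
  expect_lt(rep_$table$r_squared[2] - rep_$table$r_squared[1], 0.05)
})

test_that("planted interaction PRS wins on AIC; null LRT p uniform", {
  wins <- 0L
  reps <- 25
  for (r in seq_len(reps)) {
    set.seed(200 + r)
    n <- 300; p <- 12
    dosage <- matrix(rbinom(n * p, 2, 0.3), n, p)
    ig <- rbinom(n, 1, 0.3)
    co <- make_cohort(n, injury = ig, n_pcs = 2, seed = r)
    beta_gi <- rnorm(p, 0, 0.4)
    co$phenotype <- drop((dosage * ig) %*% beta_gi) + rnorm(n)
    g <- make_geno(dosage)
    rownames(g$dosage) <- co$sample_id
    add <- fit_additive_gwas(g, co, n_pcs = 2)
    int <- fit_interaction_gwas(g, co, n_pcs = 2)
    A <- data.frame(snp = add$id, beta_add = add$beta_add)
    I <- data.frame(snp = int$id, beta_main = int$beta_main,
                    beta_int = int$beta_int)
    prs_a <- compute_prs(A, g, co, "additive")
    prs_i <- compute_prs(list(A = A, I = I), g, co, "interaction")
    rep_ <- fit_phenotype_models(prs_a, prs_i, co)
    if (rep_$delta_aic$delta_aic > 0) wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.8)
  # LRT p uniform when the PRS carries no signal
  pvals <- vapply(seq_len(200), function(r) {
    set.seed(400 + r)
    co <- make_cohort(150, n_pcs = 0, seed = r)
    prs <- data.frame(sample_id = co$sample_id, prs = rnorm(150))
    fit_phenotype_models(prs, prs, co)$lrt$p[1]
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("cross-validation: stratification arithmetic and determinism", {
  co <- make_cohort(100, injury = rep(c(1, 0), c(30, 70)), n_pcs = 0,
                    seed = 3)
  prs <- data.frame(sample_id = co$sample_id, prs = rnorm(100))
  cv <- cross_validate(prs, prs, co, n_folds = 5, seed = 11)
  for (k in 1:5) {
    expect_equal(sum(cv$fold_assignment == k & co$injury == 1), 6)
    expect_equal(sum(cv$fold_assignment == k & co$injury == 0), 14)
  }
  cv2 <- cross_validate(prs, prs, co, n_folds = 5, seed = 11)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  # pure-noise phenotype: validation R^2 below training R^2 on average
  expect_lt(mean(cv$folds$r2_valid), mean(cv$folds$r2_train))
  expect_lt(mean(cv$folds$r2_valid[cv$folds$model == "null"]), 0.15)
  expect_error(cross_validate(prs, prs, co[co$injury == 0, ], 5, 1),
               "fewer samples")
})
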
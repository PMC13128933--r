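# Additive / interaction GWAS, lambda-GC, cross-study validation.

test_that("maf_filter keeps and drops per computed MAF", {
  d <- cbind(a = c(0, 0, 0, 1), b = c(0, 0, 0, 0), c = c(2, 2, 2, 1))
  g <- make_geno(d)
  kept <- maf_filter(g, 0.05)$snp_info
  # f = 0.125 -> kept; monomorphic -> dropped; f = 0.875 -> MAF 0.125
  expect_setequal_chr(kept$id, c("s001", "s003"))
  expect_equal(kept$maf, c(0.125, 0.125))
  expect_warning(maf_filter(make_geno(cbind(x = c(0, 0, 0, 0)))),
                 "every SNP")
})

test_that("OLS coefficients match the normal-equations oracle to 1e-8", {
  set.seed(7)
  n <- 18
  for (rep in 1:5) {
    dosage <- cbind(snp = rbinom(n, 2, 0.4))
    co <- make_cohort(n, n_pcs = 2, seed = rep)
    g <- make_geno(dosage)
    rownames(g$dosage) <- co$sample_id
    add <- fit_additive_gwas(g, co, n_pcs = 2)
    orc <- ols_oracle(co$phenotype,
                      cbind(dosage, co$injury, co$age, co$sex,
                            co$PC1, co$PC2))
    expect_equal(add$beta_add, unname(orc$beta[2]), tolerance = 1e-8)
    expect_equal(add$se_add, unname(orc$se[2]), tolerance = 1e-8)
    expect_equal(add$p_add, unname(orc$p[2]), tolerance = 1e-8)
    int <- fit_interaction_gwas(g, co, n_pcs = 2)
    orc2 <- ols_oracle(co$phenotype,
                       cbind(dosage, dosage * co$injury, co$injury,
                             co$age, co$sex, co$PC1, co$PC2))
    expect_equal(int$beta_main, unname(orc2$beta[2]), tolerance = 1e-8)
    expect_equal(int$beta_int, unname(orc2$beta[3]), tolerance = 1e-8)
    expect_equal(int$se_int, unname(orc2$se[3]), tolerance = 1e-8)
    expect_equal(int$p_int, unname(orc2$p[3]), tolerance = 1e-8)
  }
})

test_that("additive fit recovers a planted beta of 1.0 at n = 500", {
  set.seed(11)
  n <- 500
  x <- rbinom(n, 2, 0.3)
  co <- make_cohort(n, n_pcs = 2, seed = 3)
  co$phenotype <- 1.0 * x + rnorm(n, 0, 0.1)
  g <- make_geno(cbind(snp = x))
  rownames(g$dosage) <- co$sample_id
  add <- fit_additive_gwas(g, co, n_pcs = 2)
  expect_lt(abs(add$beta_add - 1.0), 0.05)
})

test_that("interaction fit recovers beta_gi = 0.8 and flags degeneracies", {
  set.seed(13)
  n <- 800
  x <- rbinom(n, 2, 0.3)
  ig <- rbinom(n, 1, 0.3)
  co <- make_cohort(n, injury = ig, n_pcs = 2, seed = 5)
  co$phenotype <- 0.8 * x * ig + rnorm(n, 0, 0.1)
  g <- make_geno(cbind(snp = x))
  rownames(g$dosage) <- co$sample_id
  int <- fit_interaction_gwas(g, co, n_pcs = 2)
  expect_lt(abs(int$beta_int - 0.8), 0.07)
  expect_lt(abs(int$beta_main - 0), 0.07)
  # affine invariance: shifting X changes only the intercept, so
  # beta_int from x and from x - 1 agree to 1e-8
  orc_a <- ols_oracle(co$phenotype, cbind(x, x * ig, ig, co$age))
  xc <- x - 1
  orc_b <- ols_oracle(co$phenotype, cbind(xc, xc * ig, ig, co$age))
  expect_equal(unname(orc_a$beta[3]) - unname(orc_b$beta[3]), 0,
               tolerance = 1e-8)
  # constant SNP -> NA row with reason code, not an error
  gc <- make_geno(cbind(snp = rep(1, n)))
  rownames(gc$dosage) <- co$sample_id
  res <- fit_additive_gwas(gc, co, n_pcs = 2)
  expect_true(is.na(res$beta_add))
  expect_equal(res$note, "constant_dosage")
  # single injury group -> error
  co1 <- co; co1$injury <- 0
  expect_error(fit_interaction_gwas(g, co1, n_pcs = 2), "injury groups")
})

test_that("missing dosages fall back to per-SNP complete-case fits", {
  set.seed(17)
  n <- 60
  x <- rbinom(n, 2, 0.4)
  co <- make_cohort(n, n_pcs = 2, seed = 7)
  xm <- x
  xm[sample(n, 6)] <- NA
  g <- make_geno(cbind(snp = xm))
  rownames(g$dosage) <- co$sample_id
  add <- fit_additive_gwas(g, co, n_pcs = 2)
  cc <- !is.na(xm)
  orc <- ols_oracle(co$phenotype[cc],
                    cbind(xm[cc], co$injury[cc], co$age[cc], co$sex[cc],
                          co$PC1[cc], co$PC2[cc]))
  expect_equal(add$n_used, sum(cc))
  expect_equal(add$beta_add, unname(orc$beta[2]), tolerance = 1e-8)
  expect_equal(add$p_add, unname(orc$p[2]), tolerance = 1e-8)
})

test_that("permuted-phenotype null: p uniform, type-I in binomial CI", {
  cfg <- sim_config(n_samples = 400, n_snps = 2000, ld_block_size = 1,
                    gxe_effect_size = 0, additive_effect_size = 0,
                    n_enriched_pathways = 0, seed = 23)
  st <- simulate_study(cfg)
  add <- fit_additive_gwas(st$genotypes, st$cohort)
  frac <- mean(add$p_add < 0.05)
  expect_gt(frac, 0.035)
  expect_lt(frac, 0.065)
  expect_gt(ks.test(add$p_add, "punif")$p.value, 0.01)
})

test_that("genomic-control lambda: fixed points and seeded uniform draw", {
  expect_equal(genomic_control_lambda(rep(0.5, 7))$lambda, 1.0)
  expect_equal(genomic_control_lambda(c(0.25, 0.5, 0.75))$lambda, 1.0)
  set.seed(31)
  lam <- genomic_control_lambda(runif(10000))$lambda
  expect_gt(lam, 0.97); expect_lt(lam, 1.03)
  qq <- genomic_control_lambda(c(0.1, 0.01))$qq
  expect_equal(dim(qq), c(2L, 2L))
  expect_error(genomic_control_lambda(numeric()), "no p-values")
  expect_error(genomic_control_lambda(c(0.5, 0)), "0,1")
})

test_that("effect-size correlation: identity, negation, attenuation", {
  set.seed(37)
  a <- data.frame(id = sprintf("rs%04d", 1:1000),
                  beta_add = rnorm(1000), ref = "A", alt = "G")
  b <- data.frame(id = a$id, beta = a$beta_add,
                  effect_allele = "G", other_allele = "A")
  expect_equal(effect_size_correlation(a, b)$r, 1.0)
  b_neg <- b; b_neg$beta <- -b_neg$beta
  expect_equal(effect_size_correlation(a, b_neg)$r, -1.0)
  # swapped alleles flip the external sign back to +1
  b_sw <- b_neg
  b_sw$effect_allele <- "A"; b_sw$other_allele <- "G"
  expect_equal(effect_size_correlation(a, b_sw)$r, 1.0)
  # independent noise of equal sd attenuates r to ~ 1/sqrt(2)
  b_noise <- b
  b_noise$beta <- b_noise$beta + rnorm(1000, 0, sd(a$beta_add))
  expect_lt(abs(effect_size_correlation(a, b_noise)$r - 0.707), 0.05)
  # strand-ambiguous pairs are dropped
  a2 <- a; a2$ref[1:10] <- "A"; a2$alt[1:10] <- "T"
  expect_equal(effect_size_correlation(a2, b)$n_overlap, 990)
  expect_error(effect_size_correlation(a[1:5, ], b[1:5, ]), "at least 10")
})

test_that("trait-correlation comparison: exact rank test and symmetry", {
  r <- compare_trait_correlations(c(0.3, 0.4, 0.5), c(0.0, 0.01, 0.02))
  expect_equal(r$p_greater, 0.05)  # complete separation, 1/C(6,3)
  same <- compare_trait_correlations(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$p_two_sided, 1.0)
  fwd <- compare_trait_correlations(c(0.3, 0.4, 0.5), c(0.0, 0.01, 0.02))
  rev <- compare_trait_correlations(c(0.0, 0.01, 0.02), c(0.3, 0.4, 0.5))
  expect_equal(fwd$p_greater, 1 - rev$p_greater + 0.05)
})
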
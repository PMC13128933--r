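# Synthetic-data generator: determinism, LD structure, planted truth.

test_that("fixed seed gives byte-identical outputs from every generator", {
  cfg <- tiny_cfg()
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$genes, b$genes)
  expect_identical(unclass(a$gene_sets), unclass(b$gene_sets))
  expect_identical(a$expression$counts, b$expression$counts)
  expect_identical(a$truth, b$truth)
  d <- simulate_genotypes(tiny_cfg(seed = 43))
  expect_false(identical(a$genotypes$dosage, d$dosage))
})

test_that("within_block_r = 0 gives uncorrelated SNPs; blocks of 1 too", {
  cfg <- sim_config(n_samples = 2000, n_snps = 120, ld_block_size = 6,
                    within_block_r = 0, seed = 2)
  g <- simulate_genotypes(cfg)
  cm <- cor(g$dosage)
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.05)
  cfg1 <- sim_config(n_samples = 2000, n_snps = 120, ld_block_size = 1,
                     within_block_r = 0.9, seed = 2)
  cm1 <- cor(simulate_genotypes(cfg1)$dosage)
  expect_lt(mean(abs(cm1[upper.tri(cm1)])), 0.05)
})

test_that("positive within_block_r produces within-block LD", {
  cfg <- sim_config(n_samples = 1500, n_snps = 100, ld_block_size = 10,
                    within_block_r = 0.8, seed = 3)
  g <- simulate_genotypes(cfg)
  cm <- cor(g$dosage)
  blk <- rep(seq_len(10), each = 10)
  within <- outer(blk, blk, "==") & upper.tri(cm)
  between <- !outer(blk, blk, "==") & upper.tri(cm)
  expect_gt(mean(cm[within]), 0.35)
  expect_lt(mean(abs(cm[between])), 0.05)
  # dosages are hard calls with per-SNP MAF inside the requested range
  expect_true(all(g$dosage %in% 0:2))
  expect_true(all(g$snp_info$maf >= 0.03 & g$snp_info$maf <= 0.5))
})

test_that("cohort: injury balance, exact covariate phenotype at sd 0", {
  cfg <- tiny_cfg(n_samples = 1522, n_snps = 500, frac_mtbi = 0.224,
                  seed = 9)
  g <- simulate_genotypes(cfg)
  genes <- simulate_gene_annotation(cfg)
  truth <- plant_truth(cfg, g, genes)
  co <- simulate_cohort(cfg, g, truth)
  # Bernoulli(0.224) at n = 1522: expected 341, allow 4 sd
  expect_lt(abs(sum(co$injury) - 341), 4 * sqrt(1522 * 0.224 * 0.776))
  expect_equal(attr(co, "pc_source"), "genotype_svd")
  # zero noise + zero genetic effects -> exact linear function of covariates
  cfg0 <- tiny_cfg(noise_sd = 0, gxe_effect_size = 0,
                   additive_effect_size = 0, n_enriched_pathways = 0)
  g0 <- simulate_genotypes(cfg0)
  t0 <- plant_truth(cfg0, g0, simulate_gene_annotation(cfg0))
  co0 <- simulate_cohort(cfg0, g0, t0)
  z_age <- as.numeric(scale(co0$age))
  manual <- 0.3 * z_age + 0.2 * co0$sex - 0.1 * co0$injury +
    0.1 * co0$PC1 - 0.1 * co0$PC2
  expect_equal(co0$phenotype, manual, tolerance = 1e-12)
})

test_that("gene annotation: sorted, non-overlapping, BED round-trip", {
  skip_if_not_installed("rtracklayer")
  cfg <- tiny_cfg()
  gm <- simulate_gene_annotation(cfg)
  expect_true(all(gm$start < gm$end))
  for (chr in unique(gm$chrom)) {
    sub <- gm[gm$chrom == chr, ]
    expect_true(all(diff(sub$start) > 0))
    expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
  path <- tempfile(fileext = ".bed")
  write_bed(gm, path)
  back <- read_bed(path)
  expect_equal(back$start, gm$start)
  expect_equal(back$end, gm$end)
  expect_equal(back$symbol, gm$symbol)
})

test_that("gene sets: sizes in range, planting consistent, GMT round-trip", {
  cfg <- tiny_cfg()
  g <- simulate_genotypes(cfg)
  genes <- simulate_gene_annotation(cfg)
  truth <- plant_truth(cfg, g, genes)
  sets <- simulate_gene_sets(cfg, genes, truth)
  expect_length(sets, cfg$n_pathways)
  expect_true(all(lengths(sets) >= cfg$pathway_size_range[1] &
                    lengths(sets) <= cfg$pathway_size_range[2]))
  # every causal interaction SNP lies within 50 kb of >= 1 gene of >= 1
  # enriched pathway
  mg <- map_snps_to_genes(g$snp_info, genes, 50000)
  enriched_genes <- unique(unlist(sets[truth$enriched_pathways]))
  for (snp in truth$causal_interaction_snps$id)
    expect_true(any(mg$gene[mg$snp == snp] %in% enriched_genes),
                info = snp)
  # enriched sets: >= 70% signal-gene membership
  for (nm in truth$enriched_pathways)
    expect_gte(mean(sets[[nm]] %in% truth$signal_genes), 0.7)
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(lapply(unclass(back), sort), lapply(unclass(sets), sort))
})

test_that("expression: integer counts, cell types, planted modules", {
  cfg <- tiny_cfg()
  g <- simulate_genotypes(cfg)
  truth <- plant_truth(cfg, g, simulate_gene_annotation(cfg))
  ex <- simulate_expression(cfg, truth)
  expect_true(all(ex$counts >= 0))
  expect_true(all(ex$counts == floor(ex$counts)))
  expect_equal(dim(ex$counts), c(cfg$n_cells, cfg$n_genes))
  expect_length(unique(ex$cell_type), cfg$n_cell_types)
  # hub drives its targets within a cell type
  hub <- names(truth$hub_regulators)[1]
  tg <- truth$hub_regulators[[hub]][1]
  rows <- ex$cell_type == ex$cell_type[1]
  expect_gt(cor(ex$counts[rows, hub], ex$counts[rows, tg]), 0.3)
})

test_that("config validation rejects bad values", {
  expect_error(sim_config(frac_mtbi = 0), "frac_mtbi")
  expect_error(sim_config(within_block_r = 1), "within_block_r")
  expect_error(sim_config(maf_range = c(0.6, 0.7)), "maf_range")
  expect_error(sim_config(n_pathways = 5, n_enriched_pathways = 6),
               "n_enriched_pathways")
  expect_error(sim_config(n_genes = 10, pathway_size_range = c(5, 20)),
               "pathway sizes")
})
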
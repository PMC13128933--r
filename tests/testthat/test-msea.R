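# Marker-set enrichment: statistic arithmetic, permutation engine,
# exhaustive oracle, calibration properties.

# small deterministic stats/map/sets world used across tests
msea_world <- function(n_genes = 5, markers_per_gene = 3, seed = 1,
                       pvals = NULL) {
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(n_genes))
  mg <- data.frame(
    snp = sprintf("m%03d", seq_len(n_genes * markers_per_gene)),
    gene = rep(genes, each = markers_per_gene))
  stats <- data.frame(id = mg$snp,
                      pos = seq_len(nrow(mg)) * 1000,
                      p_int = pvals %||% runif(nrow(mg)))
  list(genes = genes, mgmap = mg, stats = stats)
}

test_that("statistic: zero at O = E, direct arithmetic, self-universe", {
  # O_q = E_q at every quantile -> S = 0: uniform grid hits this exactly
  allp <- (1:100) / 100
  expect_equal(msea_statistic(allp, allp, quantiles = c(0.5, 0.25, 0.1)),
               0, tolerance = 1e-10)
  # single quantile, O = 9, E = 4, kappa = 1 -> 5 / sqrt(5)
  set_p <- c(rep(0.001, 9), rep(0.9, 31))   # 40 markers, 9 below t
  all_p <- (1:400) / 400                    # 0.1-quantile ~ 0.1
  s <- msea_statistic(set_p, all_p, quantiles = 0.1)
  expect_equal(s, (9 - 4) / sqrt(5), tolerance = 1e-6)
  # set = all markers -> S ~ 0 up to quantile discreteness
  expect_lt(abs(msea_statistic(allp, allp)), 0.2)
  expect_error(msea_statistic(numeric(), allp), "empty")
  expect_error(msea_statistic(allp, allp, quantiles = c(0, 0.5)),
               "strictly inside")
})

test_that("monotonicity: smaller best-marker p never decreases S", {
  set.seed(3)
  all_p <- runif(500)
  set_p <- sort(sample(all_p, 30))
  s0 <- msea_statistic(set_p, all_p)
  for (k in c(1, 10, 25)) {
    better <- set_p
    better[k] <- better[k] / 10
    expect_gte(msea_statistic(better, all_p) + 1e-12, s0)
  }
})

test_that("permutation p matches exhaustive enumeration on 5 genes", {
  w <- msea_world(n_genes = 5, markers_per_gene = 4, seed = 11)
  sets <- gene_set_collection(list(A = w$genes[1:2]))
  res <- msea_run(w$stats, w$mgmap, sets, n_perm = 4000, seed = 2,
                  min_genes = 1, max_genes = 10, min_exceed = 1e9)
  # oracle: enumerate all C(5,2) = 10 gene pairs
  pv <- setNames(w$stats$p_int, w$stats$id)
  allm <- sort(unique(w$mgmap$snp))
  s_of <- function(gs) {
    mk <- unique(w$mgmap$snp[w$mgmap$gene %in% gs])
    msea_statistic(pv[mk], pv[allm])
  }
  s_obs <- s_of(w$genes[1:2])
  expect_equal(res$statistic, s_obs, tolerance = 1e-10)
  combos <- combn(w$genes, 2)
  s_null <- apply(combos, 2, s_of)
  p_exact <- mean(s_null >= s_obs - 1e-12)
  # empirical p converges to the enumeration value; allow 3 MC SE + 1/n
  tol <- 3 * sqrt(p_exact * (1 - p_exact) / res$n_perm_used) +
    1 / res$n_perm_used
  expect_lt(abs(res$p - p_exact), max(tol, 0.02))
})

test_that("msea_run: size bounds, FDR ordering, top-gene report", {
  set.seed(21)
  w <- msea_world(n_genes = 40, markers_per_gene = 3, seed = 21)
  # plant one strong set: genes G01-G10 get tiny p on their markers
  strong <- w$mgmap$gene %in% sprintf("G%02d", 1:10)
  w$stats$p_int[strong] <- w$stats$p_int[strong] / 5000
  sets <- gene_set_collection(list(
    hot = sprintf("G%02d", 1:10),
    cold = sprintf("G%02d", 21:30),
    too_small = "G35"))
  res <- msea_run(w$stats, w$mgmap, sets, n_perm = 500, seed = 3,
                  min_genes = 2, max_genes = 100)
  expect_setequal_chr(res$set, c("hot", "cold"))  # singleton excluded
  expect_true(all(diff(res$fdr) >= 0))
  expect_true(all(res$fdr >= res$p))
  expect_lt(res$p[res$set == "hot"], 0.02)
  top <- strsplit(res$top_genes[res$set == "hot"], ";")[[1]]
  expect_true(all(top %in% sprintf("G%02d", 1:10)))
  expect_error(msea_run(w$stats, w$mgmap, sets, n_perm = 50), "at least 100")
})

test_that("null mean of S is near zero and relabeling leaves p stable", {
  w <- msea_world(n_genes = 60, markers_per_gene = 4, seed = 31)
  s_null <- gxepath:::msea_null_stats(w$stats, w$mgmap, ng = 10,
                                      n = 2000, seed = 5)
  expect_gt(mean(s_null), -0.1)
  expect_lt(mean(s_null), 0.1)
  # permuting marker p-values outside the tested set leaves the observed
  # statistic untouched and p within Monte-Carlo error
  sets <- gene_set_collection(list(A = w$genes[1:12]))
  r1 <- msea_run(w$stats, w$mgmap, sets, n_perm = 800, seed = 7,
                 min_genes = 2)
  w2 <- w
  outside <- !w$mgmap$gene %in% w$genes[1:12]
  perm <- sample(which(outside))
  w2$stats$p_int[which(outside)] <- w$stats$p_int[perm]
  r2 <- msea_run(w2$stats, w2$mgmap, sets, n_perm = 800, seed = 7,
                 min_genes = 2)
  expect_lt(abs(r1$p - r2$p), 0.12)
})

test_that("summarize_top_snps ranks by p with stated tie-breaks", {
  w <- msea_world(n_genes = 4, markers_per_gene = 1, seed = 41,
                  pvals = c(1e-4, 1e-2, 0.5, 0.5))
  sets <- gene_set_collection(list(A = w$genes))
  tab <- data.frame(set = "A")
  top <- summarize_top_snps(tab, w$stats, w$mgmap, sets, k = 2)
  expect_equal(top$snp, c("m001", "m002"))
  expect_equal(top$neg_log10_p[1], 4)
  # k larger than available -> everything, ties broken by position
  top4 <- summarize_top_snps(tab, w$stats, w$mgmap, sets, k = 99)
  expect_equal(nrow(top4), 4)
  expect_equal(top4$snp[3:4], c("m003", "m004"))  # equal p: lower pos first
})
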
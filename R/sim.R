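# Synthetic study generator with planted truth.
#
# Emulates the statistical structure of a pediatric injury cohort G x E
# study: hard-call dosage genotypes in LD blocks, an unbalanced binary
# injury indicator, a continuous cognition-like phenotype driven by
# covariates + additive SNP effects + SNP-by-injury effects + noise,
# gene sets with planted enriched membership, and a cells x genes count
# matrix with discrete cell types and planted hub-regulator modules.

#' Simulation configuration
#'
#' Defaults encode the emulated study: 1522 children of whom ~22.5%
#' carry a mild TBI (the rest are orthopedic-injury controls), a
#' genome of LD-blocked common SNPs, a 1000-gene universe with 200
#' pathways of which 20 are planted as enriched, and a brain-like
#' single-cell count matrix with hub-driven co-expression modules.
#'
#' @param n_samples,n_snps cohort and marker counts.
#' @param ld_block_size SNPs per LD block (1 = independent SNPs).
#' @param within_block_r target pairwise dosage correlation within a
#'   block, in \[0,1).
#' @param maf_range minor-allele-frequency range, fractions in (0,0.5].
#' @param frac_mtbi fraction of injured (mTBI) samples, in (0,1).
#' @param n_genes,n_pathways,pathway_size_range,n_enriched_pathways
#'   gene-universe and gene-set layout.
#' @param gxe_effect_size per-SNP interaction effect, phenotype units
#'   per alternate-allele dosage.
#' @param additive_effect_size per-SNP main effect, same units.
#' @param noise_sd residual phenotype standard deviation.
#' @param n_cells,n_cell_types,n_hub_modules,module_size single-cell
#'   matrix layout.
#' @param seed master seed; every generator derives its own child seed
#'   from it, so a fixed seed yields byte-identical outputs.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1522, n_snps = 5000,
                       ld_block_size = 10, within_block_r = 0.8,
                       maf_range = c(0.05, 0.5), frac_mtbi = 342 / 1522,
                       n_genes = 1000, n_pathways = 200,
                       pathway_size_range = c(10, 50),
                       n_enriched_pathways = 20,
                       gxe_effect_size = 0.4,
                       additive_effect_size = 0.15, noise_sd = 1,
                       n_cells = 2000, n_cell_types = 3,
                       n_hub_modules = 5, module_size = 20, seed = 1) {
  cfg <- list(n_samples = assert_count(n_samples, "n_samples"),
              n_snps = assert_count(n_snps, "n_snps"),
              ld_block_size = assert_count(ld_block_size, "ld_block_size"),
              within_block_r = within_block_r,
              maf_range = maf_range, frac_mtbi = frac_mtbi,
              n_genes = assert_count(n_genes, "n_genes"),
              n_pathways = assert_count(n_pathways, "n_pathways"),
              pathway_size_range = pathway_size_range,
              n_enriched_pathways = assert_count(n_enriched_pathways,
                                                 "n_enriched_pathways",
                                                 min = 0L),
              gxe_effect_size = gxe_effect_size,
              additive_effect_size = additive_effect_size,
              noise_sd = noise_sd,
              n_cells = assert_count(n_cells, "n_cells"),
              n_cell_types = assert_count(n_cell_types, "n_cell_types"),
              n_hub_modules = assert_count(n_hub_modules, "n_hub_modules",
                                           min = 0L),
              module_size = assert_count(module_size, "module_size"),
              seed = assert_count(seed, "seed", min = 0L))
  assert_fraction(within_block_r, "within_block_r", 0, 1, open_hi = TRUE)
  assert_fraction(frac_mtbi, "frac_mtbi", 0, 1, open_lo = TRUE,
                  open_hi = TRUE)
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop_gx("maf_range must be an increasing pair in (0,0.5]")
  if (length(pathway_size_range) != 2 ||
      pathway_size_range[1] > pathway_size_range[2] ||
      pathway_size_range[1] < 1)
    stop_gx("pathway_size_range must be an increasing pair of counts")
  if (pathway_size_range[2] > n_genes)
    stop_gx("pathway sizes cannot exceed n_genes")
  if (cfg$n_enriched_pathways > cfg$n_pathways)
    stop_gx("n_enriched_pathways cannot exceed n_pathways")
  if (cfg$noise_sd < 0) stop_gx("noise_sd must be >= 0")
  if (cfg$n_hub_modules * cfg$module_size > cfg$n_genes)
    stop_gx("hub modules cannot cover more than n_genes genes")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic genome layout shared by the genotype and gene
# generators: SNPs every 10 kb on up to 4 chromosomes.
SNP_SPACING <- 10000L
GENE_WIDTH <- 20000L

sim_layout <- function(cfg) {
  n_chrom <- if (cfg$n_snps >= 400) 4L else 1L
  per <- diff(round(seq(0, cfg$n_snps, length.out = n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(n_chrom)), times = per)
  pos <- unlist(lapply(per, function(k) SNP_SPACING * seq_len(k)),
                use.names = FALSE)
  list(n_chrom = n_chrom, chrom = chrom, pos = pos, per_chrom = per)
}

#' Simulate hard-call dosage genotypes in LD blocks
#'
#' LD is generated by haplotype copying: each haplotype draws one
#' latent uniform per block, and every SNP on that haplotype either
#' copies the block latent (probability `sqrt(within_block_r)`) or
#' draws its own, the allele being the latent thresholded at the SNP's
#' MAF. Two SNPs then share the latent with probability
#' `within_block_r`, giving pairwise dosage correlation equal to
#' `within_block_r` times the comonotone attainability bound (exactly
#' `within_block_r` for equal MAFs; somewhat less when MAFs differ,
#' as in real data where rare alleles cannot be strongly correlated
#' with common ones). Dosages are 0/1/2 hard calls.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] with positions spaced every 10 kb.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lay <- sim_layout(cfg)
  with_seed(child_seed(cfg$seed, "genotypes"), {
    n <- cfg$n_samples
    p <- cfg$n_snps
    maf <- runif(p, cfg$maf_range[1], cfg$maf_range[2])
    # block id: consecutive SNPs within a chromosome
    block <- unlist(lapply(lay$per_chrom, function(k) {
      rep(seq_len(ceiling(k / cfg$ld_block_size)),
          each = cfg$ld_block_size, length.out = k)
    }), use.names = FALSE)
    block <- cumsum(c(TRUE, diff(block) != 0) |
                      c(TRUE, lay$chrom[-1] != lay$chrom[-p]))
    w <- sqrt(cfg$within_block_r)   # per-SNP latent-copy probability
    dosage <- matrix(0L, n, p)
    for (b in unique(block)) {
      idx <- which(block == b)
      m <- length(idx)
      mafm <- matrix(maf[idx], n, m, byrow = TRUE)
      h <- matrix(0L, n, m)
      for (copy in 1:2) {
        latent <- matrix(runif(n), n, m)
        own <- matrix(runif(n * m), n, m)
        u <- ifelse(matrix(runif(n * m), n, m) < w, latent, own)
        h <- h + (u < mafm)
      }
      dosage[, idx] <- h
    }
    alleles <- matrix(c("A", "G", "T", "C", "A", "C", "T", "G"),
                      ncol = 2, byrow = TRUE)
    ai <- ((seq_len(p) - 1) %% 4) + 1
    info <- data.frame(id = sprintf("rs%06d", seq_len(p)),
                       chrom = lay$chrom, pos = lay$pos,
                       ref = alleles[ai, 1], alt = alleles[ai, 2],
                       stringsAsFactors = FALSE)
    g <- genotype_matrix(dosage, info)
    rownames(g$dosage) <- sprintf("S%04d", seq_len(n))
    g
  })
}

#' Simulate non-overlapping gene spans (BED convention)
#'
#' Genes are tiled deterministically over the same chromosomes as the
#' SNPs so every gene has mappable markers within the 50-kb window.
#'
#' @param cfg a [sim_config()].
#' @return a [gene_map()] (0-based, half-open spans).
#' @export
simulate_gene_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lay <- sim_layout(cfg)
  per_gene <- diff(round(seq(0, cfg$n_genes, length.out = lay$n_chrom + 1)))
  rows <- do.call(rbind, lapply(seq_len(lay$n_chrom), function(ci) {
    k <- per_gene[ci]
    if (k == 0) return(NULL)
    span <- lay$per_chrom[ci] * SNP_SPACING
    pitch <- max(GENE_WIDTH + SNP_SPACING, floor(span / k))
    width <- min(GENE_WIDTH, pitch - 1)
    start <- (seq_len(k) - 1) * pitch + SNP_SPACING %/% 2
    data.frame(chrom = paste0("chr", ci), start = start,
               end = start + width)
  }))
  gene_map(symbol = sprintf("GENE%04d", seq_len(nrow(rows))),
           chrom = rows$chrom, start = rows$start, end = rows$end)
}

#' Plant the ground truth of a synthetic study
#'
#' Chooses a pool of "signal" genes, assigns one causal interaction SNP
#' within 50 kb of each, samples causal additive SNPs, designates which
#' pathways are enriched, and fixes the hub-regulator modules that the
#' expression generator will realise. Every causal interaction SNP lies
#' within 50 kb of at least one gene of at least one enriched pathway.
#'
#' @param cfg a [sim_config()].
#' @param geno genotypes from [simulate_genotypes()].
#' @param genes gene spans from [simulate_gene_annotation()].
#' @return a list of class `planted_truth`.
#' @export
plant_truth <- function(cfg, geno, genes) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(child_seed(cfg$seed, "truth"), {
    # Small candidate pool of signal genes: each signal gene carries a
    # causal interaction SNP (its nearest marker), so the pool size
    # bounds the number of causal G x E SNPs and keeps the per-SNP
    # interaction variance share in the 0.5-2% band (many causal SNPs
    # would dilute each other). Enriched-set signal membership is
    # fixed HERE so that, by construction, every causal SNP lies
    # within 50 kb of a gene of at least one enriched pathway.
    pw_names <- sprintf("PW%04d", seq_len(cfg$n_pathways))
    enriched <- if (cfg$n_enriched_pathways > 0)
      sort(sample(pw_names, cfg$n_enriched_pathways)) else character()
    lo <- cfg$pathway_size_range[1]; hi <- cfg$pathway_size_range[2]
    pool_size <- min(cfg$n_genes,
                     max(ceiling(0.04 * cfg$n_genes),
                         ceiling(0.8 * hi) + 5L))
    pool <- sort(sample(genes$symbol, pool_size))
    enriched_sizes <- setNames(sample(lo:hi, length(enriched),
                                      replace = TRUE), enriched)
    enriched_members <- list()
    for (nm in enriched) {
      k_sig <- ceiling(0.8 * enriched_sizes[[nm]])
      if (k_sig > pool_size)
        stop_gx("infeasible planting: %d signal genes needed, %d exist",
                k_sig, pool_size)
      enriched_members[[nm]] <- sample(pool, k_sig)
    }
    signal_genes <- sort(unique(unlist(enriched_members,
                                       use.names = FALSE)))
    # nearest SNP to each signal gene midpoint (same chromosome);
    # nearby genes may share a causal SNP (pleiotropy), so only the
    # SNP list is deduplicated
    causal_int <- character()
    if (length(signal_genes) > 0) {
      gsub <- genes[match(signal_genes, genes$symbol), ]
      mid <- (gsub$start + gsub$end) / 2
      causal_int <- vapply(seq_len(nrow(gsub)), function(i) {
        on_chr <- which(geno$snp_info$chrom == gsub$chrom[i])
        j <- on_chr[which.min(abs(geno$snp_info$pos[on_chr] - mid[i]))]
        geno$snp_info$id[j]
      }, character(1))
      causal_int <- sort(unique(causal_int))
    }
    n_add <- max(10L, ceiling(0.01 * cfg$n_snps))
    causal_add <- sort(sample(geno$snp_info$id, n_add))
    # hub modules: disjoint gene blocks, same modules in every cell type
    hubs <- list()
    if (cfg$n_hub_modules > 0) {
      hub_pool <- sample(genes$symbol[seq_len(min(cfg$n_genes,
                                                  nrow(genes)))])
      for (m in seq_len(cfg$n_hub_modules)) {
        mem <- hub_pool[((m - 1) * cfg$module_size + 1):
                          (m * cfg$module_size)]
        hubs[[mem[1]]] <- mem[-1]
      }
    }
    structure(list(
      causal_interaction_snps = data.frame(
        id = causal_int,
        beta = cfg$gxe_effect_size *
          sample(c(-1, 1), length(causal_int), replace = TRUE),
        stringsAsFactors = FALSE),
      causal_additive_snps = data.frame(
        id = causal_add,
        beta = cfg$additive_effect_size *
          sample(c(-1, 1), length(causal_add), replace = TRUE),
        stringsAsFactors = FALSE),
      enriched_pathways = enriched,
      enriched_sizes = enriched_sizes,
      enriched_members = enriched_members,
      signal_genes = signal_genes,
      hub_regulators = hubs), class = "planted_truth")
  })
}

#' Simulate the cohort table and phenotype
#'
#' Injury is Bernoulli(`frac_mtbi`); age (months), sex (M = 1) and a
#' 5-level ethnicity are drawn independently of genotype. Genetic PCs
#' are the top-20 principal-component scores of the centered dosage
#' matrix (standard-normal placeholders when `n_snps < 100`; the
#' `pc_source` attribute records which). The phenotype is
#' `covariate effects + sum(beta_a X) + sum(beta_gi X IG) + N(0, noise_sd^2)`.
#'
#' @param cfg a [sim_config()].
#' @param geno genotypes generated from `cfg`.
#' @param truth a [plant_truth()] result.
#' @return a cohort data.frame with attribute `pc_source`.
#' @export
simulate_cohort <- function(cfg, geno, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(geno$dosage) != cfg$n_samples)
    stop_gx("genotypes have %d samples but cfg says %d",
            nrow(geno$dosage), cfg$n_samples)
  with_seed(child_seed(cfg$seed, "cohort"), {
    n <- cfg$n_samples
    ig <- rbinom(n, 1, cfg$frac_mtbi)
    age <- round(runif(n, 108, 131))           # 9-10 year olds, in months
    sex <- rbinom(n, 1, 0.5)
    eth <- sample(c("White", "Black", "Hispanic", "Asian", "Other"),
                  n, replace = TRUE,
                  prob = c(0.52, 0.15, 0.20, 0.02, 0.11))
    if (cfg$n_snps >= 100) {
      x <- scale(geno$dosage, center = TRUE, scale = FALSE)
      ev <- eigen(tcrossprod(x) / ncol(x), symmetric = TRUE)
      pcs <- ev$vectors[, 1:20, drop = FALSE]
      pcs <- scale(pcs)                        # unit-variance scores
      pc_source <- "genotype_svd"
    } else {
      pcs <- matrix(rnorm(n * 20), n, 20)
      pc_source <- "normal_placeholder"
    }
    colnames(pcs) <- paste0("PC", 1:20)
    # fixed covariate effects on the phenotype (standardised scale)
    z_age <- as.numeric(scale(age))
    pheno <- 0.3 * z_age + 0.2 * sex - 0.1 * ig +
      0.1 * pcs[, 1] - 0.1 * pcs[, 2]
    add <- truth$causal_additive_snps
    if (nrow(add) > 0) {
      xa <- geno$dosage[, match(add$id, geno$snp_info$id), drop = FALSE]
      xa[is.na(xa)] <- 0
      pheno <- pheno + drop(xa %*% add$beta)
    }
    gxe <- truth$causal_interaction_snps
    if (nrow(gxe) > 0) {
      xi <- geno$dosage[, match(gxe$id, geno$snp_info$id), drop = FALSE]
      xi[is.na(xi)] <- 0
      pheno <- pheno + ig * drop(xi %*% gxe$beta)
    }
    if (cfg$noise_sd > 0) pheno <- pheno + rnorm(n, 0, cfg$noise_sd)
    cohort <- data.frame(sample_id = rownames(geno$dosage),
                         phenotype = pheno, injury = ig, age = age,
                         sex = sex, ethnicity = eth,
                         stringsAsFactors = FALSE)
    cohort <- cbind(cohort, as.data.frame(pcs))
    attr(cohort, "pc_source") <- pc_source
    as_cohort_table(cohort)
  })
}

#' Simulate gene sets with planted enriched membership
#'
#' Null sets are sampled uniformly from the gene universe; each planted
#' enriched set draws at least 70% (by construction, 80%) of its
#' members from the signal-gene pool, i.e. genes within 50 kb of a
#' causal interaction SNP.
#'
#' @param cfg a [sim_config()].
#' @param genes gene spans from [simulate_gene_annotation()].
#' @param truth a [plant_truth()] result.
#' @return a [gene_set_collection()].
#' @export
simulate_gene_sets <- function(cfg, genes, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(child_seed(cfg$seed, "gene_sets"), {
    pw_names <- sprintf("PW%04d", seq_len(cfg$n_pathways))
    lo <- cfg$pathway_size_range[1]
    hi <- cfg$pathway_size_range[2]
    sizes <- sample(lo:hi, cfg$n_pathways, replace = TRUE)
    other <- setdiff(genes$symbol, truth$signal_genes)
    sets <- vector("list", cfg$n_pathways)
    names(sets) <- pw_names
    for (i in seq_len(cfg$n_pathways)) {
      if (pw_names[i] %in% truth$enriched_pathways) {
        # signal membership was fixed in plant_truth; top up with
        # non-signal filler genes to the drawn size
        core <- truth$enriched_members[[pw_names[i]]]
        sz <- truth$enriched_sizes[[pw_names[i]]]
        sets[[i]] <- c(core, sample(other, sz - length(core)))
      } else {
        sets[[i]] <- sample(genes$symbol, sizes[i])
      }
    }
    gene_set_collection(sets, description = setNames(
      ifelse(pw_names %in% truth$enriched_pathways, "planted_enriched",
             "null"), pw_names))
  })
}

#' Simulate a single-cell count matrix with hub-driven modules
#'
#' Cells are split over `n_cell_types` types with distinct mean
#' profiles (each type up-regulates its own marker genes). Within every
#' cell type, each planted hub regulator carries a per-cell latent
#' activity; its module targets have negative-binomial counts whose
#' mean is linear in the hub's realised expression, so the network
#' stage has recoverable edges. Non-module genes are independent given
#' cell type.
#'
#' @param cfg a [sim_config()].
#' @param truth a [plant_truth()] result (supplies the hub modules).
#' @return an [expression_matrix()] with cell-type labels.
#' @export
simulate_expression <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_hub_modules * cfg$module_size > cfg$n_genes)
    stop_gx("modules exceed gene universe")
  with_seed(child_seed(cfg$seed, "expression"), {
    g <- cfg$n_genes
    genes <- sprintf("GENE%04d", seq_len(g))
    types <- c("excitatory", "inhibitory", "oligodendrocyte",
               "astrocyte", "microglia")
    types <- if (cfg$n_cell_types <= 5) types[seq_len(cfg$n_cell_types)]
             else paste0("CT", seq_len(cfg$n_cell_types))
    cell_type <- sort(rep_len(types, cfg$n_cells))
    base_mu <- exp(rnorm(g, log(0.5), 1))
    names(base_mu) <- genes
    module_genes <- unlist(c(names(truth$hub_regulators),
                             truth$hub_regulators), use.names = FALSE)
    module_genes <- intersect(module_genes, genes)
    # distinct marker genes per type, disjoint from module genes
    free <- setdiff(genes, module_genes)
    n_marker <- max(5L, ceiling(0.05 * g))
    markers <- split(head(free, n_marker * length(types)),
                     rep(types, each = n_marker,
                         length.out = min(length(free),
                                          n_marker * length(types))))
    counts <- matrix(0L, cfg$n_cells, g, dimnames = list(NULL, genes))
    for (ty in types) {
      rows <- which(cell_type == ty)
      nc <- length(rows)
      mu <- matrix(base_mu, nc, g, byrow = TRUE)
      mk <- markers[[ty]]
      if (length(mk)) mu[, match(mk, genes)] <-
          mu[, match(mk, genes), drop = FALSE] * 8
      cnt <- matrix(rnbinom(nc * g, mu = mu, size = 5), nc, g)
      for (hub in names(truth$hub_regulators)) {
        if (!hub %in% genes) next
        act <- rgamma(nc, shape = 2, scale = 1)
        hub_cnt <- rnbinom(nc, mu = 2 * act, size = 10)
        cnt[, match(hub, genes)] <- hub_cnt
        tg <- intersect(truth$hub_regulators[[hub]], genes)
        for (t1 in tg) {
          cnt[, match(t1, genes)] <-
            rnbinom(nc, mu = 0.2 + 0.6 * hub_cnt, size = 10)
        }
      }
      counts[rows, ] <- cnt
    }
    rownames(counts) <- sprintf("CELL%05d", seq_len(cfg$n_cells))
    expression_matrix(counts, cell_type)
  })
}

#' Generate a complete synthetic study
#'
#' Runs all five generators in dependency order under the master seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes`, `genes`, `truth`, `cohort`,
#'   `gene_sets`, `expression`.
#' @export
simulate_study <- function(cfg) {
  geno <- simulate_genotypes(cfg)
  genes <- simulate_gene_annotation(cfg)
  truth <- plant_truth(cfg, geno, genes)
  list(genotypes = geno, genes = genes, truth = truth,
       cohort = simulate_cohort(cfg, geno, truth),
       gene_sets = simulate_gene_sets(cfg, genes, truth),
       expression = simulate_expression(cfg, truth))
}
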
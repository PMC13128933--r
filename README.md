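# gxepath

Gene-by-injury interaction GWAS, pathway enrichment, network key
drivers, and pathway polygenic risk scores — an omnigenic
systems-genetics toolchain for a continuous phenotype measured in an
injured cohort.

## Who this is for

Statistical geneticists and systems biologists who want to ask, end to
end: *which SNPs change their effect on a quantitative outcome in the
presence of an environmental exposure (here: mild traumatic brain
injury vs an orthopedic-injury control group), which biological
pathways carry that signal, which network hub genes plausibly drive
those pathways in specific brain cell types, and does condensing the
signal into a polygenic score improve outcome prediction?* The package
implements every stage against plain-text standard formats (VCF /
dosage TSV, TSV cohort tables, BED, GMT, MTX, edge-list TSV) and ships
a synthetic-data generator with planted ground truth so that every
stage has calibration and recovery tests.

## The models in brief

Per SNP with dosage `X`, injury indicator `IG` (mTBI = 1, control = 0):

    additive:     y ~ b_a X            + sum_k g_k PC_k + b_age Age + b_sex Sex + b_IG IG + e
    interaction:  y ~ b_i X + b_gi IG.X + sum_k g_k PC_k + b_age Age + b_sex Sex + b_IG IG + e

QC uses the genomic-control inflation factor
`lambda_GC = median(qchisq(1 - p, 1)) / 0.4549` (≈1 for a calibrated
scan). Pathways are scored by marker-set enrichment analysis (MSEA)
with the chi-like statistic `S = sum_q (O_q - E_q) / sqrt(E_q + 1)`
over p-value quantile thresholds and a gene-level permutation null;
key drivers by the same standardized excess count
`Z = (O - E)/sqrt(E + 1)` on network neighborhoods against permuted
node labels; both families are BH-corrected. Pathway PRS:

    PRS_add = sum_{a in A} b_a^add X_a
    PRS_int = sum_{a in A\I} b_a^add X_a + sum_{i in I} (b_i^int X_i + IG b_gi^int X_i)

compared through null / additive / interaction linear models (LRT for
nested pairs, AIC with the ≥10-point convention for the non-nested
pair, stratified 5-fold cross-validation).

## Worked example

Simulate a full study at its default scale (1522 children, 5000 SNPs
in LD blocks, 200 pathways of which 20 are enriched through planted
SNP-by-injury effects), run the genetic arm, and compare PRS models:

```r
library(gxepath)

cfg <- sim_config(seed = 31)
st  <- simulate_study(cfg)

geno <- maf_filter(st$genotypes)               # MAF >= 0.05
add  <- fit_additive_gwas(geno, st$cohort)
int  <- fit_interaction_gwas(geno, st$cohort)

keep <- marker_dependency_filter(geno, int, r2_max = 0.5)
mg   <- map_snps_to_genes(geno$snp_info[geno$snp_info$id %in% keep, ],
                          st$genes, window_bp = 50000)
en   <- msea_run(int[int$id %in% keep, ], mg, st$gene_sets,
                 n_perm = 1000, seed = 5)

sel_int <- select_pathway_snps(en, mg, st$gene_sets, int, top_k = 20)
sel_add <- select_pathway_snps(en, mg, st$gene_sets, add, top_k = 20)
sel_int <- injury_specific_filter(sel_int, geno, st$cohort)

prs_a <- compute_prs(sel_add, geno, st$cohort, "additive")
prs_i <- compute_prs(list(A = sel_add, I = sel_int), geno, st$cohort,
                     "interaction")
fit_phenotype_models(prs_a, prs_i, st$cohort)
```

which prints (this exact run):

```
<model_report>
        model  r_squared   log_lik      aic
1        null 0.07512203 -2682.127 5382.255
2    additive 0.19420376 -2577.238 5174.476
3 interaction 0.32856001 -2438.427 4896.854
           comparison statistic df             p
1    null_vs_additive  209.7786  1  1.535188e-47
2 null_vs_interaction  487.4010  1 5.240067e-108
AIC(additive) - AIC(interaction) = 277.62 (>=10 rule: TRUE)
```

Read: covariates alone explain 7.5% of phenotype variance; adding the
additive pathway PRS lifts R² to 0.194; modelling the injury-dependent
part of the signal through the interaction PRS lifts it to 0.329, a
clearly significant improvement under the ≥10-point AIC convention —
the expected ordering when SNP-by-injury effects are truly present.
The planted enrichment is likewise recovered: of the sets declared by
MSEA at FDR ≤ 0.05 in this run, all but at most one are planted ones.

The single-cell arm runs analogously: `build_pseudocells()` →
`infer_grn()` (bootstrapped gradient boosting, consensus at bootstrap
frequency ≥ 0.5) → `kda_run()` on the enriched pathways →
`extract_kd_subnetwork()`.

A command-line wrapper covering every stage lives in
`inst/cli/gxepath` (subcommands `simulate`, `gwas`, `mdf`, `map`,
`msea`, `grn`, `kda`, `run`, `report`), and `run_pipeline()` executes
the whole chain with a checksummed, resumable manifest.

## Method documentation

`vignettes/gxepath-methods.Rmd` describes the models and their
assumptions, every tunable default and why it has its value, what the
synthetic generator does and does not emulate (and hence what a green
test establishes), and the numerical conventions (tie-breaks,
coordinate systems, degenerate-input behavior).
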
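---
title: "Methods: gene-by-injury GWAS, pathway enrichment, network key drivers, and pathway PRS"
author: "gxepath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-by-injury GWAS, pathway enrichment, network key drivers, and pathway PRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`gxepath` implements an omnigenic gene-by-environment analysis for a
continuous neurocognitive phenotype in an injured pediatric cohort,
where the environment is a binary injury indicator `IG` (mild traumatic
brain injury = 1, orthopedic-injury control = 0). The chain is:

1. per-SNP additive and SNP-by-injury interaction regression,
2. LD-based marker dependency filtering and 50-kb SNP-to-gene mapping,
3. marker-set enrichment analysis (MSEA) of the full summary-statistic
   distribution against gene sets, with a gene-level permutation null,
4. cell-type gene regulatory network (GRN) inference from single-cell
   counts (pseudocells, bootstrapped gradient boosting, consensus),
5. key-driver analysis (KDA) of network hub neighborhoods, and
6. pathway-based additive and interaction polygenic risk scores (PRS)
   with null / additive / interaction model comparison.

The regression models are, per SNP with dosage $X$:

$$y \sim \beta_a X + \sum_{k=1}^{20}\gamma_k PC_k + \beta_{age} Age +
  \beta_{sex} Sex + \beta_{IG} IG + e \quad\text{(additive)}$$

$$y \sim \beta_i X + \beta_{gi}\, IG\!\cdot\!X + \sum_k \gamma_k PC_k +
  \beta_{age} Age + \beta_{sex} Sex + \beta_{IG} IG + e
  \quad\text{(interaction)}$$

Ethnicity is deliberately absent from the GWAS covariates and present
(dummy-coded, largest category as reference) in the PRS prediction
models; the two conventions are kept distinct on purpose. Fits are OLS
on per-SNP complete cases with t-distribution p-values (exact under
normal errors at modest n). Covariates are projected out once by QR and
each SNP is then a scalar (or 2-by-2) solve, which is algebraically the
full fit. The PRS formulas are

$$PRS_{add} = \sum_{a \in A} \beta_a^{add} X_a, \qquad
  PRS_{int} = \sum_{a \in A\setminus I} \beta_a^{add} X_a +
  \sum_{i \in I} \left(\beta_i^{int} X_i + IG\,\beta_{gi}^{int} X_i\right)$$

with $A$ the SNPs selected from the additive scan and $I$ from the
interaction scan (top 20 per enriched pathway by the relevant p-value,
deduplicated; by default further reduced to the injury-specific subset,
i.e. SNPs associated within the injured group at BH FDR $\le 0.05$ but
not within the controls, with a flag to use the unfiltered union).

# The chi-like enrichment statistic

MSEA scores a gene set's markers against quantile thresholds
$q \in \{0.5, 0.25, 0.1, 0.05, 0.01\}$ of all mapped marker p-values:

$$S = \sum_q \frac{O_q - E_q}{\sqrt{E_q + \kappa}},\qquad
  E_q = n_{set}\,q,\ \kappa = 1.$$

Markers shared by several genes of a set count once. The null draws,
per permutation, a random gene set with the same mapped-gene count from
the mapped-gene universe, each gene carrying its complete marker block
— this preserves LD and marker-count structure that SNP-level
permutation would destroy. Permutation is adaptive (stop at 50 null
exceedances, cap 10,000 by default) and the empirical p is
$(1 + \#\{S_0 \ge S\})/(1 + n_{done})$; BH correction is applied once
across every set tested in a run. KDA reuses the same standardized
excess-count score on hub neighborhoods,
$Z = (O - E)/\sqrt{E + \kappa}$ with
$E = |N(h)|\,|P \cap V|/|V|$, with node-label permutations drawn
independently per (hub, pathway) pair. With integer overlaps the
add-one permutation p is conservative by construction; the test suite
therefore checks one-sided uniformity (no anti-conservatism).

# Synthetic data: the stated world

The generator emulates the statistical structure of the motivating
study rather than its biology:

* **Cohort**: 1522 children, injury indicator Bernoulli(342/1522),
  age 108–131 months, sex Bernoulli(0.5), a 5-level ethnicity drawn
  independently of genotype, and 20 genetic PCs computed as the
  principal-component scores of the centered dosage matrix (falling
  back to standard-normal placeholder columns below 100 SNPs, recorded
  in the `pc_source` attribute).
* **Genotypes**: 5000 biallelic SNPs every 10 kb on four chromosomes,
  per-SNP MAF uniform on [0.05, 0.5], hard calls. LD is produced by
  latent-uniform haplotype copying: each haplotype draws one uniform
  per block and each SNP copies it with probability
  $\sqrt{r}$, so two SNPs share the latent with probability $r$
  (`within_block_r`, default 0.8) and the realized dosage correlation
  is $r$ times the comonotone bound — exactly $r$ for equal MAFs, less
  when MAFs differ, which mirrors the real constraint that rare
  alleles cannot be strongly correlated with common ones. A two-pool
  haplotype-class construction was tried first and rejected: its
  attainable correlation collapses for MAF below $r/(1+r)$, leaving
  the LD filter nothing to prune.
* **Phenotype**: fixed covariate effects (0.3 per SD of age, 0.2 for
  sex, −0.1 for injury, ±0.1 on the first two PCs) plus additive SNP
  effects, SNP-by-injury effects, and N(0, 1) noise.
* **Planted pathways**: 200 sets of 10–50 genes, 20 enriched. Enriched
  sets draw 80% of members from a small signal-gene pool (4% of the
  universe, floor tied to the largest set size); each signal gene's
  nearest SNP becomes a causal interaction SNP, so by construction
  every causal SNP lies within 50 kb of a gene of an enriched set.
  The per-SNP interaction effect defaults to 0.4 phenotype units per
  dosage: with ~45 causal SNPs this puts each SNP's interaction
  variance share at roughly 0.8–1% of total phenotype variance, inside
  the 0.5–2% per-SNP band the design targets — a first draft with
  β = 0.25 and a 12%-of-genes pool landed near 0.3% because the many
  causal SNPs inflate the total variance, and was revised before the
  acceptance thresholds were frozen.
* **Expression**: negative-binomial counts for 2000 cells over
  discrete cell types with distinct marker-gene profiles; within each
  type, each planted hub regulator carries a per-cell Gamma latent
  activity and its module targets have mean $0.2 + 0.6\,\times$ the
  hub's realized count, so module edges are recoverable. The generator
  does not model droplet artifacts, ambient RNA, or batch effects.

One master seed fans out to per-generator child seeds
(`child_seed()`), so a fixed seed reproduces every output
byte-for-byte while any single generator can be re-run alone.

# GRN inference: what is identifiable at desk scale

Cells of one type are normalized (counts-per-10k, log1p), reduced to 30
PCs, joined by a kNN graph, and partitioned by Leiden communities with
the resolution auto-adjusted toward a mean community size of ~20 cells;
pseudocell profiles are community means. For each target gene the top
50 candidates by absolute correlation feed a depth-3, 100-tree
least-squares gradient-boosting ensemble (learning rate 0.1,
implemented in C++; no boosted-tree package exists in the supported
stack). Edges are candidates whose normalized importance exceeds the
uniform share `1/n_candidates`; 100 bootstrap subsamples (80%) are
aggregated and edges kept at bootstrap frequency ≥ 0.5.

Two guards make the importance scores meaningful at ~100 pseudocells:
per-split feature subsampling (`colsample = 1/3`) decorrelates trees,
and boosting is early-stopped on the 20% of pseudocells left out of
each subsample, with a per-target gate requiring held-out
$R^2 \ge 0.3$ before any edge is emitted. Without the gate, the top
in-sample correlations (|r| ≈ 0.3 among 50 preselected candidates at
this sample size) are stable across subsamples and every target —
including targets with no real regulator — retains a dozen spurious
edges; with it, a null (independent-gene) matrix of the same
dimensions yields essentially no consensus edges while planted module
edges are untouched.

What a green recovery test establishes, and what it does not: after
community averaging, a hub and its targets are statistically
near-exchangeable (their independent noise shrinks with community
size while the shared module signal does not), so neither edge
direction nor the hub-vs-target distinction is identifiable from
observational expression. Planted-truth recovery is therefore scored
on unordered hub–target pairs (bootstrap-frequency claim) and on
within-module co-membership (precision claim). Downstream KDA is
degree-based and unaffected by direction.

# Numerical and procedural conventions

* MAF from non-missing dosages, `min(f, 1-f)`; threshold 0.05.
* Marker dependency filtering: within each chromosome, candidates are
  visited by ascending association p (ties: position, then id) and
  kept only if squared dosage correlation with every retained SNP
  inside a 1-Mb window stays below 0.5. This greedy order makes the
  "keep the smaller-p SNP of a redundant pair" rule global and the
  filter idempotent.
* BED coordinates are 0-based half-open on disk; every public distance
  is on 1-based inclusive coordinates, converted in one helper.
* p-value ties anywhere break by genomic position, then id.
* Missing dosages: complete-case per SNP in every GWAS fit; mean
  imputation (2 × alternate-allele frequency) in PRS scoring only.
* A constant PRS (empty selection) degenerates its prediction model to
  the null model (R² equal, LRT p = 1) instead of erroring.
* λ~GC~ = median(qchisq(1−p, 1))/0.4549. The λ of a single scan
  wobbles with the phenotype realisation (per-SNP statistics are
  exchangeable but dependent through the shared noise draw; sd ≈ 0.03
  for an additive 5,000-SNP scan, ≈ 0.08 for the interaction scan), so
  calibration claims are evaluated on means over replicate null
  cohorts, and single-scan KS uniformity tests are avoided by design.
* Cross-study effect-size correlation harmonizes alleles by id, flips
  the sign on ref/alt swaps, and drops strand-ambiguous (A/T, C/G)
  pairs when alleles are available.

# Known limitations

* The synthetic world uses equal-spaced SNPs, rectangular LD blocks,
  and independent ethnicity; it contains no ancestry structure beyond
  what the genotype PCs capture, so confounding-correction claims are
  limited to the simulated design.
* GRN recovery is demonstrated for linear hub→target modules; feedback
  loops, combinatorial regulation, and cross-cell-type edges are out
  of scope.
* The permutation engines (MSEA, KDA) are exact only in the Monte
  Carlo limit; empirical p-values are floored at 1/(n_perm + 1).
* PRS weights are taken from the same cohort used for evaluation, as
  in the motivating design; cross-validation quantifies but does not
  remove that optimism.
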
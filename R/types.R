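# Core containers. Deliberately light S3: data.frames and matrices with
# validated constructors, in the style of GWAS/network tooling where the
# on-disk table is the contract.

#' Construct a genotype matrix
#'
#' Samples x SNPs dosage matrix (values in \[0,2\], `NA` allowed) with
#' per-SNP metadata. Dosages are counts of the alternate allele.
#'
#' @param dosage numeric matrix, samples in rows (rownames = sample ids),
#'   SNPs in columns (colnames = SNP ids).
#' @param snp_info data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; a `maf` column is recomputed from the dosages.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snp_info) {
  stopifnot(is.matrix(dosage), is.data.frame(snp_info))
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(snp_info)))
    stop_gx("snp_info must have columns: %s", paste(need, collapse = ", "))
  if (ncol(dosage) != nrow(snp_info))
    stop_gx("dosage has %d SNPs but snp_info has %d rows",
            ncol(dosage), nrow(snp_info))
  if (anyDuplicated(snp_info$id)) stop_gx("SNP ids must be unique")
  if (any(snp_info$pos <= 0)) stop_gx("positions must be positive (1-based)")
  if (length(dosage) > 0 && sum(!is.na(dosage)) > 0) {
    rng <- range(dosage, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop_gx("dosages must lie in [0,2]")
  }
  colnames(dosage) <- snp_info$id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  snp_info$maf <- compute_maf(dosage)
  structure(list(dosage = dosage, snp_info = snp_info),
            class = "genotype_matrix")
}

#' Minor allele frequency per SNP from dosages
#'
#' `f = mean(dosage)/2` over non-missing samples; MAF = `min(f, 1-f)`.
#'
#' @param dosage samples x SNPs dosage matrix.
#' @return numeric vector of MAFs in \[0, 0.5\].
#' @export
compute_maf <- function(dosage) {
  f <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs, %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$snp_info$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# Subset SNP columns by id, keeping metadata aligned.
geno_subset <- function(geno, ids) {
  keep <- match(ids, geno$snp_info$id)
  if (anyNA(keep)) stop_gx("unknown SNP ids: %s",
                           paste(head(ids[is.na(keep)], 5), collapse = ", "))
  genotype_matrix(geno$dosage[, keep, drop = FALSE],
                  geno$snp_info[keep, , drop = FALSE])
}

#' Validate a cohort table
#'
#' Per-sample phenotype and covariates: `sample_id`, continuous
#' `phenotype`, binary `injury` (1 = mTBI, 0 = orthopedic-injury
#' reference), `age` (months), `sex` (M = 1), 5-level `ethnicity`, and
#' genetic principal-component columns `PC1..PCk`.
#'
#' @param cohort data.frame.
#' @param n_pcs number of PC columns expected (default 20).
#' @return the validated data.frame (invisibly classed `cohort_table`).
#' @export
as_cohort_table <- function(cohort, n_pcs = 20) {
  need <- c("sample_id", "phenotype", "injury", "age", "sex", "ethnicity")
  if (!all(need %in% names(cohort)))
    stop_gx("cohort must have columns: %s", paste(need, collapse = ", "))
  if (anyNA(cohort$phenotype) || anyNA(cohort$injury))
    stop_gx("phenotype and injury must be complete")
  if (!all(cohort$injury %in% c(0, 1)))
    stop_gx("injury must be a 0/1 indicator (1 = mTBI)")
  pcs <- grep("^PC[0-9]+$", names(cohort), value = TRUE)
  if (length(pcs) < n_pcs)
    stop_gx("cohort has %d PC columns, need %d", length(pcs), n_pcs)
  class(cohort) <- unique(c("cohort_table", class(cohort)))
  cohort
}

pc_cols <- function(cohort, n_pcs) paste0("PC", seq_len(n_pcs))

#' Construct a gene map (BED convention)
#'
#' @param symbol,chrom character vectors; `start`,`end` numeric, 0-based
#'   half-open spans with `start < end`.
#' @return data.frame of class `gene_map`, sorted by chrom then start.
#' @export
gene_map <- function(symbol, chrom, start, end) {
  if (anyDuplicated(symbol)) stop_gx("gene symbols must be unique")
  if (any(start >= end)) stop_gx("gene spans require start < end")
  gm <- data.frame(symbol = as.character(symbol),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  gm <- gm[order(gm$chrom, gm$start), , drop = FALSE]
  rownames(gm) <- NULL
  class(gm) <- c("gene_map", "data.frame")
  gm
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene symbols).
#' @param description optional character vector, one per set.
#' @return named list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  stopifnot(is.list(sets))
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_gx("sets must have unique names")
  if (any(lengths(sets) == 0)) stop_gx("sets must be non-empty")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(sets, description = description %||%
              setNames(rep("", length(sets)), names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Construct a single-cell expression matrix container
#'
#' @param counts non-negative integer matrix, cells x genes.
#' @param cell_type character/factor vector, one label per cell.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, cell_type) {
  stopifnot(is.matrix(counts) || methods::is(counts, "Matrix"))
  if (length(cell_type) != nrow(counts))
    stop_gx("cell_type length must equal the number of cells (rows)")
  if (min(counts) < 0) stop_gx("counts must be non-negative")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("G", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("C", seq_len(nrow(counts)))
  structure(list(counts = counts, cell_type = as.character(cell_type),
                 genes = colnames(counts), cells = rownames(counts)),
            class = "expression_matrix")
}

#' Construct a gene regulatory network edge table
#'
#' Directed regulator -> target edges with a non-negative `weight` (mean
#' gradient-boosting feature importance) and a bootstrap `freq` in (0,1].
#'
#' @param edges data.frame with columns `source`, `target`, `weight`,
#'   `freq`.
#' @return data.frame of class `grn`.
#' @export
as_grn <- function(edges) {
  need <- c("source", "target", "weight", "freq")
  if (!all(need %in% names(edges)))
    stop_gx("grn edges need columns: %s", paste(need, collapse = ", "))
  if (any(edges$source == edges$target)) stop_gx("self-loops are not allowed")
  if (any(edges$freq > 1 | edges$freq <= 0)) stop_gx("freq must be in (0,1]")
  if (any(edges$weight < 0)) stop_gx("weights must be >= 0")
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) stop_gx("one record per ordered pair required")
  edges <- edges[order(-edges$freq, -edges$weight, edges$source,
                       edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("grn", "data.frame")
  edges
}
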
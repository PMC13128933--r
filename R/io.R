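# Readers/writers for every on-disk format the pipeline touches.
# All tables are tab-separated; metadata lines are '#'-prefixed so the
# files stay parseable by generic TSV tooling.

meta_header <- function(extra = character()) {
  c(sprintf("# gxepath %s", as.character(packageVersion("gxepath"))), extra)
}

write_tsv_meta <- function(df, path, extra_meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(extra_meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  skip = "", ...))
}

#' Write / read a dosage matrix as TSV
#'
#' Two sibling files are written: `<prefix>.dosage.tsv` (samples x SNPs,
#' first column `sample_id`) and `<prefix>.snps.tsv` (SNP metadata).
#'
#' @param geno a [genotype_matrix()].
#' @param prefix path prefix for the two files.
#' @return the prefix, invisibly.
#' @export
write_dosage_tsv <- function(geno, prefix) {
  d <- as.data.frame(geno$dosage)
  d <- cbind(sample_id = rownames(geno$dosage), d)
  data.table::fwrite(d, paste0(prefix, ".dosage.tsv"), sep = "\t")
  data.table::fwrite(geno$snp_info, paste0(prefix, ".snps.tsv"), sep = "\t")
  invisible(prefix)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(prefix) {
  d <- data.table::fread(paste0(prefix, ".dosage.tsv"), sep = "\t",
                         header = TRUE, data.table = FALSE)
  info <- data.table::fread(paste0(prefix, ".snps.tsv"), sep = "\t",
                            header = TRUE, data.table = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  genotype_matrix(m, info)
}

#' Write genotypes as a minimal VCF
#'
#' Hard-call dosages are emitted as unphased GT fields (`0/0`, `0/1`,
#' `1/1`); missing dosages become `./.`. One sample column per row of
#' the dosage matrix.
#'
#' @param geno a [genotype_matrix()]; dosages must be in {0,1,2,NA}.
#' @param path output `.vcf` path (uncompressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  d <- geno$dosage
  if (!all(is.na(d) | d %in% 0:2))
    stop_gx("VCF output requires hard-call dosages in {0,1,2}")
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1], nrow = nrow(d))
  gt[is.na(d)] <- "./."
  info <- geno$snp_info
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=gxepath",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(d)),
                     collapse = "\t")), con)
  body <- cbind(info$chrom, info$pos, info$id, info$ref, info$alt,
                ".", ".", ".", "GT", t(gt))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a VCF into a genotype matrix (GT to dosage)
#'
#' Uses `VariantAnnotation::readVcf()`; the GT field is converted to an
#' alternate-allele dosage, with `./.` read as `NA`.
#'
#' @param path a VCF file.
#' @return a [genotype_matrix()].
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_gx("read_vcf_dosage() needs the VariantAnnotation package")
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(v)$GT      # variants x samples
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean == "1/1"] <- 2
  rr <- SummarizedExperiment::rowRanges(v)
  info <- data.frame(
    id = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a)[1], character(1)),
    stringsAsFactors = FALSE)
  m <- t(dos)
  rownames(m) <- colnames(gt)
  genotype_matrix(m, info)
}

#' Write / read a cohort table TSV
#' @param cohort a cohort data.frame; `path` the TSV file.
#' @return path / the cohort, respectively.
#' @export
write_cohort_tsv <- function(cohort, path) {
  data.table::fwrite(as.data.frame(cohort), path, sep = "\t")
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  as_cohort_table(data.table::fread(path, sep = "\t", data.table = FALSE),
                  n_pcs = 0)
}

#' Write / read gene spans as BED (0-based, half-open)
#'
#' Uses `rtracklayer` so coordinate conventions are handled by the
#' standard importer; the in-memory representation stays BED-like.
#'
#' @param genes a [gene_map()]; `path` a `.bed` file.
#' @return path / a `gene_map`, respectively.
#' @export
write_bed <- function(genes, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_gx("write_bed() needs the rtracklayer package")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    name = genes$symbol)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_gx("read_bed() needs the rtracklayer package")
  gr <- rtracklayer::import(path, format = "BED")
  gene_map(symbol = gr$name,
           chrom = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr) - 1,
           end = GenomicRanges::end(gr))
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then member symbols, all
#' tab-separated.
#'
#' @param sets a [gene_set_collection()]; `path` a `.gmt` file.
#' @return path / a `gene_set_collection`, respectively.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop_gx("malformed GMT line %d: need name, description, >=1 member",
            bad[1])
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  gene_set_collection(sets, description = setNames(
    vapply(parts, `[`, character(1), 2L), names(sets)))
}

#' Write / read expression counts as an MTX triplet
#'
#' Writes `matrix.mtx` (genes x cells, MatrixMarket), `features.tsv`
#' (gene symbols) and `barcodes.tsv` (cell ids with cell-type labels)
#' into `dir`, mirroring the common 10X layout.
#'
#' @param expr an [expression_matrix()]; `dir` the output directory.
#' @return dir / an `expression_matrix`, respectively.
#' @export
write_mtx <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(expr$counts), sparse = TRUE)  # genes x cells
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(expr$genes, file.path(dir, "features.tsv"))
  data.table::fwrite(
    data.frame(barcode = expr$cells, cell_type = expr$cell_type),
    file.path(dir, "barcodes.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "features.tsv"))
  bc <- data.table::fread(file.path(dir, "barcodes.tsv"), sep = "\t",
                          data.table = FALSE)
  counts <- as.matrix(Matrix::t(m))
  dimnames(counts) <- list(bc$barcode, genes)
  expression_matrix(counts, bc$cell_type)
}

#' Write / read a dense expression TSV (cells x genes)
#' @param expr an [expression_matrix()]; `path` the TSV file.
#' @return path / an `expression_matrix`.
#' @export
write_expression_tsv <- function(expr, path) {
  d <- as.data.frame(as.matrix(expr$counts))
  d <- cbind(cell = expr$cells, cell_type = expr$cell_type, d)
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(m) <- d$cell
  expression_matrix(m, d$cell_type)
}

#' Write / read GWAS summary statistics
#'
#' Whitespace-delimited table with columns SNP, CHR, BP, A1, A2, N,
#' BETA, SE, P and, for interaction runs, BETA_INT, SE_INT, P_INT.
#'
#' @param stats a summary-statistics data.frame from the GWAS fitters.
#' @param path the TSV file.
#' @return path / a summary-statistics data.frame.
#' @export
write_summary_tsv <- function(stats, path) {
  out <- data.frame(SNP = stats$id, CHR = stats$chrom, BP = stats$pos,
                    A1 = stats$alt, A2 = stats$ref, N = stats$n_used)
  if ("beta_add" %in% names(stats)) {
    out$BETA <- stats$beta_add; out$SE <- stats$se_add; out$P <- stats$p_add
  } else {
    out$BETA <- stats$beta_main; out$SE <- stats$se_main
    out$P <- stats$p_main
    out$BETA_INT <- stats$beta_int; out$SE_INT <- stats$se_int
    out$P_INT <- stats$p_int
  }
  data.table::fwrite(out, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_summary_tsv
#' @export
read_summary_tsv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  out <- data.frame(id = d$SNP, chrom = d$CHR, pos = d$BP,
                    ref = d$A2, alt = d$A1, n_used = d$N)
  if ("BETA_INT" %in% names(d)) {
    out$beta_main <- d$BETA; out$se_main <- d$SE; out$p_main <- d$P
    out$beta_int <- d$BETA_INT; out$se_int <- d$SE_INT
    out$p_int <- d$P_INT
    attr(out, "model") <- "interaction"
  } else {
    out$beta_add <- d$BETA; out$se_add <- d$SE; out$p_add <- d$P
    attr(out, "model") <- "additive"
  }
  out
}

#' Write / read a GRN edge list TSV (SOURCE, TARGET, WEIGHT, FREQ)
#' @param grn a `grn` edge table; `path` the TSV file.
#' @return path / a `grn`.
#' @export
write_grn_tsv <- function(grn, path) {
  data.table::fwrite(
    data.frame(SOURCE = grn$source, TARGET = grn$target,
               WEIGHT = grn$weight, FREQ = grn$freq),
    path, sep = "\t")
  invisible(path)
}

#' @rdname write_grn_tsv
#' @export
read_grn_tsv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  as_grn(data.frame(source = d$SOURCE, target = d$TARGET,
                    weight = d$WEIGHT, freq = d$FREQ))
}

#' Write / read a SNP-to-gene map TSV (SNP, GENE, DIST)
#' @param mgmap marker-gene map data.frame; `path` the TSV file.
#' @return path / the map.
#' @export
write_mgmap_tsv <- function(mgmap, path) {
  data.table::fwrite(
    data.frame(SNP = mgmap$snp, GENE = mgmap$gene, DIST = mgmap$distance),
    path, sep = "\t")
  invisible(path)
}

#' @rdname write_mgmap_tsv
#' @export
read_mgmap_tsv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  data.frame(snp = d$SNP, gene = d$GENE, distance = d$DIST)
}
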
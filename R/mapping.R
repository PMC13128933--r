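# Marker dependency filtering (LD pruning by association strength) and
# SNP-to-gene / gene-symbol translation utilities.

#' Marker dependency filter (LD-redundancy pruning)
#'
#' Removes SNPs that are in strong linkage disequilibrium with a more
#' strongly associated SNP. Within each chromosome, candidates are
#' visited in order of ascending association p-value (ties broken by
#' position, then id) and retained only if their squared dosage
#' correlation with every already-retained SNP inside a `window_bp`
#' position window stays below `r2_max`. The retained set therefore has
#' no within-window pair with r-squared at or above the threshold, and
#' re-filtering it is a no-op.
#'
#' @param geno a [genotype_matrix()] covering the SNPs in `stats`.
#' @param stats summary statistics; the interaction p-value column is
#'   used when present, else the additive one (`p_col` overrides).
#' @param r2_max squared-correlation threshold in (0, 1\] (default 0.5).
#' @param window_bp sliding position window (default 1 Mb, which bounds
#'   compute and exceeds the typical LD range).
#' @param p_col optional explicit p-value column name.
#' @return character vector of retained SNP ids, in genome order.
#' @export
marker_dependency_filter <- function(geno, stats, r2_max = 0.5,
                                     window_bp = 1e6, p_col = NULL) {
  assert_fraction(r2_max, "r2_max", 0, 1, open_lo = TRUE)
  p_col <- p_col %||% if ("p_int" %in% names(stats)) "p_int" else "p_add"
  if (!p_col %in% names(stats)) stop_gx("stats lacks column '%s'", p_col)
  idx <- match(geno$snp_info$id, stats$id)
  if (anyNA(idx)) stop_gx("stats do not cover all genotype SNPs")
  p <- stats[[p_col]][idx]
  info <- geno$snp_info
  keep <- character(0)
  for (chr in unique(info$chrom)) {
    on_chr <- which(info$chrom == chr & !is.na(p))
    ord <- on_chr[order_p_pos_id(p[on_chr], info$pos[on_chr],
                                 info$id[on_chr])]
    kept_idx <- integer(0)
    for (j in ord) {
      near <- kept_idx[abs(info$pos[kept_idx] - info$pos[j]) <= window_bp]
      ok <- TRUE
      if (length(near)) {
        r2 <- suppressWarnings(
          cor(geno$dosage[, j], geno$dosage[, near, drop = FALSE],
              use = "pairwise.complete.obs"))^2
        ok <- all(is.na(r2) | r2 < r2_max)
      }
      if (ok) kept_idx <- c(kept_idx, j)
    }
    keep <- c(keep, info$id[kept_idx])
  }
  info2 <- info[match(keep, info$id), ]
  keep[order(info2$chrom, info2$pos)]
}

#' Map SNPs to genes within a distance window
#'
#' A SNP at 1-based position `pos` maps to a gene with BED span
#' `[start, end)` iff `pos` falls in `[start + 1 - window, end + window]`
#' (the BED span converted to 1-based inclusive, extended by the
#' window). Distance is 0 inside the span, else the bp gap to the
#' nearest span edge. A SNP may map to multiple genes.
#'
#' @param snps SNP metadata data.frame (`id`, `chrom`, `pos`).
#' @param genes a [gene_map()].
#' @param window_bp mapping window in bp (default 50 kb).
#' @return data.frame with `snp`, `gene`, `distance`, sorted by gene
#'   then distance.
#' @export
map_snps_to_genes <- function(snps, genes, window_bp = 50000) {
  if (window_bp < 0) stop_gx("window_bp must be >= 0")
  shared <- intersect(unique(snps$chrom), unique(genes$chrom))
  missing_chr <- setdiff(unique(genes$chrom), unique(snps$chrom))
  if (length(missing_chr))
    warn_gx("no SNPs on chromosome(s): %s",
            paste(missing_chr, collapse = ", "))
  sdt <- data.table::data.table(snp = snps$id, chrom = snps$chrom,
                                lo = snps$pos, hi = snps$pos)
  one <- bed_to_1based(genes$start, genes$end)
  gdt <- data.table::data.table(gene = genes$symbol, chrom = genes$chrom,
                                first = one$first, last = one$last,
                                lo = one$first - window_bp,
                                hi = one$last + window_bp)
  data.table::setkey(gdt, chrom, lo, hi)
  ov <- data.table::foverlaps(sdt, gdt, type = "within", nomatch = NULL)
  if (nrow(ov) == 0)
    return(data.frame(snp = character(), gene = character(),
                      distance = numeric()))
  pos <- ov$i.lo
  dist <- pmax(0, pmax(ov$first - pos, pos - ov$last))
  out <- data.frame(snp = ov$snp, gene = ov$gene, distance = dist)
  out <- out[order(out$gene, out$distance, out$snp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Translate gene symbols in a set collection or network
#'
#' Applies a user-supplied two-column mapping table (e.g. a mouse to
#' human orthology table). Unmapped symbols are dropped with a logged
#' count; one-to-many mappings expand to all pairs and are flagged.
#'
#' @param x a [gene_set_collection()] or `grn` edge table.
#' @param mapping data.frame whose first column is the source symbol
#'   and second the translated symbol.
#' @return an object of the same type as `x`; for networks, an
#'   `expanded` logical column flags one-to-many expansions.
#' @export
orthology_translate <- function(x, mapping) {
  if (is.null(mapping) || nrow(mapping) == 0) stop_gx("empty mapping table")
  from <- as.character(mapping[[1]]); to <- as.character(mapping[[2]])
  multi <- names(which(table(from) > 1))
  tr <- split(to, from)
  if (inherits(x, "gene_set_collection")) {
    dropped <- 0L
    sets <- lapply(unclass(x), function(s) {
      hit <- s %in% names(tr)
      dropped <<- dropped + sum(!hit)
      unique(unlist(tr[s[hit]], use.names = FALSE))
    })
    sets <- sets[lengths(sets) > 0]
    if (dropped) message(sprintf("orthology_translate: dropped %d unmapped symbols", dropped))
    return(gene_set_collection(sets))
  }
  if (inherits(x, "grn") || all(c("source", "target") %in% names(x))) {
    hit <- x$source %in% names(tr) & x$target %in% names(tr)
    if (any(!hit))
      message(sprintf("orthology_translate: dropped %d edges with unmapped symbols",
                      sum(!hit)))
    x <- x[hit, , drop = FALSE]
    rows <- lapply(seq_len(nrow(x)), function(i) {
      s <- tr[[x$source[i]]]; t1 <- tr[[x$target[i]]]
      g <- expand.grid(source = s, target = t1, stringsAsFactors = FALSE)
      g$weight <- x$weight[i]; g$freq <- x$freq[i]
      g$expanded <- x$source[i] %in% multi | x$target[i] %in% multi
      g
    })
    out <- do.call(rbind, rows)
    out <- out[out$source != out$target, , drop = FALSE]
    out <- out[!duplicated(paste(out$source, out$target)), , drop = FALSE]
    return(as_grn(out))
  }
  stop_gx("unsupported object type for orthology_translate")
}
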
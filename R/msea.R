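# Marker-set enrichment analysis (MSEA).
#
# Tests whether the markers mapped to a gene set sit in the stronger
# tail of the GWAS p-value distribution more often than random gene
# sets of the same mapped-gene count. The statistic is chi-like:
#   S = sum_q (O_q - E_q) / sqrt(E_q + kappa)
# over p-value quantile thresholds q, with O_q the observed number of
# set markers at or below the q-quantile of all mapped marker p-values
# and E_q = n_set * q the expectation under uniform sampling.
# The null is gene-level: permuted sets draw whole genes (each gene
# carrying its full marker block) from the mapped-gene universe, which
# preserves LD / marker-count structure.

MSEA_QUANTILES <- c(0.5, 0.25, 0.1, 0.05, 0.01)

#' Chi-like enrichment statistic
#'
#' @param marker_pvals_in_set p-values of the (deduplicated) markers of
#'   one set.
#' @param all_marker_pvals p-values of every mapped marker (the
#'   universe defining the quantile thresholds).
#' @param quantiles threshold quantiles in (0,1).
#' @param kappa variance stabiliser added to the expected count
#'   (default 1).
#' @return the scalar statistic S.
#' @export
msea_statistic <- function(marker_pvals_in_set, all_marker_pvals,
                           quantiles = MSEA_QUANTILES, kappa = 1) {
  if (length(marker_pvals_in_set) == 0) stop_gx("empty marker set")
  if (any(quantiles <= 0 | quantiles >= 1))
    stop_gx("quantiles must lie strictly inside (0,1)")
  thr <- quantile(all_marker_pvals, quantiles, names = FALSE, type = 7)
  n_set <- length(marker_pvals_in_set)
  O <- vapply(thr, function(t1) sum(marker_pvals_in_set <= t1),
              numeric(1))
  E <- n_set * quantiles
  sum((O - E) / sqrt(E + kappa))
}

# Internal engine shared by msea_run and the null-calibration tests.
# gene_markers: list of integer marker-index vectors per mapped gene;
# marker_level[i]: number of thresholds marker i passes (thresholds
# sorted by increasing quantile are nested, so a count suffices).
msea_set_stat <- function(marker_idx, marker_level, n_thr, E_unit, kappa) {
  n_set <- length(marker_idx)
  lev <- marker_level[marker_idx]
  cnt <- tabulate(lev, nbins = n_thr)
  # O for quantile q_j = number of markers with level >= (n_thr - j + 1)
  O <- rev(cumsum(rev(cnt)))
  E <- n_set * E_unit
  sum((O - E) / sqrt(E + kappa))
}

#' Run MSEA over a gene-set collection
#'
#' Maps each set to its markers through `mgmap` (markers shared by
#' several genes of a set are counted once per set), computes the
#' observed statistic, and builds a gene-level permutation null with
#' adaptive early stopping: permutation stops for a set once
#' `min_exceed` null exceedances accumulate, up to `n_perm` draws.
#' Empirical p = (1 + #\{S_null >= S_obs\}) / (1 + n_done); BH FDR is
#' applied once across every set tested in the run.
#'
#' @param stats summary statistics; the interaction p-value column is
#'   used when present (`p_col` overrides). Pass stats whose SNPs have
#'   been through [marker_dependency_filter()].
#' @param mgmap SNP-to-gene map from [map_snps_to_genes()].
#' @param sets a [gene_set_collection()].
#' @param n_perm permutation cap per set (default 10000; < 100 refused).
#' @param seed integer seed for the permutation stream.
#' @param min_genes,max_genes mapped-gene count bounds for testing a
#'   set (defaults 10 and 500).
#' @param quantiles,kappa see [msea_statistic()].
#' @param min_exceed adaptive stopping rule (default 50 exceedances).
#' @param p_col optional explicit p-value column.
#' @param top_k how many top genes/SNPs to report per set.
#' @return an enrichment table sorted by FDR then p, with per-set
#'   mapped-gene and marker counts, statistic, permutation p, BH FDR
#'   and top contributing genes/SNPs.
#' @export
msea_run <- function(stats, mgmap, sets, n_perm = 10000, seed = 1,
                     min_genes = 10, max_genes = 500,
                     quantiles = MSEA_QUANTILES, kappa = 1,
                     min_exceed = 50, p_col = NULL, top_k = 5) {
  if (n_perm < 100) stop_gx("n_perm must be at least 100")
  p_col <- p_col %||% if ("p_int" %in% names(stats)) "p_int" else "p_add"
  if (!p_col %in% names(stats)) stop_gx("stats lacks column '%s'", p_col)
  pv <- setNames(stats[[p_col]], stats$id)
  mg <- mgmap[mgmap$snp %in% names(pv)[!is.na(pv)], , drop = FALSE]
  markers <- sort(unique(mg$snp))
  marker_p <- pv[markers]
  thr <- quantile(marker_p, quantiles, names = FALSE, type = 7)
  # thresholds are nested, so a marker's "level" = number of thresholds
  # passed; markers with level >= j are exactly those at or below the
  # threshold of the j-th largest quantile.
  E_unit <- sort(quantiles, decreasing = TRUE)
  marker_level <- rowSums(outer(marker_p, thr, "<="))
  gene_markers <- split(match(mg$snp, markers), mg$gene)
  universe <- names(gene_markers)
  n_thr <- length(quantiles)

  rows <- list()
  with_seed(child_seed(seed, "msea"), {
    for (nm in names(sets)) {
      genes_mapped <- intersect(sets[[nm]], universe)
      ng <- length(genes_mapped)
      if (ng < min_genes || ng > max_genes) next
      obs_idx <- unique(unlist(gene_markers[genes_mapped],
                               use.names = FALSE))
      s_obs <- msea_set_stat(obs_idx, marker_level, n_thr, E_unit, kappa)
      exceed <- 0L; done <- 0L
      chunk <- 200L
      while (done < n_perm && exceed < min_exceed) {
        b <- min(chunk, n_perm - done)
        for (k in seq_len(b)) {
          pg <- sample(universe, ng)
          pi <- unique(unlist(gene_markers[pg], use.names = FALSE))
          s0 <- msea_set_stat(pi, marker_level, n_thr, E_unit, kappa)
          if (s0 >= s_obs) exceed <- exceed + 1L
        }
        done <- done + b
      }
      pperm <- (1 + exceed) / (1 + done)
      # top contributing genes: ranked by their best marker p
      best <- vapply(genes_mapped, function(g)
        min(marker_p[gene_markers[[g]]]), numeric(1))
      topg <- genes_mapped[order(best)][seq_len(min(top_k, ng))]
      tops <- vapply(topg, function(g) {
        mi <- gene_markers[[g]]
        markers[mi[which.min(marker_p[mi])]]
      }, character(1))
      rows[[nm]] <- data.frame(
        set = nm, n_genes_mapped = ng, n_markers = length(obs_idx),
        statistic = s_obs, p = pperm, n_perm_used = done,
        top_genes = paste(topg, collapse = ";"),
        top_snps = paste(tops, collapse = ";"),
        top_logp = paste(sprintf("%.2f", -log10(marker_p[tops])),
                         collapse = ";"),
        stringsAsFactors = FALSE)
    }
  })
  if (length(rows) == 0) {
    warn_gx("no set passed the mapped-gene size bounds")
    return(data.frame(set = character(), n_genes_mapped = integer(),
                      n_markers = integer(), statistic = numeric(),
                      p = numeric(), fdr = numeric()))
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out <- out[order(out$fdr, out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "p_col") <- p_col
  attr(out, "universe_size") <- length(universe)
  out
}

# Draw n null statistics for a random set of ng genes; used by the
# calibration tests (mean of S over null draws should be near 0).
msea_null_stats <- function(stats, mgmap, ng, n, seed = 1,
                            quantiles = MSEA_QUANTILES, kappa = 1,
                            p_col = NULL) {
  p_col <- p_col %||% if ("p_int" %in% names(stats)) "p_int" else "p_add"
  pv <- setNames(stats[[p_col]], stats$id)
  mg <- mgmap[mgmap$snp %in% names(pv)[!is.na(pv)], , drop = FALSE]
  markers <- sort(unique(mg$snp))
  marker_p <- pv[markers]
  thr <- quantile(marker_p, quantiles, names = FALSE, type = 7)
  E_unit <- sort(quantiles, decreasing = TRUE)
  marker_level <- rowSums(outer(marker_p, thr, "<="))
  gene_markers <- split(match(mg$snp, markers), mg$gene)
  universe <- names(gene_markers)
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      pg <- sample(universe, ng)
      pi <- unique(unlist(gene_markers[pg], use.names = FALSE))
      msea_set_stat(pi, marker_level, length(quantiles), E_unit, kappa)
    }, numeric(1))
  })
}

#' Per-set top interaction SNPs
#'
#' For each set in an enrichment table, reports the `k` mapped SNPs
#' with the smallest p-values, with gene attribution and -log10 p.
#' Ties in p are broken by position then id.
#'
#' @param table an enrichment table from [msea_run()].
#' @param stats the summary statistics used for the run.
#' @param mgmap the SNP-to-gene map used for the run.
#' @param sets the gene-set collection used for the run.
#' @param k top count per set (default 5).
#' @param p_col optional explicit p-value column.
#' @return data.frame with `set`, `snp`, `gene`, `p`, `neg_log10_p`.
#' @export
summarize_top_snps <- function(table, stats, mgmap, sets, k = 5,
                               p_col = NULL) {
  if (k < 1) stop_gx("k must be >= 1")
  p_col <- p_col %||% if ("p_int" %in% names(stats)) "p_int" else "p_add"
  pv <- stats[[p_col]][match(mgmap$snp, stats$id)]
  pos <- stats$pos[match(mgmap$snp, stats$id)]
  out <- lapply(table$set, function(nm) {
    rows <- mgmap[mgmap$gene %in% sets[[nm]] & !is.na(pv), , drop = FALSE]
    pv_r <- stats[[p_col]][match(rows$snp, stats$id)]
    pos_r <- stats$pos[match(rows$snp, stats$id)]
    dup <- duplicated(rows$snp)
    rows <- rows[!dup, , drop = FALSE]
    pv_r <- pv_r[!dup]; pos_r <- pos_r[!dup]
    ord <- order_p_pos_id(pv_r, pos_r, rows$snp)
    take <- ord[seq_len(min(k, length(ord)))]
    data.frame(set = nm, snp = rows$snp[take], gene = rows$gene[take],
               p = pv_r[take], neg_log10_p = -log10(pv_r[take]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
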
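# Key-driver analysis: network hubs whose neighborhoods are enriched
# for a pathway's genes, against a permuted-network null.

#' Run key-driver analysis on a network
#'
#' Candidate hubs are nodes with degree >= `min_degree`. A hub's
#' neighborhood is every node within `depth` edges (edges treated as
#' undirected, hub included). For hub h and pathway P restricted to
#' network nodes V: overlap `O = |N(h) ∩ P|`, expectation
#' `E = |N(h)| |P ∩ V| / |V|`, and the chi-like score
#' `Z = (O - E) / sqrt(E + kappa)`. The null permutes node labels of
#' the whole network (topology preserved) `n_perm` times, recomputing Z
#' for every hub x pathway pair; empirical
#' `p = (1 + #{Z_null >= Z_obs}) / (1 + n_perm)` with BH FDR across all
#' pairs in the run.
#'
#' @param grn a `grn` edge table (direction is ignored here).
#' @param sets a [gene_set_collection()]; pathways with no genes in the
#'   network are skipped with a warning.
#' @param depth neighborhood radius in edges (default 1).
#' @param n_perm label permutations (default 2000).
#' @param min_degree candidate degree floor (default 5).
#' @param kappa score stabiliser (default 1, as in the enrichment
#'   statistic).
#' @param seed permutation seed.
#' @return a key-driver table sorted by FDR then p: one row per
#'   (hub, pathway) with neighborhood size, overlap, expectation, fold
#'   `O/E`, `z`, permutation `p` and `fdr`.
#' @export
kda_run <- function(grn, sets, depth = 1, n_perm = 2000, min_degree = 5,
                    kappa = 1, seed = 1) {
  g <- igraph::graph_from_data_frame(grn[, c("source", "target")],
                                     directed = FALSE)
  g <- igraph::simplify(g)
  nodes <- igraph::V(g)$name
  nv <- length(nodes)
  if (nv == 0 || igraph::ecount(g) == 0) {
    warn_gx("degenerate network: no edges, no candidates")
    return(empty_kda())
  }
  deg <- igraph::degree(g)
  hubs <- nodes[deg >= min_degree]
  if (length(hubs) == 0) {
    warn_gx("no node reaches min_degree = %d", min_degree)
    return(empty_kda())
  }
  neigh <- igraph::ego(g, order = depth, nodes = hubs, mindist = 0)
  neigh_idx <- lapply(neigh, as.integer)
  names(neigh_idx) <- hubs
  member <- list()
  for (nm in names(sets)) {
    inset <- nodes %in% sets[[nm]]
    if (!any(inset)) {
      warn_gx("pathway '%s' shares no genes with the network; skipped", nm)
      next
    }
    member[[nm]] <- inset
  }
  if (length(member) == 0) return(empty_kda())

  z_of <- function(ind, idx) {
    m <- length(idx)
    O <- sum(ind[idx])
    E <- m * sum(ind) / nv
    (O - E) / sqrt(E + kappa)
  }
  obs <- expand.grid(hub = hubs, pathway = names(member),
                     stringsAsFactors = FALSE)
  obs$neigh_size <- lengths(neigh_idx)[obs$hub]
  stat <- mapply(function(h, pw) {
    idx <- neigh_idx[[h]]
    ind <- member[[pw]]
    c(O = sum(ind[idx]), E = length(idx) * sum(ind) / nv)
  }, obs$hub, obs$pathway)
  obs$overlap <- stat["O", ]
  obs$expected <- stat["E", ]
  obs$z <- (obs$overlap - obs$expected) / sqrt(obs$expected + kappa)
  obs$fold <- ifelse(obs$expected > 0, obs$overlap / obs$expected, NA)

  # independent node-label permutations per (hub, pathway) pair: a
  # permuted network re-scores the fixed neighborhood against shuffled
  # labels; independence across pairs keeps the per-candidate p-values
  # exchangeable with the uniform null
  exceed <- numeric(nrow(obs))
  with_seed(child_seed(seed, "kda"), {
    for (r in seq_len(nrow(obs))) {
      ind <- member[[obs$pathway[r]]]
      idx <- neigh_idx[[obs$hub[r]]]
      for (b in seq_len(n_perm)) {
        perm <- sample.int(nv)
        if (z_of(ind[perm], idx) >= obs$z[r] - 1e-12)
          exceed[r] <- exceed[r] + 1
      }
    }
  })
  obs$p <- (1 + exceed) / (1 + n_perm)
  obs$fdr <- bh_fdr(obs$p)
  obs <- obs[order(obs$fdr, obs$p, obs$hub), , drop = FALSE]
  rownames(obs) <- NULL
  class(obs) <- c("kda_table", "data.frame")
  obs
}

empty_kda <- function() {
  structure(data.frame(hub = character(), pathway = character(),
                       neigh_size = integer(), overlap = integer(),
                       expected = numeric(), z = numeric(),
                       fold = numeric(), p = numeric(), fdr = numeric()),
            class = c("kda_table", "data.frame"))
}

#' Extract the significant key-driver subnetwork
#'
#' The union of hubs at `fdr <= fdr_max` and their depth-1 neighbors,
#' with node annotations: key-driver flag, pathway membership, and the
#' best mapped interaction-GWAS -log10 p when summary statistics and a
#' SNP-to-gene map are supplied.
#'
#' @param grn the `grn` the table was computed on.
#' @param table a `kda_table` from [kda_run()].
#' @param fdr_max significance cut (default 0.05).
#' @param stats,mgmap optional summary statistics + SNP-gene map for
#'   GWAS annotation.
#' @return list with `edges` (subnetwork edge table) and `nodes`
#'   (annotation data.frame); both empty when nothing is significant.
#' @export
extract_kd_subnetwork <- function(grn, table, fdr_max = 0.05,
                                  stats = NULL, mgmap = NULL) {
  sig <- table[table$fdr <= fdr_max, , drop = FALSE]
  if (nrow(sig) == 0)
    return(list(edges = grn[0, , drop = FALSE],
                nodes = data.frame(node = character(),
                                   is_kd = logical(),
                                   pathways = character())))
  g <- igraph::graph_from_data_frame(grn[, c("source", "target")],
                                     directed = FALSE)
  hubs <- unique(sig$hub)
  nb <- igraph::ego(g, order = 1, nodes = hubs, mindist = 0)
  keep <- unique(unlist(lapply(nb, function(v) igraph::V(g)$name[v])))
  edges <- grn[grn$source %in% keep & grn$target %in% keep, ,
               drop = FALSE]
  pw <- vapply(keep, function(nd)
    paste(sort(unique(sig$pathway[sig$hub == nd])), collapse = ";"),
    character(1))
  nodes <- data.frame(node = keep, is_kd = keep %in% hubs,
                      pathways = pw, stringsAsFactors = FALSE)
  if (!is.null(stats) && !is.null(mgmap)) {
    p_col <- if ("p_int" %in% names(stats)) "p_int" else "p_add"
    pv <- stats[[p_col]][match(mgmap$snp, stats$id)]
    best <- vapply(keep, function(nd) {
      pp <- pv[mgmap$gene == nd]
      if (all(is.na(pp)) || length(pp) == 0) NA_real_
      else -log10(min(pp, na.rm = TRUE))
    }, numeric(1))
    nodes$best_neg_log10_p <- best
  }
  rownames(nodes) <- NULL
  list(edges = edges, nodes = nodes)
}
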
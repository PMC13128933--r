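# Cell-type gene regulatory network inference: pseudocell aggregation
# (kNN graph + Leiden communities on normalised expression), per-target
# gradient-boosted regulator selection on bootstrap subsamples, and a
# bootstrap-consensus edge set.

#' Aggregate cells of one type into pseudocells
#'
#' Counts are normalised (counts-per-10k, log1p), reduced to at most 30
#' principal components, connected by a k-nearest-neighbour graph and
#' partitioned with Leiden community detection; each community's
#' pseudocell profile is the arithmetic mean of its members' normalised
#' expression. The resolution is auto-adjusted (at most 5 iterations)
#' toward a target mean community size unless `auto_resolution = FALSE`.
#'
#' @param expr an [expression_matrix()].
#' @param cell_type which cell type to aggregate (required when the
#'   matrix holds more than one type).
#' @param k_neighbors kNN graph degree (default 15).
#' @param resolution Leiden (modularity) resolution (default 1).
#' @param target_size target mean cells per pseudocell (default 20).
#' @param auto_resolution adjust resolution toward `target_size`.
#' @param seed seed for the Leiden refinement.
#' @return list with `profiles` (pseudocells x genes), `sizes`,
#'   `membership`, and the `resolution` used.
#' @export
build_pseudocells <- function(expr, cell_type = NULL, k_neighbors = 15,
                              resolution = 1, target_size = 20,
                              auto_resolution = TRUE, seed = 1) {
  types <- unique(expr$cell_type)
  if (is.null(cell_type)) {
    if (length(types) > 1)
      stop_gx("matrix holds %d cell types; pick one", length(types))
    cell_type <- types
  }
  rows <- which(expr$cell_type == cell_type)
  if (length(rows) < 2 * k_neighbors)
    stop_gx("need at least %d cells of type '%s'", 2 * k_neighbors,
            cell_type)
  counts <- as.matrix(expr$counts[rows, , drop = FALSE])
  lib <- pmax(rowSums(counts), 1)
  norm <- log1p(counts / lib * 1e4)
  keep_var <- which(apply(norm, 2, sd) > 0)
  n_pc <- min(30L, length(keep_var) - 1L, nrow(norm) - 1L)
  pc <- prcomp(norm[, keep_var, drop = FALSE], rank. = n_pc,
               center = TRUE, scale. = FALSE)$x
  # kNN graph on Euclidean distance in PC space
  d <- as.matrix(dist(pc))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
  el <- cbind(rep(seq_len(nrow(nn)), k_neighbors), as.vector(nn))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  res <- resolution
  for (iter in seq_len(if (auto_resolution) 5L else 1L)) {
    memb <- with_seed(child_seed(seed, "leiden"), {
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = res, n_iterations = 3)$membership
    })
    mean_size <- length(rows) / length(unique(memb))
    if (!auto_resolution ||
        (mean_size >= target_size / 2 && mean_size <= target_size * 2))
      break
    res <- res * mean_size / target_size
  }
  sizes <- as.vector(table(memb))
  if (length(sizes) < 10)
    warn_gx("only %d pseudocells; bootstrap GRNs may be unstable",
            length(sizes))
  profiles <- rowsum(norm, memb) / sizes
  rownames(profiles) <- paste0("PC_", sort(unique(memb)))
  list(profiles = profiles, sizes = sizes, membership = memb,
       resolution = res, cell_type = cell_type)
}

#' Infer one bootstrap GRN from pseudocell profiles
#'
#' On a `sub_frac` subsample of pseudocells, each gene in turn is the
#' regression target: its candidate regulators are the `n_candidates`
#' genes with the largest absolute Pearson correlation (self excluded),
#' a gradient-boosted tree ensemble predicts the target from the
#' candidates, and candidates whose normalised feature importance
#' exceeds `importance_min` (default the uniform share
#' `1/n_candidates`) become regulator -> target edges.
#'
#' @param pseudocells pseudocells x genes matrix (from
#'   [build_pseudocells()]`$profiles`).
#' @param sub_frac subsample fraction (default 0.8).
#' @param n_candidates candidate regulators per target (default 50).
#' @param n_trees,max_depth,learning_rate boosting hyper-parameters
#'   (defaults 100, 3, 0.1).
#' @param importance_min edge retention floor on normalised importance;
#'   `NULL` means `1/n_candidates`.
#' @param colsample fraction of candidates offered to each tree split
#'   (default 1/3); the induced randomness spreads importance near the
#'   uniform share for targets with no real driver.
#' @param r2_min minimum held-out R-squared (on the pseudocells left
#'   out of the subsample) a target's ensemble must reach before any
#'   of its edges are emitted (default 0.3). Boosting itself is
#'   early-stopped on the same held-out cells, so targets without real
#'   regulators stop almost immediately and are dropped here.
#' @param seed seed controlling the subsample.
#' @return data.frame of edges (`source`, `target`, `weight`).
#' @export
infer_bootstrap_grn <- function(pseudocells, sub_frac = 0.8,
                                n_candidates = 50, n_trees = 100,
                                max_depth = 3, learning_rate = 0.1,
                                importance_min = NULL, colsample = 1 / 3,
                                r2_min = 0.3, seed = 1) {
  m <- nrow(pseudocells)
  if (m < 20) stop_gx("need at least 20 pseudocells, have %d", m)
  genes <- colnames(pseudocells)
  idx <- with_seed(seed, sort(sample.int(m, ceiling(sub_frac * m))))
  P <- pseudocells[idx, , drop = FALSE]
  # held-out pseudocells drive early stopping of the boosting, so a
  # target with no real regulators accrues (almost) no importance
  V <- pseudocells[setdiff(seq_len(m), idx), , drop = FALSE]
  has_valid <- nrow(V) >= 5
  n_candidates <- min(n_candidates, ncol(P) - 1L)
  importance_min <- importance_min %||% (1 / n_candidates)
  cm <- suppressWarnings(cor(P))
  diag(cm) <- NA
  out <- vector("list", ncol(P))
  for (j in seq_len(ncol(P))) {
    yv <- P[, j]
    if (sd(yv) == 0) next                 # constant target: no edges
    ac <- abs(cm[, j])
    cand <- order(ac, decreasing = TRUE, na.last = NA)
    cand <- cand[seq_len(min(n_candidates, length(cand)))]
    cand <- cand[!is.na(ac[cand]) & ac[cand] > 0]
    if (length(cand) == 0) next
    fit <- .gbm_importance(P[, cand, drop = FALSE], yv,
                           n_trees = n_trees, max_depth = max_depth,
                           learning_rate = learning_rate,
                           colsample = colsample,
                           seed = child_seed(seed, paste0("gbm", j)),
                           X_valid = if (has_valid)
                             V[, cand, drop = FALSE] else NULL,
                           y_valid = if (has_valid) V[, j] else NULL)
    if (has_valid && (is.na(fit$valid_r2) || fit$valid_r2 < r2_min))
      next  # ensemble does not beat the intercept on held-out cells
    imp <- fit$importance
    tot <- sum(imp)
    if (tot <= 0) next
    imp <- imp / tot
    keep <- which(imp > importance_min)
    if (length(keep))
      out[[j]] <- data.frame(source = genes[cand[keep]],
                             target = genes[j], weight = imp[keep],
                             stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric())
  rownames(edges) <- NULL
  edges
}

#' Aggregate bootstrap GRNs into a consensus network
#'
#' An edge enters the consensus iff it appears in at least `freq_min`
#' of the bootstraps; its weight is the mean importance over the
#' bootstraps containing it and its `freq` the containment fraction.
#' `freq_min = 1` gives the intersection of the bootstrap edge sets;
#' `freq_min = 0` the union.
#'
#' @param bootstrap_edges list of edge data.frames from
#'   [infer_bootstrap_grn()].
#' @param freq_min consensus threshold in \[0, 1\] (default 0.5).
#' @return a `grn` edge table (see [as_grn()]).
#' @export
consensus_grn <- function(bootstrap_edges, freq_min = 0.5) {
  B <- length(bootstrap_edges)
  if (B < 2) stop_gx("need at least 2 bootstraps")
  all <- data.table::rbindlist(bootstrap_edges)
  if (nrow(all) == 0)
    return(as_grn(data.frame(source = character(), target = character(),
                             weight = numeric(), freq = numeric())))
  agg <- all[, list(weight = mean(weight), count = .N),
             by = c("source", "target")]
  agg$freq <- agg$count / B
  keep <- agg$freq >= max(freq_min, 1e-12)
  as_grn(as.data.frame(agg[keep, c("source", "target", "weight",
                                   "freq")]))
}

#' Full bootstrap-consensus GRN for one cell type
#'
#' Convenience driver: `n_bootstrap` subsample networks (seeds derived
#' from the master seed) aggregated by [consensus_grn()].
#'
#' @inheritParams infer_bootstrap_grn
#' @param n_bootstrap number of bootstraps (default 100; scaled-down
#'   runs use fewer).
#' @param freq_min consensus threshold (default 0.5).
#' @return a `grn` edge table.
#' @export
infer_grn <- function(pseudocells, n_bootstrap = 100, sub_frac = 0.8,
                      n_candidates = 50, n_trees = 100, max_depth = 3,
                      learning_rate = 0.1, importance_min = NULL,
                      colsample = 1 / 3, r2_min = 0.3, freq_min = 0.5,
                      seed = 1) {
  boots <- lapply(seq_len(n_bootstrap), function(b) {
    infer_bootstrap_grn(pseudocells, sub_frac = sub_frac,
                        n_candidates = n_candidates, n_trees = n_trees,
                        max_depth = max_depth,
                        learning_rate = learning_rate,
                        importance_min = importance_min,
                        colsample = colsample, r2_min = r2_min,
                        seed = child_seed(seed, paste0("boot", b)))
  })
  consensus_grn(boots, freq_min = freq_min)
}
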
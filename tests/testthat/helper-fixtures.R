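# Shared fixtures and independent oracles. Everything is generated in
# code; no stored data.

# small, fast simulation config for structural tests
tiny_cfg <- function(...) {
  args <- modifyList(list(
    n_samples = 200, n_snps = 300, ld_block_size = 5,
    within_block_r = 0.6, n_genes = 80, n_pathways = 20,
    pathway_size_range = c(5, 12), n_enriched_pathways = 2,
    n_cells = 400, n_cell_types = 2, n_hub_modules = 2,
    module_size = 8, seed = 42), list(...))
  do.call(sim_config, args)
}

# hand-built genotype matrix from a dosage matrix
make_geno <- function(dosage, chrom = "chr1", spacing = 1000L) {
  p <- ncol(dosage)
  info <- data.frame(id = sprintf("s%03d", seq_len(p)),
                     chrom = rep_len(chrom, p),
                     pos = spacing * seq_len(p),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(dosage, info)
}

# minimal cohort with n_pcs PC columns
make_cohort <- function(n, injury = NULL, phenotype = NULL, n_pcs = 2,
                        seed = 1) {
  set.seed(seed)
  injury <- injury %||% rbinom(n, 1, 0.3)
  d <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                  phenotype = phenotype %||% rnorm(n),
                  injury = injury,
                  age = round(runif(n, 108, 131)),
                  sex = rbinom(n, 1, 0.5),
                  ethnicity = sample(c("White", "Black", "Hispanic",
                                       "Asian", "Other"), n, TRUE),
                  stringsAsFactors = FALSE)
  if (n_pcs > 0) {
    pcs <- matrix(rnorm(n * n_pcs), n)
    colnames(pcs) <- paste0("PC", seq_len(n_pcs))
    d <- cbind(d, pcs)
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent OLS oracle: normal equations, t-based p-values.
ols_oracle <- function(y, X) {
  X <- cbind(intercept = 1, X)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  tt <- drop(beta) / se
  list(beta = drop(beta), se = se, p = 2 * pt(-abs(tt), df), df = df)
}

# unordered-pair keys of planted hub-module edges
module_pairs <- function(truth, directed = FALSE) {
  hubs <- names(truth$hub_regulators)
  fwd <- paste(rep(hubs, lengths(truth$hub_regulators)),
               unlist(truth$hub_regulators))
  if (directed) return(fwd)
  rev <- paste(unlist(truth$hub_regulators),
               rep(hubs, lengths(truth$hub_regulators)))
  c(fwd, rev)
}

# all within-module (co-membership) ordered pair keys
within_module_pairs <- function(truth) {
  unlist(lapply(names(truth$hub_regulators), function(h) {
    mem <- c(h, truth$hub_regulators[[h]])
    eg <- expand.grid(mem, mem, stringsAsFactors = FALSE)
    eg <- eg[eg[, 1] != eg[, 2], ]
    paste(eg[, 1], eg[, 2])
  }), use.names = FALSE)
}

expect_setequal_chr <- function(a, b) {
  expect_true(setequal(a, b), info = sprintf(
    "setequal failed: only-in-a=%s only-in-b=%s",
    paste(setdiff(a, b), collapse = ","),
    paste(setdiff(b, a), collapse = ",")))
}
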
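# Configuration handling and the end-to-end pipeline driver.

#' Default pipeline configuration
#'
#' One nested list holds every tunable default named across the
#' modules; [read_pipeline_config()] validates user files against this
#' schema (unknown keys are rejected).
#'
#' @return a nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    out_dir = "gxepath_run",
    seed = 1L,
    simulate = unclass(sim_config()),
    gwas = list(maf = 0.05, n_pcs = 20L),
    mdf = list(r2_max = 0.5, window_bp = 1e6),
    map = list(window_bp = 50000),
    msea = list(n_perm = 2000L, min_genes = 10L, max_genes = 500L,
                fdr = 0.05, kappa = 1,
                quantiles = MSEA_QUANTILES),
    grn = list(cell_type = NULL, k_neighbors = 15L, resolution = 1,
               target_size = 20L, n_bootstrap = 100L, sub_frac = 0.8,
               n_candidates = 50L, n_trees = 100L, max_depth = 3L,
               learning_rate = 0.1, freq_min = 0.5),
    kda = list(depth = 1L, n_perm = 2000L, min_degree = 5L,
               fdr = 0.05),
    prs = list(top_k = 20L, fdr = 0.05, injury_filter = TRUE,
               n_folds = 5L)), class = "pipeline_config")
}

check_keys <- function(user, ref, path = "") {
  extra <- setdiff(names(user), names(ref))
  if (length(extra))
    stop_gx("unknown config key(s): %s",
            paste0(path, extra, collapse = ", "))
  for (nm in names(user))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      check_keys(as.list(user[[nm]]), ref[[nm]], paste0(path, nm, "."))
  invisible(TRUE)
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' Values merge over [default_config()]; unknown keys are an error so
#' typos cannot silently fall back to defaults.
#'
#' @param path a `.yaml`/`.yml` or `.json` file; `NULL` for defaults.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_gx("YAML configs need the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(user, cfg)
  merged <- modifyList(unclass(cfg), user)
  # revalidate the simulation block through its constructor
  merged$simulate <- unclass(do.call(sim_config, merged$simulate))
  class(merged) <- "pipeline_config"
  merged
}

#' Write a pipeline configuration
#' @param cfg a `pipeline_config`; `path` ending in `.yaml` or `.json`.
#' @return path, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_gx("YAML configs need the yaml package; use JSON instead")
    yaml::write_yaml(unclass(cfg), path, precision = 15L)
  } else jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

stage_checksums <- function(files) {
  files <- files[file.exists(files)]
  as.list(tools::md5sum(files))
}

#' Run the full pipeline on synthetic data
#'
#' Executes, in order: simulate, MAF filter, additive GWAS, interaction
#' GWAS, genomic-control QC, marker dependency filtering, SNP-to-gene
#' mapping, MSEA, GRN inference, KDA, and PRS select/score/fit. Every
#' stage writes its outputs under `cfg$out_dir` and records row counts
#' and md5 checksums in `manifest.json`. With `resume = TRUE`, stages
#' whose outputs already exist with matching checksums are skipped and
#' marked cached.
#'
#' @param cfg a `pipeline_config` (see [read_pipeline_config()]).
#' @param resume reuse intact outputs of a previous run (default FALSE).
#' @return the manifest, invisibly (a nested list, also on disk).
#' @export
run_pipeline <- function(cfg = default_config(), resume = FALSE) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  old_manifest <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else NULL
  manifest <- list(package_version =
                     as.character(packageVersion("gxepath")),
                   seed = cfg$seed, stages = list())
  state <- new.env(parent = emptyenv())

  cached_ok <- function(name, outputs) {
    if (is.null(old_manifest)) return(FALSE)
    st <- old_manifest$stages[[name]]
    if (is.null(st)) return(FALSE)
    cur <- stage_checksums(outputs)
    identical(lapply(st$checksums, as.character), cur) &&
      all(file.exists(outputs))
  }
  run_stage <- function(name, outputs, fresh, load) {
    t0 <- Sys.time()
    cached <- cached_ok(name, outputs)
    info <- tryCatch({
      if (cached) load() else fresh()
    }, error = function(e)
      stop_gx("stage '%s' failed: %s", name, conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      cached = cached,
      rows = info$rows %||% NA,
      outputs = outputs,
      checksums = stage_checksums(outputs),
      seconds = round(as.numeric(difftime(Sys.time(), t0,
                                          units = "secs")), 2))
    message(sprintf("[%s] %s (%s)", name,
                    if (cached) "cached" else "done",
                    manifest$stages[[name]]$seconds))
  }
  out <- function(...) file.path(cfg$out_dir, ...)

  scfg <- do.call(sim_config, cfg$simulate)
  run_stage("simulate",
            c(out("genotypes.dosage.tsv"), out("genotypes.snps.tsv"),
              out("cohort.tsv"), out("genes.bed"), out("sets.gmt"),
              out("truth.json")),
    fresh = function() {
      study <- simulate_study(scfg)
      state$study <- study
      write_dosage_tsv(study$genotypes, out("genotypes"))
      write_cohort_tsv(study$cohort, out("cohort.tsv"))
      if (requireNamespace("rtracklayer", quietly = TRUE))
        write_bed(study$genes, out("genes.bed"))
      else
        data.table::fwrite(study$genes, out("genes.bed"), sep = "\t",
                           col.names = FALSE)
      write_gmt(study$gene_sets, out("sets.gmt"))
      jsonlite::write_json(
        list(causal_interaction_snps = study$truth$causal_interaction_snps,
             causal_additive_snps = study$truth$causal_additive_snps,
             enriched_pathways = study$truth$enriched_pathways,
             signal_genes = study$truth$signal_genes,
             hub_regulators = study$truth$hub_regulators),
        out("truth.json"), digits = NA)
      list(rows = scfg$n_samples)
    },
    load = function() {
      state$study <- list(
        genotypes = read_dosage_tsv(out("genotypes")),
        cohort = read_cohort_tsv(out("cohort.tsv")),
        genes = local({
          g <- data.table::fread(out("genes.bed"), data.table = FALSE,
                                 header = FALSE)
          gene_map(g[[4]], g[[1]], g[[2]], g[[3]])
        }),
        gene_sets = read_gmt(out("sets.gmt")),
        truth = jsonlite::read_json(out("truth.json"),
                                    simplifyVector = TRUE))
      list(rows = nrow(state$study$cohort))
    })

  run_stage("maf_filter", out("genotypes_maf.snps.tsv"),
    fresh = function() {
      state$geno <- maf_filter(state$study$genotypes, cfg$gwas$maf)
      data.table::fwrite(state$geno$snp_info,
                         out("genotypes_maf.snps.tsv"), sep = "\t")
      list(rows = ncol(state$geno$dosage))
    },
    load = function() {
      info <- data.table::fread(out("genotypes_maf.snps.tsv"),
                                data.table = FALSE)
      state$geno <- geno_subset(state$study$genotypes, info$id)
      list(rows = nrow(info))
    })

  run_stage("gwas_additive", out("gwas_additive.tsv"),
    fresh = function() {
      state$add <- fit_additive_gwas(state$geno, state$study$cohort,
                                     n_pcs = cfg$gwas$n_pcs)
      write_summary_tsv(state$add, out("gwas_additive.tsv"))
      list(rows = nrow(state$add))
    },
    load = function() {
      state$add <- read_summary_tsv(out("gwas_additive.tsv"))
      list(rows = nrow(state$add))
    })

  run_stage("gwas_interaction", out("gwas_interaction.tsv"),
    fresh = function() {
      state$int <- fit_interaction_gwas(state$geno, state$study$cohort,
                                        n_pcs = cfg$gwas$n_pcs)
      write_summary_tsv(state$int, out("gwas_interaction.tsv"))
      list(rows = nrow(state$int))
    },
    load = function() {
      state$int <- read_summary_tsv(out("gwas_interaction.tsv"))
      list(rows = nrow(state$int))
    })

  run_stage("lambda_gc", out("lambda_gc.json"),
    fresh = function() {
      lam <- list(
        additive = genomic_control_lambda(
          state$add$p_add[!is.na(state$add$p_add)])$lambda,
        interaction = genomic_control_lambda(
          state$int$p_int[!is.na(state$int$p_int)])$lambda)
      jsonlite::write_json(lam, out("lambda_gc.json"),
                           auto_unbox = TRUE, digits = NA)
      list(rows = 2)
    },
    load = function() list(rows = 2))

  run_stage("mdf", out("mdf_snps.txt"),
    fresh = function() {
      keep <- marker_dependency_filter(state$geno, state$int,
                                       r2_max = cfg$mdf$r2_max,
                                       window_bp = cfg$mdf$window_bp)
      state$mdf <- keep
      writeLines(keep, out("mdf_snps.txt"))
      list(rows = length(keep))
    },
    load = function() {
      state$mdf <- readLines(out("mdf_snps.txt"))
      list(rows = length(state$mdf))
    })

  run_stage("map", out("snp_gene_map.tsv"),
    fresh = function() {
      info <- state$geno$snp_info
      info <- info[info$id %in% state$mdf, , drop = FALSE]
      state$mgmap <- map_snps_to_genes(info, state$study$genes,
                                       window_bp = cfg$map$window_bp)
      write_mgmap_tsv(state$mgmap, out("snp_gene_map.tsv"))
      list(rows = nrow(state$mgmap))
    },
    load = function() {
      state$mgmap <- read_mgmap_tsv(out("snp_gene_map.tsv"))
      list(rows = nrow(state$mgmap))
    })

  run_stage("msea", out("msea.tsv"),
    fresh = function() {
      state$enrich <- msea_run(state$int, state$mgmap,
                               state$study$gene_sets,
                               n_perm = cfg$msea$n_perm,
                               seed = child_seed(cfg$seed, "msea_stage"),
                               min_genes = cfg$msea$min_genes,
                               max_genes = cfg$msea$max_genes,
                               quantiles = cfg$msea$quantiles,
                               kappa = cfg$msea$kappa)
      data.table::fwrite(state$enrich, out("msea.tsv"), sep = "\t")
      list(rows = nrow(state$enrich))
    },
    load = function() {
      state$enrich <- data.table::fread(out("msea.tsv"),
                                        data.table = FALSE)
      list(rows = nrow(state$enrich))
    })

  run_stage("grn", out("grn.tsv"),
    fresh = function() {
      expr <- state$study$expression %||% simulate_expression(
        scfg, plant_truth(scfg, state$study$genotypes,
                          state$study$genes))
      ct <- cfg$grn$cell_type %||% expr$cell_type[1]
      pc <- build_pseudocells(expr, cell_type = ct,
                              k_neighbors = cfg$grn$k_neighbors,
                              resolution = cfg$grn$resolution,
                              target_size = cfg$grn$target_size,
                              seed = child_seed(cfg$seed, "pseudocell"))
      state$grn <- infer_grn(pc$profiles,
                             n_bootstrap = cfg$grn$n_bootstrap,
                             sub_frac = cfg$grn$sub_frac,
                             n_candidates = cfg$grn$n_candidates,
                             n_trees = cfg$grn$n_trees,
                             max_depth = cfg$grn$max_depth,
                             learning_rate = cfg$grn$learning_rate,
                             freq_min = cfg$grn$freq_min,
                             seed = child_seed(cfg$seed, "grn_stage"))
      write_grn_tsv(state$grn, out("grn.tsv"))
      list(rows = nrow(state$grn))
    },
    load = function() {
      state$grn <- read_grn_tsv(out("grn.tsv"))
      list(rows = nrow(state$grn))
    })

  run_stage("kda", out("kda.tsv"),
    fresh = function() {
      sig_sets <- state$enrich$set[state$enrich$fdr <= cfg$kda$fdr]
      sets <- state$study$gene_sets
      use <- if (length(sig_sets)) sets[names(sets) %in% sig_sets]
             else unclass(sets)[seq_len(min(5, length(sets)))]
      use <- gene_set_collection(use)
      state$kda <- suppressWarnings(
        kda_run(state$grn, use, depth = cfg$kda$depth,
                n_perm = cfg$kda$n_perm,
                min_degree = cfg$kda$min_degree,
                seed = child_seed(cfg$seed, "kda_stage")))
      data.table::fwrite(state$kda, out("kda.tsv"), sep = "\t")
      list(rows = nrow(state$kda))
    },
    load = function() {
      state$kda <- data.table::fread(out("kda.tsv"), data.table = FALSE)
      list(rows = nrow(state$kda))
    })

  run_stage("prs", c(out("prs_selection.tsv"), out("prs_scores.tsv"),
                     out("prs_models.json")),
    fresh = function() {
      sets <- state$study$gene_sets
      sel_int <- select_pathway_snps(state$enrich, state$mgmap, sets,
                                     state$int, top_k = cfg$prs$top_k,
                                     fdr_max = cfg$prs$fdr)
      sel_add <- select_pathway_snps(state$enrich, state$mgmap, sets,
                                     state$add, top_k = cfg$prs$top_k,
                                     fdr_max = cfg$prs$fdr)
      if (cfg$prs$injury_filter && nrow(sel_int) > 0)
        sel_int <- injury_specific_filter(sel_int, state$geno,
                                          state$study$cohort,
                                          fdr_max = cfg$prs$fdr,
                                          n_pcs = cfg$gwas$n_pcs)
      prs_a <- compute_prs(sel_add, state$geno, state$study$cohort,
                           mode = "additive")
      prs_i <- compute_prs(list(A = sel_add, I = sel_int), state$geno,
                           state$study$cohort, mode = "interaction")
      rep_ <- fit_phenotype_models(prs_a, prs_i, state$study$cohort)
      cv <- cross_validate(prs_a, prs_i, state$study$cohort,
                           n_folds = cfg$prs$n_folds,
                           seed = child_seed(cfg$seed, "cv_stage"))
      data.table::fwrite(as.data.frame(sel_int), out("prs_selection.tsv"),
                         sep = "\t")
      data.table::fwrite(data.frame(sample_id = prs_a$sample_id,
                                    prs_add = prs_a$prs,
                                    prs_int = prs_i$prs),
                         out("prs_scores.tsv"), sep = "\t")
      jsonlite::write_json(list(models = rep_$table, lrt = rep_$lrt,
                                delta_aic = rep_$delta_aic,
                                cv = cv$folds),
                           out("prs_models.json"), digits = NA,
                           dataframe = "rows")
      list(rows = nrow(sel_int))
    },
    load = function()
      list(rows = nrow(data.table::fread(out("prs_selection.tsv")))))

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
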
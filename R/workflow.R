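#' Assemble a workflow configuration
#'
#' Collects everything the end-to-end pipeline needs. Can also be read
#' from a YAML file with [read_workflow_config()].
#'
#' @param input_path Path to the compendium TSV.
#' @param template_metadata Path to the template sample-metadata TSV
#'   (`sample_id`, `group`).
#' @param out_dir Output directory.
#' @param orientation Compendium orientation on disk.
#' @param scale Scale of the stored compendium values.
#' @param log_transform Apply log10 before normalization.
#' @param vae Named list of [vae_config()] overrides (e.g.
#'   `list(hidden_dim = 250, epochs = 20)`).
#' @param n_sim Number of simulated background experiments (>= 2).
#' @param max_fdr,min_abs_log2fc DEG-calling thresholds.
#' @param gene_sets Optional GMT path; when absent the enrichment stage
#'   is skipped.
#' @param n_permutations Permutations for enrichment significance.
#' @param seed Master seed for the whole run.
#' @param retrain Ignore any cached model checkpoint.
#' @return An object of class `workflow_config`.
#' @export
workflow_config <- function(input_path, template_metadata, out_dir,
                            orientation = "samples_by_genes",
                            scale = "raw_counts", log_transform = FALSE,
                            vae = list(), n_sim = 25L, max_fdr = 0.05,
                            min_abs_log2fc = 1.0, gene_sets = NULL,
                            n_permutations = 1000L, seed = 1L,
                            retrain = FALSE) {
  if (n_sim < 2L) stop("n_sim must be at least 2")
  for (p in c(input_path, template_metadata)) {
    if (!file.exists(p)) stop("path does not exist: ", p)
  }
  if (!is.null(gene_sets) && !file.exists(gene_sets)) {
    stop("gene-set path does not exist: ", gene_sets)
  }
  structure(
    list(input_path = input_path, template_metadata = template_metadata,
         out_dir = out_dir, orientation = orientation, scale = scale,
         log_transform = log_transform, vae = vae,
         n_sim = as.integer(n_sim), max_fdr = max_fdr,
         min_abs_log2fc = min_abs_log2fc, gene_sets = gene_sets,
         n_permutations = as.integer(n_permutations),
         seed = as.integer(seed), retrain = isTRUE(retrain)),
    class = "workflow_config")
}

#' Read a workflow configuration from YAML
#'
#' @param path YAML file whose keys match the [workflow_config()]
#'   arguments.
#' @return A `workflow_config`.
#' @export
read_workflow_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(workflow_config, cfg)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full specificity workflow
#'
#' Executes load -> normalize -> train (or reuse a cached model) ->
#' simulate -> differential expression on the template and every
#' simulated experiment -> specificity report, and optionally enrichment
#' plus pathway commonness percentiles when a gene-set collection is
#' configured. Every artifact is written as TSV under `out_dir` together
#' with a manifest recording paths, seeds and the configuration hash, so
#' the run is fully reproducible: the same configuration and seed yield
#' byte-identical reports.
#'
#' @param cfg A [workflow_config()] or the path to a YAML file.
#' @return The manifest data frame, invisibly.
#' @export
run_specificity_workflow <- function(cfg) {
  if (is.character(cfg)) cfg <- read_workflow_config(cfg)
  stopifnot(inherits(cfg, "workflow_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(artifact = character(0), path = character(0),
                         seed = integer(0))
  add <- function(artifact, path, seed = cfg$seed) {
    manifest <<- rbind(manifest,
                       data.frame(artifact = artifact, path = path,
                                  seed = seed))
  }

  t0 <- Sys.time()
  comp <- load_expression_matrix(cfg$input_path, cfg$orientation,
                                 scale = cfg$scale,
                                 log10_transform = cfg$log_transform)
  template <- read_template_metadata(cfg$template_metadata,
                                     compendium = comp)
  stage_log("load", "%d samples x %d genes; template '%s' (%d samples)",
            nrow(comp$values), ncol(comp$values), template$experiment_id,
            length(template$sample_ids))

  cn <- normalize_per_gene(comp)
  vae_args <- utils::modifyList(list(seed = cfg$seed), cfg$vae)
  vcfg <- do.call(vae_config, vae_args)
  cfg_hash <- rlang::hash(list(values = cn$values, config = vcfg))
  ckpt <- file.path(cfg$out_dir, paste0("model_", cfg_hash, ".rds"))
  if (file.exists(ckpt) && !cfg$retrain) {
    model <- readRDS(ckpt)
    stage_log("train", "reusing checkpoint %s", basename(ckpt))
  } else {
    model <- train_vae(cn, vcfg)
    saveRDS(model, ckpt)
    stage_log("train", "%d epochs, final val loss %.3f",
              vcfg$epochs, utils::tail(model$loss$val_loss, 1))
  }
  loss_path <- file.path(cfg$out_dir, "loss_trace.tsv")
  write_loss_trace(model, loss_path)
  add("model_checkpoint", ckpt)
  add("loss_trace", loss_path)

  sim_seed <- cfg$seed + 1L
  sims <- simulate_background_set(model, template, cn, n_sim = cfg$n_sim,
                                  seed = sim_seed)
  stage_log("simulate", "%d experiments of %d samples", sims$n_sim,
            length(template$sample_ids))

  # template DE on the original data scale; counts are log2(x+1)'d
  t_vals <- template_values(template, comp)
  to_log2 <- function(x) if (cfg$scale == "raw_counts") log2_counts(pmax(x, 0)) else x
  de_t <- moderated_t_test(to_log2(t_vals), template$group_labels)
  de_t_path <- file.path(cfg$out_dir, "template_DE.tsv")
  write_de_result(de_t, de_t_path)
  add("template_DE", de_t_path)
  de_sims <- vector("list", sims$n_sim)
  for (i in seq_len(sims$n_sim)) {
    de_sims[[i]] <- moderated_t_test(to_log2(sims$experiments[[i]]),
                                     sims$group_labels)
    p <- file.path(cfg$out_dir, sprintf("simulated_DE_%03d.tsv", i))
    write_de_result(de_sims[[i]], p)
    add(sprintf("simulated_DE_%03d", i), p, sims$sub_seeds[i])
  }
  stage_log("de", "template + %d simulated experiments tested", sims$n_sim)

  report <- compute_zscores(de_t, de_sims)
  report_path <- file.path(cfg$out_dir, "specificity_report.tsv")
  write_specificity_report(report, report_path)
  add("specificity_report", report_path)
  degs <- call_degs(de_t, deg_thresholds(cfg$max_fdr, cfg$min_abs_log2fc))
  stage_log("specificity", "%d genes scored; %d template DEGs",
            nrow(report), length(degs))

  if (!is.null(cfg$gene_sets)) {
    collection <- read_gmt(cfg$gene_sets, universe = comp$gene_ids,
                           min_size = 3L)
    stats_t <- stats::setNames(de_t$log2fc, de_t$gene_id)
    enr_t <- gsea_significance(stats_t, collection,
                               n_permutations = cfg$n_permutations,
                               seed = cfg$seed)
    enr_sims <- lapply(seq_along(de_sims), function(i) {
      gsea_significance(stats::setNames(de_sims[[i]]$log2fc,
                                        de_sims[[i]]$gene_id),
                        collection, n_permutations = cfg$n_permutations,
                        seed = sims$sub_seeds[i])
    })
    pw <- pathway_percentile(enr_t, enr_sims)
    enr_path <- file.path(cfg$out_dir, "template_enrichment.tsv")
    pw_path <- file.path(cfg$out_dir, "pathway_percentiles.tsv")
    utils::write.table(enr_t, enr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(pw, pw_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add("template_enrichment", enr_path)
    add("pathway_percentiles", pw_path)
    stage_log("enrich", "%d gene sets scored", nrow(enr_t))
  } else {
    add("enrichment", "skipped")
    stage_log("enrich", "no gene sets configured; skipped")
  }

  manifest$config_hash <- cfg_hash
  manifest_path <- file.path(cfg$out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stage_log("done", "%d artifacts in %s (%.1f s)", nrow(manifest),
            cfg$out_dir, as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(manifest)
}
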
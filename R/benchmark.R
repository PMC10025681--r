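#' Specification of the spike-in benchmark compendium
#'
#' Describes the fully synthetic validation compendium: negative-binomial
#' count experiments in which a known set of genes is commonly perturbed
#' in every experiment and a small per-experiment set is specifically
#' perturbed, so that specificity ranking can be scored against ground
#' truth.
#'
#' @param n_experiments Number of background experiments (default 90).
#' @param samples_per_experiment Samples per experiment (default 8: the
#'   first half control, the second half perturbed).
#' @param n_genes Genes per experiment (default 1000).
#' @param n_common Genes spiked in every experiment (default 100).
#' @param n_specific Genes spiked only in one experiment (default 10,
#'   drawn per experiment from the non-common genes).
#' @param scaler_quantile The additive spike ("scaler") for an experiment
#'   is this quantile of its per-gene median expression (default 0.98).
#' @param nb_dispersion Negative-binomial size parameter (default 2).
#' @param nb_success_rate_range Per-gene success rates are drawn
#'   uniformly from this interval (default (0.1, 0.9)).
#' @param scaler Optional fixed scaler overriding the quantile rule
#'   (`scaler = 0` produces a spike-free null compendium).
#' @param seed Integer seed; the full compendium is a deterministic
#'   function of the spec.
#' @return An object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_experiments = 90L, samples_per_experiment = 8L,
                           n_genes = 1000L, n_common = 100L,
                           n_specific = 10L, scaler_quantile = 0.98,
                           nb_dispersion = 2,
                           nb_success_rate_range = c(0.1, 0.9),
                           scaler = NULL, seed = 1L) {
  stopifnot(n_common + n_specific <= n_genes,
            samples_per_experiment %% 2 == 0, samples_per_experiment >= 4,
            scaler_quantile > 0, scaler_quantile <= 1,
            nb_dispersion > 0,
            length(nb_success_rate_range) == 2,
            all(nb_success_rate_range > 0), all(nb_success_rate_range < 1))
  structure(
    list(n_experiments = as.integer(n_experiments),
         samples_per_experiment = as.integer(samples_per_experiment),
         n_genes = as.integer(n_genes),
         n_common = as.integer(n_common),
         n_specific = as.integer(n_specific),
         scaler_quantile = scaler_quantile,
         nb_dispersion = nb_dispersion,
         nb_success_rate_range = nb_success_rate_range,
         scaler = scaler,
         seed = as.integer(seed)),
    class = "benchmark_spec")
}

#' Generate the spike-in benchmark compendium
#'
#' Draws a per-gene negative-binomial success rate, then generates every
#' background experiment plus one template experiment by the same
#' recipe: sample counts for all genes, compute the experiment's scaler
#' as the `scaler_quantile` quantile of per-gene median expression, and
#' add it to the common genes and that experiment's own specific genes in
#' the perturbed samples only. The template's specific genes are the
#' ground-truth "specific" set; the common genes are shared by all
#' experiments.
#'
#' @param spec A [benchmark_spec()].
#' @return List with `compendium` (an [expression_compendium()] of
#'   `n_experiments * samples_per_experiment` samples), `template` (a
#'   [template_experiment()] carrying its own count matrix) and
#'   `ground_truth` (common gene ids, per-experiment specific gene ids
#'   including the template's, and the per-experiment scaler values).
#' @export
generate_benchmark_compendium <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  set.seed(spec$seed)
  n_g <- spec$n_genes
  n_s <- spec$samples_per_experiment
  gene_ids <- sprintf("g%04d", seq_len(n_g))
  p_gene <- stats::runif(n_g, spec$nb_success_rate_range[1],
                         spec$nb_success_rate_range[2])
  common <- sort(sample(gene_ids, spec$n_common))
  noncommon <- setdiff(gene_ids, common)
  perturbed_rows <- (n_s / 2 + 1):n_s
  groups <- factor(rep(c("control", "perturbed"), each = n_s / 2),
                   levels = c("control", "perturbed"))

  one_experiment <- function() {
    counts <- matrix(
      stats::rnbinom(n_s * n_g, size = spec$nb_dispersion,
                     prob = rep(p_gene, each = n_s)),
      nrow = n_s, ncol = n_g)
    colnames(counts) <- gene_ids
    specific <- sort(sample(noncommon, spec$n_specific))
    scaler <- if (is.null(spec$scaler)) {
      stats::quantile(apply(counts, 2, stats::median),
                      spec$scaler_quantile, names = FALSE)
    } else {
      spec$scaler
    }
    counts[perturbed_rows, c(common, specific)] <-
      counts[perturbed_rows, c(common, specific)] + scaler
    list(counts = counts, specific = specific, scaler = scaler)
  }

  experiments <- lapply(seq_len(spec$n_experiments), function(i) one_experiment())
  template_raw <- one_experiment()

  values <- do.call(rbind, lapply(experiments, `[[`, "counts"))
  rownames(values) <- unlist(lapply(seq_len(spec$n_experiments), function(e) {
    sprintf("e%03d_s%d", e, seq_len(n_s))
  }))
  compendium <- expression_compendium(values, scale = "raw_counts")

  template <- template_experiment(
    experiment_id = "benchmark_template",
    sample_ids = sprintf("template_s%d", seq_len(n_s)),
    group_labels = groups,
    values = template_raw$counts)

  specific_by_experiment <- c(lapply(experiments, `[[`, "specific"),
                              list(template_raw$specific))
  names(specific_by_experiment) <- c(sprintf("e%03d", seq_len(spec$n_experiments)),
                                     "template")
  scalers <- c(vapply(experiments, `[[`, numeric(1), "scaler"),
               template = template_raw$scaler)
  names(scalers) <- names(specific_by_experiment)

  list(compendium = compendium,
       template = template,
       ground_truth = list(common_gene_ids = common,
                           specific_by_experiment = specific_by_experiment,
                           scalers = scalers,
                           group_labels = groups))
}

#' Default reduced VAE settings for the benchmark
#'
#' A compact architecture (hidden 250, latent 10, 20 epochs) sized for
#' the 720 x 1000 benchmark compendium so that the full pipeline runs in
#' minutes on one CPU. The full-size configuration remains available via
#' [vae_config()].
#'
#' @param seed Integer seed.
#' @return A [vae_config()].
#' @export
benchmark_vae_config <- function(seed = 1L) {
  vae_config(hidden_dim = 250L, latent_dim = 10L, epochs = 20L,
             batch_size = 10L, learning_rate = 0.001,
             kl_warmup_rate = 0.01, seed = seed)
}

#' Run the specificity-vs-fold-change method comparison
#'
#' The end-to-end benchmark: generates the spike-in compendium, trains
#' the VAE on it (0-1 normalized), simulates `n_sim` background
#' experiments from the template, runs moderated-t DE on the template and
#' every simulation (counts log2(x+1)-transformed), computes specificity
#' z-scores, and ranks every gene twice - by z-score (specificity
#' ranking) and by template log2 fold change (traditional ranking) -
#' ascending with average-rank ties, so that a higher rank means "called
#' more specific" by that method.
#'
#' @param spec A [benchmark_spec()].
#' @param vae_cfg A [vae_config()]; defaults to [benchmark_vae_config()]
#'   seeded from the spec.
#' @param n_sim Number of simulated background experiments (default 25).
#' @return A `method_comparison` data frame: `gene_id`, `label`
#'   (common / specific / other from the ground truth), `z_score`,
#'   `template_log2fc`, `specificity_rank`, `traditional_rank`; the full
#'   specificity report and ground truth are attached as attributes.
#' @export
run_method_comparison <- function(spec = benchmark_spec(), vae_cfg = NULL,
                                  n_sim = 25L) {
  stopifnot(inherits(spec, "benchmark_spec"))
  data <- generate_benchmark_compendium(spec)
  if (is.null(vae_cfg)) {
    vae_cfg <- benchmark_vae_config(seed = spec$seed + 1000000L)
  }
  cn <- normalize_per_gene(data$compendium)
  model <- train_vae(cn, vae_cfg)
  sims <- simulate_background_set(model, data$template, cn, n_sim = n_sim,
                                  seed = spec$seed + 2000000L)
  report <- specificity_from_counts(data$template, sims)
  template_de <- attr(report, "template_de")

  spec_rank <- rank(report$z_score, ties.method = "average")
  trad_rank <- rank(template_de$log2fc, ties.method = "average")
  label <- rep("other", nrow(report))
  label[report$gene_id %in% data$ground_truth$common_gene_ids] <- "common"
  label[report$gene_id %in%
          data$ground_truth$specific_by_experiment$template] <- "specific"

  res <- data.frame(gene_id = report$gene_id,
                    label = factor(label, c("common", "specific", "other")),
                    z_score = report$z_score,
                    template_log2fc = template_de$log2fc,
                    specificity_rank = spec_rank,
                    traditional_rank = trad_rank,
                    row.names = NULL)
  attr(res, "report") <- report
  attr(res, "ground_truth") <- data$ground_truth
  attr(res, "model") <- model
  class(res) <- c("method_comparison", "data.frame")
  res
}

# DE on template + simulated counts (log2(x+1) scale) and z-scores
specificity_from_counts <- function(template, sims) {
  x_t <- log2_counts(template_values(template, NULL))
  de_t <- moderated_t_test(x_t, template$group_labels)
  de_sims <- lapply(sims$experiments, function(x) {
    moderated_t_test(log2_counts(x), sims$group_labels)
  })
  report <- compute_zscores(de_t, de_sims)
  attr(report, "template_de") <- de_t
  report
}

#' Paired Wilcoxon signed-rank comparison of two rank vectors
#'
#' Tests, over a gene subset, whether ranks under method A are shifted
#' relative to method B using the signed-rank statistic on the paired
#' differences. Zero differences are dropped; the exact null
#' distribution is used for n <= 25 untied differences, the normal
#' approximation (tie-corrected, continuity-corrected) otherwise. If
#' every difference is zero the test is degenerate and reported as
#' p = 1 with a flag.
#'
#' @param ranks_a,ranks_b Named per-gene rank vectors.
#' @param gene_subset Gene ids to restrict to (non-empty).
#' @param alternative `"greater"` (A tends to rank higher), `"less"`, or
#'   `"two.sided"`.
#' @return List: `statistic` (sum of positive-difference ranks `W`),
#'   `p_value`, `n_used`, `method` ("exact"/"approximate"), `degenerate`.
#' @export
wilcoxon_rank_comparison <- function(ranks_a, ranks_b, gene_subset,
                                     alternative = c("greater", "less",
                                                     "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(gene_subset) == 0L) stop("empty gene subset")
  if (length(setdiff(gene_subset, names(ranks_a))) ||
      length(setdiff(gene_subset, names(ranks_b)))) {
    stop("every subset gene needs a rank under both methods")
  }
  d <- ranks_a[gene_subset] - ranks_b[gene_subset]
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; degenerate test")
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  exact_ok <- n <= 25L && !anyDuplicated(abs(d))
  if (exact_ok) {
    p <- switch(alternative,
      greater = stats::psignrank(W - 1, n, lower.tail = FALSE),
      less = stats::psignrank(W, n),
      two.sided = min(1, 2 * min(
        stats::psignrank(W - 1, n, lower.tail = FALSE),
        stats::psignrank(W, n))))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    sigma <- sqrt(sigma2)
    p <- switch(alternative,
      greater = stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE),
      less = stats::pnorm((W - mu + 0.5) / sigma),
      two.sided = min(1, 2 * min(
        stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE),
        stats::pnorm((W - mu + 0.5) / sigma))))
    method <- "approximate"
  }
  list(statistic = W, p_value = p, n_used = n, method = method,
       degenerate = FALSE)
}

#' Directional rank tests for the benchmark comparison
#'
#' The two ground-truth checks of the benchmark: common genes should
#' rank *lower* (less specific) under the specificity ranking than under
#' the traditional fold-change ranking, and the template's specific
#' genes should rank *higher*.
#'
#' @param cmp A [run_method_comparison()] result.
#' @return Data frame with one row per test (`subset`, `n`, `statistic`,
#'   `p_value`, `mean_rank_specificity`, `mean_rank_traditional`).
#' @export
compare_benchmark_rankings <- function(cmp) {
  stopifnot(inherits(cmp, "method_comparison"))
  ra <- stats::setNames(cmp$specificity_rank, cmp$gene_id)
  rb <- stats::setNames(cmp$traditional_rank, cmp$gene_id)
  subsets <- list(common = list(genes = cmp$gene_id[cmp$label == "common"],
                                alternative = "less"),
                  specific = list(genes = cmp$gene_id[cmp$label == "specific"],
                                  alternative = "greater"))
  rows <- lapply(names(subsets), function(nm) {
    s <- subsets[[nm]]
    w <- wilcoxon_rank_comparison(ra, rb, s$genes, s$alternative)
    data.frame(subset = nm, n = length(s$genes),
               statistic = w$statistic, p_value = w$p_value,
               mean_rank_specificity = mean(ra[s$genes]),
               mean_rank_traditional = mean(rb[s$genes]))
  })
  do.call(rbind, rows)
}
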
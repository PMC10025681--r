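#' Per-gene specificity z-scores against a simulated background
#'
#' For each gene, compares the template experiment's log2 fold change to
#' the distribution of that gene's log2 fold changes across the simulated
#' background experiments:
#'
#'   z = (template_log2fc - mean(sim log2fc)) / max(sd(sim log2fc), eps)
#'
#' The denominator is the sample standard deviation (n - 1 divisor) of
#' the simulated fold changes, floored at `var_floor`; a variance
#' denominator is available via `denominator = "variance"` (that form is
#' not unit-consistent and over-rewards genes whose background variance
#' is tiny, so sd is the default). A high z-score
#' marks a gene whose change in the template exceeds what the background
#' of unrelated experiments produces, i.e. a context-specific change; a
#' low z-score marks a commonly changed gene. The report also ranks genes
#' by their median |log2FC| across the simulations and converts the ranks
#' to commonness percentiles (high percentile = commonly changed).
#'
#' @param template_de [moderated_t_test()] result for the template.
#' @param sim_des List of at least two `de_result`s, one per simulated
#'   experiment, over the same genes in the same order.
#' @param denominator `"sd"` (default) or `"variance"`.
#' @param var_floor Floor for the denominator (default 1e-8), protecting
#'   genes that are flat across every simulation.
#' @return A `specificity_report` data frame with columns `gene_id`,
#'   `template_log2fc`, `sim_mean`, `sim_var`, `z_score`,
#'   `abs_log2fc_median`, `rank`, `percentile`.
#' @export
compute_zscores <- function(template_de, sim_des,
                            denominator = c("sd", "variance"),
                            var_floor = 1e-8) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(template_de, "de_result"), is.list(sim_des))
  if (length(sim_des) < 2L) stop("need at least 2 simulated experiments")
  genes <- template_de$gene_id
  for (s in sim_des) {
    if (!identical(s$gene_id, genes)) {
      stop("all DE results must share the same gene set and order")
    }
  }
  sim_lfc <- do.call(rbind, lapply(sim_des, function(s) s$log2fc))
  sim_mean <- colMeans(sim_lfc)
  sim_var <- apply(sim_lfc, 2, stats::var)
  abs_med <- apply(abs(sim_lfc), 2, stats::median)
  denom <- pmax(if (denominator == "variance") sim_var else sqrt(sim_var),
                var_floor)
  z <- (template_de$log2fc - sim_mean) / denom
  rp <- rank_to_percentile(abs_med)
  res <- data.frame(gene_id = genes,
                    template_log2fc = template_de$log2fc,
                    sim_mean = sim_mean,
                    sim_var = sim_var,
                    z_score = z,
                    abs_log2fc_median = abs_med,
                    rank = rp$rank,
                    percentile = rp$percentile,
                    row.names = NULL)
  attr(res, "n_sim") <- length(sim_des)
  attr(res, "denominator") <- denominator
  class(res) <- c("specificity_report", "data.frame")
  res
}

#' Convert values to ascending ranks and 0-100 percentiles
#'
#' Ranks ascending (average ranks on ties) and linearly scales them to
#' percentiles: `100 * (rank - 1) / (N - 1)`. Invariant under any
#' strictly increasing transform of the input.
#'
#' @param values Numeric vector with at least 2 entries.
#' @return List with `rank` and `percentile` vectors.
#' @export
rank_to_percentile <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to rank")
  r <- rank(values, ties.method = "average")
  list(rank = r, percentile = 100 * (r - 1) / (length(values) - 1))
}

#' Spearman correlation of two percentile vectors
#'
#' Compares two per-gene percentile (or rank) vectors on the intersection
#' of their gene universes.
#'
#' @param a,b Named numeric vectors (names are gene ids).
#' @return Spearman rank correlation on the shared genes.
#' @export
compare_percentiles_spearman <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b))) {
    stop("'a' and 'b' must be named by gene id")
  }
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) stop("fewer than 3 shared genes")
  if (length(shared) < length(a) || length(shared) < length(b)) {
    message(sprintf("compare_percentiles_spearman: using %d shared genes",
                    length(shared)))
  }
  stats::cor(a[shared], b[shared], method = "spearman")
}

#' Over-representation of one common-DEG set within another
#'
#' One-sided Fisher exact test of the 2x2 membership table of two gene
#' sets over a shared universe, testing whether genes called common by
#' the specificity analysis are over-represented among a reference set of
#' common DEGs.
#'
#' @param predicted_common,reference_common Gene-id sets, both subsets of
#'   `universe`.
#' @param universe Gene-id universe.
#' @return List with `odds_ratio` and `p_value`.
#' @export
common_deg_overrepresentation <- function(predicted_common,
                                          reference_common, universe) {
  if (length(universe) == 0L) stop("empty universe")
  if (length(setdiff(predicted_common, universe)) ||
      length(setdiff(reference_common, universe))) {
    stop("both sets must be subsets of the universe")
  }
  in_a <- universe %in% predicted_common
  in_b <- universe %in% reference_common
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Label genes as common, specific or other
#'
#' Commonness wins over specificity: a gene at or above the commonness
#' percentile cutoff is `common`; otherwise a gene with z-score at or
#' above `z_min` is `specific`; everything else is `other`.
#'
#' @param report A [compute_zscores()] report.
#' @param common_percentile_min Commonness percentile cutoff
#'   (default 60).
#' @param z_min Specificity z-score cutoff. No universal default exists
#'   (how large is "specific" depends on the context), so it must be
#'   chosen by the analyst.
#' @return Factor of labels `common` / `specific` / `other`, one per
#'   gene, named by gene id.
#' @export
classify_common_specific <- function(report, common_percentile_min = 60,
                                     z_min) {
  stopifnot(inherits(report, "specificity_report"),
            common_percentile_min >= 0, common_percentile_min <= 100)
  lab <- rep("other", nrow(report))
  lab[report$z_score >= z_min] <- "specific"
  lab[report$percentile >= common_percentile_min] <- "common"
  stats::setNames(factor(lab, levels = c("common", "specific", "other")),
                  report$gene_id)
}

#' Write a specificity report as TSV
#'
#' @param report A `specificity_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specificity_report <- function(report, path) {
  stopifnot(inherits(report, "specificity_report"))
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
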
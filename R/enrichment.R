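#' Read a gene-set collection from a GMT file
#'
#' GMT lines are tab-separated: set name, description, then member
#' genes. Duplicate genes within a set are removed. Sets are optionally
#' intersected with a gene universe and filtered by size.
#'
#' @param path GMT file path.
#' @param universe Optional gene universe to intersect each set with.
#' @param min_size,max_size Size filters applied after intersection.
#' @return Named list of gene-id vectors (class `gene_set_collection`),
#'   with the filters recorded as attributes.
#' @export
read_gmt <- function(path, universe = NULL, min_size = 1L,
                     max_size = Inf) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  gene_set_collection(sets, universe = universe, min_size = min_size,
                      max_size = max_size)
}

#' Build a gene-set collection from a named list
#'
#' @param sets Named list of gene-id vectors.
#' @inheritParams read_gmt
#' @return Filtered named list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL, min_size = 1L,
                                max_size = Inf) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  sets <- lapply(sets, unique)
  if (!is.null(universe)) sets <- lapply(sets, intersect, y = universe)
  sizes <- lengths(sets)
  sets <- sets[sizes >= min_size & sizes <= max_size]
  if (length(sets) == 0L) stop("no gene sets left after filtering")
  structure(sets, class = c("gene_set_collection", "list"),
            min_size = min_size, max_size = max_size)
}

# running-sum ES core: `stat_sorted` descending, `hit` logical mask
es_running_sum <- function(stat_sorted, hit, weight_exponent) {
  n <- length(stat_sorted)
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set has no genes in the ranking")
  if (n_hit == n) stop("gene set equals the whole ranking")
  w <- abs(stat_sorted[hit])^weight_exponent
  if (sum(w) == 0) w <- rep(1, n_hit) # all-zero stats: equal weights
  steps <- numeric(n)
  steps[hit] <- w / sum(w)
  steps[!hit] <- -1 / (n - n_hit)
  run <- cumsum(steps)
  mx <- max(run)
  mn <- min(run)
  # signed maximal deviation; an exact two-sided tie resolves positive
  if (mx >= -mn - 1e-12) mx else mn
}

#' Preranked gene-set enrichment score
#'
#' Walks the ranking from top to bottom keeping a running sum that
#' increases by `|stat|^p / sum_set |stat|^p` at each gene-set member and
#' decreases by `1/(N - |S|)` otherwise. The enrichment score is the
#' running-sum value of maximal absolute deviation from zero (signed):
#' positive when the set concentrates at the top of the ranking,
#' negative at the bottom.
#'
#' @param stats Named numeric vector of per-gene ranking statistics
#'   (e.g. log2 fold changes); ranked descending internally.
#' @param gene_set Gene ids of the set (intersected with the ranking).
#' @param weight_exponent Weighting exponent p (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov-like statistic).
#' @return The enrichment score in `[-1, 1]`.
#' @export
gsea_enrichment_score <- function(stats, gene_set, weight_exponent = 1) {
  if (is.null(names(stats))) stop("'stats' must be named by gene id")
  ord <- order(stats, decreasing = TRUE)
  stat_sorted <- stats[ord]
  hit <- names(stat_sorted) %in% gene_set
  es_running_sum(stat_sorted, hit, weight_exponent)
}

#' Permutation significance for preranked enrichment scores
#'
#' Scores every set in the collection, then builds a null distribution
#' per set size by drawing random same-size gene sets from the ranking
#' and rescoring. `p = (1 + #{|ES_null| >= |ES_obs|}) / (n_permutations
#' + 1)`, Benjamini-Hochberg adjusted across sets. Random gene sets
#' (rather than phenotype label permutations) are used because simulated
#' experiments carry only a handful of samples, which makes label
#' permutation degenerate.
#'
#' @param stats Named per-gene ranking statistics.
#' @param collection A [gene_set_collection()] (or named list of sets).
#' @param n_permutations Number of random sets per size (>= 100).
#' @param seed Integer seed.
#' @param weight_exponent Passed to [gsea_enrichment_score()].
#' @return An `enrichment_result` data frame: `set_name`, `size`, `ES`,
#'   `p_raw`, `p_adj`, with `n_permutations` and `seed` attributes.
#' @export
gsea_significance <- function(stats, collection, n_permutations = 1000L,
                              seed = 1L, weight_exponent = 1) {
  if (n_permutations < 100L) stop("use at least 100 permutations")
  if (!inherits(collection, "gene_set_collection")) {
    collection <- gene_set_collection(collection)
  }
  if (length(collection) == 0L) stop("empty collection")
  ord <- order(stats, decreasing = TRUE)
  stat_sorted <- stats[ord]
  genes <- names(stat_sorted)
  n <- length(genes)

  obs <- vapply(collection, function(s) {
    es_running_sum(stat_sorted, genes %in% s, weight_exponent)
  }, numeric(1))
  sizes <- vapply(collection, function(s) sum(genes %in% s), integer(1))

  set.seed(seed)
  uniq_sizes <- sort(unique(sizes))
  null_abs <- lapply(uniq_sizes, function(k) {
    vapply(seq_len(n_permutations), function(b) {
      hit <- logical(n)
      hit[sample.int(n, k)] <- TRUE
      abs(es_running_sum(stat_sorted, hit, weight_exponent))
    }, numeric(1))
  })
  names(null_abs) <- as.character(uniq_sizes)

  p_raw <- vapply(seq_along(obs), function(i) {
    nul <- null_abs[[as.character(sizes[i])]]
    (1 + sum(nul >= abs(obs[i]))) / (n_permutations + 1)
  }, numeric(1))

  res <- data.frame(set_name = names(collection), size = sizes,
                    ES = unname(obs), p_raw = p_raw,
                    p_adj = bh_adjust(p_raw), row.names = NULL)
  attr(res, "n_permutations") <- as.integer(n_permutations)
  attr(res, "seed") <- as.integer(seed)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric probability of observing at least the
#' actual overlap between a selected gene list (e.g. DEGs) and a gene
#' set, over a finite universe.
#'
#' @param selected Selected gene ids (non-empty subset of `universe`).
#' @param gene_set Gene-set member ids (subset of `universe`).
#' @param universe Gene universe.
#' @return The enrichment p-value.
#' @export
ora_hypergeometric <- function(selected, gene_set, universe) {
  if (length(universe) == 0L) stop("empty universe")
  if (length(selected) == 0L) stop("empty selection")
  if (length(setdiff(selected, universe)) ||
      length(setdiff(gene_set, universe))) {
    stop("'selected' and 'gene_set' must be subsets of the universe")
  }
  k <- length(intersect(selected, gene_set))
  m <- length(gene_set)
  stats::phyper(k - 1, m, length(universe) - m, length(selected),
                lower.tail = FALSE)
}

#' Pathway commonness percentiles across simulated experiments
#'
#' For each gene set, takes the median BH-adjusted enrichment p-value
#' across the simulated experiments; sets with smaller median p are more
#' commonly enriched and receive higher percentiles (linear 0-100
#' scaling of the ranks, average ranks on ties).
#'
#' @param template_result [gsea_significance()] result for the template.
#' @param sim_results List of `enrichment_result`s for the simulated
#'   experiments, over the same collection.
#' @return Data frame: `set_name`, `template_ES`, `template_p_adj`,
#'   `median_sim_p_adj`, `rank`, `percentile`.
#' @export
pathway_percentile <- function(template_result, sim_results) {
  stopifnot(inherits(template_result, "enrichment_result"),
            is.list(sim_results), length(sim_results) >= 1L)
  sets <- template_result$set_name
  for (s in sim_results) {
    if (!identical(s$set_name, sets)) {
      stop("all enrichment results must share the same gene-set collection")
    }
  }
  padj <- do.call(rbind, lapply(sim_results, function(s) s$p_adj))
  med <- apply(padj, 2, stats::median)
  r <- rank(-med, ties.method = "average")
  data.frame(set_name = sets,
             template_ES = template_result$ES,
             template_p_adj = template_result$p_adj,
             median_sim_p_adj = med,
             rank = r,
             percentile = 100 * (r - 1) / (length(sets) - 1),
             row.names = NULL)
}
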
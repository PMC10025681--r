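#' Log2 transform counts
#'
#' `log2(x + 1)`, the transform applied to count-scale data (template or
#' simulated) before two-group testing so that fold changes from all
#' experiments live on one comparable log scale.
#'
#' @param x Numeric matrix of non-negative values.
#' @return Matrix of the same shape.
#' @export
log2_counts <- function(x) {
  if (min(x) < 0) stop("counts must be non-negative")
  log2(x + 1)
}

#' Per-gene log2 fold change between two groups
#'
#' @param x Samples x genes matrix on the log2 scale.
#' @param groups Two-level factor over the rows; the fold change is
#'   mean(second level) - mean(first level), so swapping the levels
#'   negates the result exactly.
#' @return Named per-gene numeric vector.
#' @export
compute_log2fc <- function(x, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) == 0L)) stop("both groups must be non-empty")
  g1 <- x[groups == levels(groups)[1], , drop = FALSE]
  g2 <- x[groups == levels(groups)[2], , drop = FALSE]
  colMeans(g2) - colMeans(g1)
}

# Newton inversion of the trigamma function (monotone decreasing on R+)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# Method-of-moments fit of the scaled-F prior for gene variances:
# log s^2 is matched to the log-chi-squared mixture via digamma/trigamma.
# Returns prior df d0 (possibly Inf) and prior variance s02.
fit_variance_prior <- function(s2, df) {
  s2 <- pmax(s2, 1e-10)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / max(length(e) - 1L, 1L) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

# posterior (shrunken) variance pooling observed and prior
pool_variances <- function(s2, df, d0, s02) {
  if (!is.finite(d0)) return(rep(s02, length.out = length(s2)))
  (d0 * s02 + df * s2) / (d0 + df)
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Computes per-gene log2 fold changes and moderated t-statistics in
#' which each gene's residual variance is shrunk toward a prior estimated
#' from all genes. With `df` residual degrees of freedom per gene and
#' observed variance `s_g^2`, the prior `(d0, s0^2)` is fitted by
#' method-of-moments on `log s_g^2` (digamma/trigamma inversion) and the
#' posterior variance is `(d0 s0^2 + df s_g^2) / (d0 + df)`. The t
#' statistic uses `d0 + df` degrees of freedom and two-sided p-values are
#' Benjamini-Hochberg adjusted.
#'
#' @param x Samples x genes matrix on the log2 scale (use [log2_counts()]
#'   first for count data).
#' @param groups Two-level factor over the rows, each level with at least
#'   2 samples; the contrast is second level minus first.
#' @param prior `"moments"` (default) or `"pooled"` (`s0^2 = mean s_g^2`,
#'   `d0 = 10`), a fallback for very small gene sets.
#' @param var_floor Variances are floored at this value before pooling so
#'   degenerate (zero-variance) genes cannot produce infinite statistics.
#' @return A `de_result` data frame with columns `gene_id`, `log2fc`,
#'   `t_stat`, `p_raw`, `p_adj` and attributes `d0`, `s02`, `df_residual`
#'   and `df_total`.
#' @export
moderated_t_test <- function(x, groups, prior = c("moments", "pooled"),
                             var_floor = 1e-10) {
  prior <- match.arg(prior)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  if (ncol(x) < 1L) stop("no genes to test")

  g1 <- x[groups == levels(groups)[1], , drop = FALSE]
  g2 <- x[groups == levels(groups)[2], , drop = FALSE]
  lfc <- colMeans(g2) - colMeans(g1)
  v1 <- apply(g1, 2, stats::var)
  v2 <- apply(g2, 2, stats::var)
  df <- n1 + n2 - 2L
  s2 <- pmax(((n1 - 1) * v1 + (n2 - 1) * v2) / df, var_floor)

  if (prior == "moments") {
    pr <- fit_variance_prior(s2, df)
  } else {
    pr <- list(d0 = 10, s02 = mean(s2))
  }
  s2_post <- pool_variances(s2, df, pr$d0, pr$s02)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- lfc / se
  df_total <- df + pr$d0
  p_raw <- 2 * stats::pt(-abs(t_stat), df = df_total)
  p_adj <- bh_adjust(p_raw)

  res <- data.frame(gene_id = colnames(x), log2fc = lfc, t_stat = t_stat,
                    p_raw = p_raw, p_adj = p_adj, row.names = NULL)
  attr(res, "d0") <- pr$d0
  attr(res, "s02") <- pr$s02
  attr(res, "df_residual") <- df
  attr(res, "df_total") <- df_total
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone step-up, clipped at 1), never
#'   smaller than the input.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression calling thresholds
#'
#' @param max_fdr Adjusted-p cutoff (strict; default 0.05).
#' @param min_abs_log2fc Absolute log2 fold-change cutoff (strict;
#'   default 1).
#' @return An object of class `deg_thresholds`.
#' @export
deg_thresholds <- function(max_fdr = 0.05, min_abs_log2fc = 1.0) {
  stopifnot(max_fdr > 0, max_fdr < 1, min_abs_log2fc >= 0)
  structure(list(max_fdr = max_fdr, min_abs_log2fc = min_abs_log2fc),
            class = "deg_thresholds")
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when `p_adj < max_fdr` and `|log2fc| > min_abs_log2fc`
#' (both strict inequalities).
#'
#' @param r A [moderated_t_test()] result.
#' @param th A [deg_thresholds()].
#' @return Character vector of DEG gene ids.
#' @export
call_degs <- function(r, th = deg_thresholds()) {
  stopifnot(inherits(r, "de_result"), inherits(th, "deg_thresholds"))
  r$gene_id[r$p_adj < th$max_fdr & abs(r$log2fc) > th$min_abs_log2fc]
}

#' Write a DE result as TSV
#'
#' @param r A `de_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(r, path) {
  stopifnot(inherits(r, "de_result"))
  utils::write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
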
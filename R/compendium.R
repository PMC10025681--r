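#' Construct an expression compendium
#'
#' An expression compendium is a samples x genes numeric matrix together
#' with scale metadata. Per-gene minima and maxima are recorded when the
#' compendium is normalized so that normalization is invertible.
#'
#' @param values Numeric matrix, samples in rows, genes in columns, with
#'   row and column names.
#' @param scale One of `"raw_counts"`, `"log2"` or `"normalized01"`.
#' @param gene_min,gene_max Optional per-gene numima/maxima recorded at
#'   normalization time (required when `scale = "normalized01"` is to be
#'   inverted later).
#' @param prev_scale Scale the data had before normalization, if any.
#'
#' @return An object of class `expression_compendium`.
#' @export
expression_compendium <- function(values,
                                  scale = c("raw_counts", "log2", "normalized01"),
                                  gene_min = NULL, gene_max = NULL,
                                  prev_scale = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (samples x genes)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have sample row names and gene column names")
  }
  if (anyNA(values)) {
    stop("compendium contains missing values; filter them at load time")
  }
  if (scale == "normalized01" &&
      (min(values) < -1e-8 || max(values) > 1 + 1e-8)) {
    stop("scale 'normalized01' requires all values in [0, 1]")
  }
  if (!is.null(gene_min) && length(gene_min) != ncol(values)) {
    stop("'gene_min' length must equal the number of genes")
  }
  if (!is.null(gene_max) && length(gene_max) != ncol(values)) {
    stop("'gene_max' length must equal the number of genes")
  }
  structure(
    list(values = values,
         sample_ids = rownames(values),
         gene_ids = colnames(values),
         scale = scale,
         gene_min = gene_min,
         gene_max = gene_max,
         prev_scale = prev_scale),
    class = "expression_compendium")
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat(sprintf("expression_compendium: %d samples x %d genes (scale: %s)\n",
              length(x$sample_ids), length(x$gene_ids), x$scale))
  invisible(x)
}

#' @export
dim.expression_compendium <- function(x) dim(x$values)

#' Load an expression matrix from a tab-separated file
#'
#' Reads a TSV with one header row and one leading identifier column.
#' Rows or columns containing any missing value are dropped, genes first
#' and then samples, and the drop counts are reported.
#'
#' @param path Path to the tab-separated file.
#' @param orientation `"samples_by_genes"` (default; rows are samples) or
#'   `"genes_by_samples"` for transposed files.
#' @param scale Scale of the stored values (`"raw_counts"` or `"log2"`).
#' @param log10_transform If `TRUE`, apply a log10 transform after
#'   loading (useful for log-intensity compendia with a very large
#'   spread). Off by default.
#'
#' @return An [expression_compendium()].
#' @export
load_expression_matrix <- function(path,
                                   orientation = c("samples_by_genes",
                                                   "genes_by_samples"),
                                   scale = c("raw_counts", "log2"),
                                   log10_transform = FALSE) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("non-numeric cells found after header parsing in ", path)
  }
  m <- as.matrix(df)
  if (orientation == "genes_by_samples") m <- t(m)

  gene_has_na <- apply(m, 2, anyNA)
  if (any(gene_has_na)) m <- m[, !gene_has_na, drop = FALSE]
  sample_has_na <- apply(m, 1, anyNA)
  if (any(sample_has_na)) m <- m[!sample_has_na, , drop = FALSE]
  message(sprintf("load_expression_matrix: dropped %d gene(s), %d sample(s) with missing values",
                  sum(gene_has_na), sum(sample_has_na)))
  if (nrow(m) == 0L || ncol(m) == 0L) {
    stop("empty matrix after missing-value filtering")
  }
  if (log10_transform) {
    if (min(m) <= 0) stop("log10 transform requires strictly positive values")
    m <- log10(m)
  }
  expression_compendium(m, scale = scale)
}

#' Write an expression compendium to a tab-separated file
#'
#' @param c An [expression_compendium()].
#' @param path Output path. Written samples x genes with a leading
#'   `sample_id` column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(c, path) {
  stopifnot(inherits(c, "expression_compendium"))
  df <- data.frame(sample_id = c$sample_ids, c$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize each gene to the range 0-1
#'
#' Maps every gene by `(x - min) / (max - min)` and records the per-gene
#' minima and maxima so the map can be inverted. Genes that are constant
#' across all samples map to 0 everywhere (the stored minimum restores
#' them on denormalization).
#'
#' @param c An [expression_compendium()] not already normalized.
#' @return A normalized [expression_compendium()] (`scale = "normalized01"`).
#' @export
normalize_per_gene <- function(c) {
  stopifnot(inherits(c, "expression_compendium"))
  if (c$scale == "normalized01") stop("compendium is already normalized")
  gmin <- apply(c$values, 2, min)
  gmax <- apply(c$values, 2, max)
  rng <- gmax - gmin
  denom <- ifelse(rng == 0, 1, rng)
  v <- sweep(sweep(c$values, 2, gmin, "-"), 2, denom, "/")
  expression_compendium(v, scale = "normalized01",
                        gene_min = gmin, gene_max = gmax,
                        prev_scale = c$scale)
}

#' Invert the per-gene 0-1 normalization
#'
#' @param c A normalized [expression_compendium()] carrying
#'   `gene_min`/`gene_max` metadata.
#' @return The compendium on its original scale. Round trips are exact
#'   for non-constant genes; constant genes recover their stored minimum.
#' @export
denormalize_per_gene <- function(c) {
  stopifnot(inherits(c, "expression_compendium"))
  if (c$scale != "normalized01") stop("compendium is not normalized")
  if (is.null(c$gene_min) || is.null(c$gene_max)) {
    stop("missing gene_min/gene_max metadata; cannot invert")
  }
  v <- denormalize_values(c$values, c$gene_min, c$gene_max)
  expression_compendium(v, scale = if (is.null(c$prev_scale)) "raw_counts" else c$prev_scale)
}

#' Map a matrix onto the 0-1 scale of a normalized compendium
#'
#' Applies a compendium's stored per-gene min/max to new samples (e.g. a
#' template experiment generated outside the compendium). Values are
#' clipped to `[0, 1]` since new samples can fall slightly outside the
#' compendium's observed range.
#'
#' @param c A normalized [expression_compendium()].
#' @param x Numeric matrix, samples x genes, on the compendium's original
#'   scale, with the same genes in the same order.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_with_compendium <- function(c, x) {
  stopifnot(inherits(c, "expression_compendium"),
            c$scale == "normalized01",
            identical(colnames(x), c$gene_ids))
  rng <- c$gene_max - c$gene_min
  denom <- ifelse(rng == 0, 1, rng)
  v <- sweep(sweep(x, 2, c$gene_min, "-"), 2, denom, "/")
  v[v < 0] <- 0
  v[v > 1] <- 1
  v
}

# inverse of the per-gene 0-1 map on a bare matrix
denormalize_values <- function(x, gene_min, gene_max) {
  rng <- gene_max - gene_min
  sweep(sweep(x, 2, rng, "*"), 2, gene_min, "+")
}

#' Split a compendium into training and validation sets
#'
#' @param c An [expression_compendium()].
#' @param fraction Training fraction in (0, 1); the training set has
#'   `floor(fraction * n)` samples, clamped so both sides are non-empty.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return A list with `train` and `validation` compendia (disjoint
#'   sample partition).
#' @export
split_train_validation <- function(c, fraction = 0.75, seed = 1L) {
  stopifnot(inherits(c, "expression_compendium"),
            fraction > 0, fraction < 1)
  n <- nrow(c$values)
  if (n < 2) stop("need at least 2 samples to split")
  n_train <- max(1L, min(n - 1L, as.integer(floor(fraction * n))))
  set.seed(seed)
  idx <- sample.int(n, n_train)
  subset_c <- function(i) {
    expression_compendium(c$values[i, , drop = FALSE], scale = c$scale,
                          gene_min = c$gene_min, gene_max = c$gene_max,
                          prev_scale = c$prev_scale)
  }
  list(train = subset_c(sort(idx)),
       validation = subset_c(sort(setdiff(seq_len(n), idx))))
}

#' Define a two-group template experiment
#'
#' The template experiment is the user's experiment of interest: a set of
#' samples with a control / perturbed design whose layout the background
#' simulation mirrors. The second factor level is treated as the
#' perturbed group in all downstream contrasts.
#'
#' @param experiment_id Identifier string.
#' @param sample_ids Character vector of sample identifiers.
#' @param group_labels Factor (or coercible) with exactly two non-empty
#'   levels over the samples; level order defines the contrast
#'   (second level minus first).
#' @param values Optional samples x genes matrix holding the template's
#'   expression on the original data scale. When absent, the samples are
#'   looked up in the compendium by id.
#' @return An object of class `template_experiment`.
#' @export
template_experiment <- function(experiment_id, sample_ids, group_labels,
                                values = NULL) {
  group_labels <- as.factor(group_labels)
  if (nlevels(group_labels) != 2L) {
    stop("template experiment needs exactly two groups")
  }
  if (any(table(group_labels) == 0L)) stop("both groups must be non-empty")
  if (length(group_labels) != length(sample_ids)) {
    stop("one group label per sample required")
  }
  if (!is.null(values)) {
    stopifnot(is.matrix(values), nrow(values) == length(sample_ids))
    rownames(values) <- sample_ids
  }
  structure(
    list(experiment_id = experiment_id,
         sample_ids = as.character(sample_ids),
         group_labels = group_labels,
         values = values),
    class = "template_experiment")
}

#' @export
print.template_experiment <- function(x, ...) {
  cat(sprintf("template_experiment '%s': %d samples (%s)\n",
              x$experiment_id, length(x$sample_ids),
              paste(sprintf("%s: %d", levels(x$group_labels),
                            table(x$group_labels)), collapse = ", ")))
  invisible(x)
}

#' Read template-experiment metadata from a two-column TSV
#'
#' @param path TSV with columns `sample_id` and `group`.
#' @param experiment_id Identifier for the template experiment.
#' @param compendium Optional compendium used to check that every sample
#'   id exists.
#' @return A [template_experiment()].
#' @export
read_template_metadata <- function(path, experiment_id = basename(path),
                                   compendium = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("metadata file needs 'sample_id' and 'group' columns")
  }
  if (!is.null(compendium)) {
    missing <- setdiff(df$sample_id, compendium$sample_ids)
    if (length(missing)) {
      stop("sample ids not in compendium: ", paste(missing, collapse = ", "))
    }
  }
  template_experiment(experiment_id, df$sample_id, df$group)
}

# template expression on the original scale: stored values, or rows of
# the (denormalized) compendium
template_values <- function(template, compendium) {
  if (!is.null(template$values)) return(template$values)
  missing <- setdiff(template$sample_ids, compendium$sample_ids)
  if (length(missing)) {
    stop("template samples not in compendium: ",
         paste(missing, collapse = ", "))
  }
  compendium$values[template$sample_ids, , drop = FALSE]
}
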
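#' Sample a latent location from the compendium's encoded distribution
#'
#' Fits an independent Gaussian per latent dimension (mean and sd of the
#' encoded compendium samples) and draws one latent vector from it. With
#' `method = "resample"` an encoded real sample is drawn instead.
#'
#' @param m A [train_vae()] model.
#' @param c The normalized [expression_compendium()] the model was
#'   trained on.
#' @param seed Integer seed.
#' @param method `"gaussian"` (default) or `"resample"`.
#' @return A latent vector of length `latent_dim`.
#' @export
sample_latent_location <- function(m, c, seed = 1L,
                                   method = c("gaussian", "resample")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "trained_latent_model"),
            inherits(c, "expression_compendium"))
  z <- encode_samples(m, c$values)
  set.seed(seed)
  if (method == "resample") {
    return(z[sample.int(nrow(z), 1L), ])
  }
  mu <- colMeans(z)
  sd <- apply(z, 2, stats::sd)
  stats::rnorm(ncol(z), mean = mu, sd = sd)
}

#' Translate encoded samples so their centroid lands on a target
#'
#' Adds the vector connecting the centroid of the encoded samples and
#' `target` to every row. The translation is exact: the shifted centroid
#' equals `target` and all pairwise differences between samples are
#' preserved to machine precision.
#'
#' @param encoded Samples x latent matrix.
#' @param target Latent vector.
#' @return Shifted samples x latent matrix.
#' @export
shift_latent <- function(encoded, target) {
  stopifnot(is.matrix(encoded), length(target) == ncol(encoded))
  centroid <- colMeans(encoded)
  sweep(encoded, 2, target - centroid, "+")
}

#' Shift a template experiment to a new latent location and decode
#'
#' Encodes the template samples, translates them so their latent centroid
#' sits at `target` (preserving their relative positioning), and decodes
#' the shifted points back to expression space. This simulates an
#' experiment with the template's design but different biology.
#'
#' @param m A [train_vae()] model.
#' @param t_norm Template samples x genes matrix on the normalized 0-1
#'   scale.
#' @param target Latent vector of length `latent_dim`.
#' @return Decoded samples x genes matrix in `[0, 1]`, with the shifted
#'   latent coordinates attached as attribute `"latent"`.
#' @export
shift_template_experiment <- function(m, t_norm, target) {
  stopifnot(inherits(m, "trained_latent_model"),
            length(target) == m$config$latent_dim)
  enc <- encode_samples(m, t_norm)
  shifted <- shift_latent(enc, target)
  out <- decode_latent(m, shifted)
  rownames(out) <- rownames(t_norm)
  attr(out, "latent") <- shifted
  out
}

#' Simulate a background set of experiments from a template
#'
#' Draws `n_sim` independent latent targets from the compendium's encoded
#' distribution and produces one simulated experiment per target by
#' latent-shifting the encoded template samples and decoding. Each
#' simulated experiment has the template's sample count and group labels.
#' By default the decoded 0-1 values are denormalized back to the
#' compendium's original scale so differential expression on template and
#' background is comparable.
#'
#' @param m A [train_vae()] model.
#' @param template A [template_experiment()]. Its expression is taken
#'   from its own `values` (original scale, normalized with the
#'   compendium's per-gene min/max) or looked up in the compendium.
#' @param c The normalized [expression_compendium()] used for training.
#' @param n_sim Number of simulated experiments (default 25).
#' @param seed Master seed; per-experiment sub-seeds are derived from it.
#' @param denormalize Return experiments on the original data scale
#'   (default) rather than the normalized 0-1 scale.
#' @param method Latent sampling method, see [sample_latent_location()].
#' @return An object of class `simulated_experiment_set`: list of
#'   expression matrices, the latent target per experiment, the group
#'   labels, `n_sim` and `seed`.
#' @export
simulate_background_set <- function(m, template, c, n_sim = 25L, seed = 1L,
                                    denormalize = TRUE,
                                    method = c("gaussian", "resample")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "trained_latent_model"),
            inherits(template, "template_experiment"),
            inherits(c, "expression_compendium"))
  if (n_sim < 1L) stop("n_sim must be at least 1")
  if (c$scale != "normalized01") {
    stop("simulate_background_set needs the normalized compendium the model was trained on")
  }
  if (is.null(template$values)) {
    t_norm <- c$values[template$sample_ids, , drop = FALSE]
  } else {
    t_norm <- normalize_with_compendium(c, template$values)
  }
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_sim)
  # fit the latent distribution once; each draw below matches
  # sample_latent_location(m, c, seed = sub_seeds[i]) exactly
  z_comp <- encode_samples(m, c$values)
  z_mu <- colMeans(z_comp)
  z_sd <- apply(z_comp, 2, stats::sd)
  targets <- matrix(NA_real_, n_sim, m$config$latent_dim)
  experiments <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    set.seed(sub_seeds[i])
    target <- if (method == "resample") {
      z_comp[sample.int(nrow(z_comp), 1L), ]
    } else {
      stats::rnorm(ncol(z_comp), mean = z_mu, sd = z_sd)
    }
    targets[i, ] <- target
    x <- shift_template_experiment(m, t_norm, target)
    attr(x, "latent") <- NULL
    if (denormalize) x <- denormalize_values(x, c$gene_min, c$gene_max)
    experiments[[i]] <- x
  }
  structure(
    list(experiments = experiments,
         latent_targets = targets,
         group_labels = template$group_labels,
         template_id = template$experiment_id,
         n_sim = as.integer(n_sim),
         seed = as.integer(seed),
         sub_seeds = sub_seeds,
         scale = if (denormalize) "original" else "normalized01"),
    class = "simulated_experiment_set")
}

#' @export
print.simulated_experiment_set <- function(x, ...) {
  cat(sprintf(
    "simulated_experiment_set: %d experiments of %d samples x %d genes (template '%s', %s scale)\n",
    x$n_sim, nrow(x$experiments[[1]]), ncol(x$experiments[[1]]),
    x$template_id, x$scale))
  invisible(x)
}

#' Write a simulated experiment set to a directory
#'
#' One TSV per experiment plus a manifest TSV (experiment index, seed,
#' latent target).
#'
#' @param s A [simulate_background_set()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_simulated_experiments <- function(s, dir) {
  stopifnot(inherits(s, "simulated_experiment_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(s$n_sim)) {
    df <- data.frame(sample_id = rownames(s$experiments[[i]]),
                     group = s$group_labels,
                     s$experiments[[i]], check.names = FALSE,
                     row.names = NULL)
    utils::write.table(df, file.path(dir, sprintf("simulated_%03d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- data.frame(experiment = seq_len(s$n_sim),
                         seed = s$sub_seeds,
                         latent_target = apply(s$latent_targets, 1, paste,
                                               collapse = ","))
  mp <- file.path(dir, "simulation_manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mp)
}
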
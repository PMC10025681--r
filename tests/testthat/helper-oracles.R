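# Independent brute-force oracles used to validate the package's
# statistical primitives. These are deliberately naive implementations
# kept free of the code paths they check.

# Benjamini-Hochberg step-up applied literally: sort ascending, compute
# p * m / i, enforce monotonicity from the largest p downwards, clip at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Upper-tail hypergeometric P(overlap >= k) by direct summation of
# choose() terms: K selected from a universe of N containing m set genes.
oracle_hyper <- function(k, m, N, K) {
  upper <- min(m, K)
  if (k > upper) return(0)
  sum(vapply(k:upper, function(i) {
    choose(m, i) * choose(N - m, K - i)
  }, numeric(1))) / choose(N, K)
}

# GSEA running-sum enrichment score by an explicit loop.
oracle_es <- function(stats, gene_set, weight_exponent = 1) {
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  hit <- names(s) %in% gene_set
  nr <- sum(abs(s[hit])^weight_exponent)
  if (nr == 0) {
    inc <- rep(1 / sum(hit), sum(hit))
  } else {
    inc <- unname(abs(s[hit])^weight_exponent / nr)
  }
  dec <- 1 / (length(s) - sum(hit))
  run <- 0
  mx <- 0
  mn <- 0
  j <- 0
  for (i in seq_along(s)) {
    if (hit[i]) {
      j <- j + 1
      run <- run + inc[j]
    } else {
      run <- run - dec
    }
    if (run > mx) mx <- run
    if (run < mn) mn <- run
  }
  # same documented tie-break as the package: positive on a two-sided tie
  if (mx >= -mn - 1e-12) mx else mn
}

# Exact one-sided signed-rank p-value P(W >= w_obs) by enumerating all
# 2^n sign assignments over the ranks of |d| (no zeros, no tied |d|).
oracle_signrank_greater <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- as.matrix(signs) %*% r
  mean(w_all >= w_obs)
}

# Small random expression compendium with a low-rank factor structure,
# for VAE behaviour tests.
make_factor_compendium <- function(n_samples, n_genes, n_factors = 3,
                                   noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  scores <- matrix(rnorm(n_samples * n_factors), n_samples)
  loadings <- matrix(rnorm(n_factors * n_genes), n_factors)
  x <- scores %*% loadings + rnorm(n_samples * n_genes, sd = noise_sd)
  x <- apply(x, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  dimnames(x) <- list(sprintf("s%03d", seq_len(n_samples)),
                      sprintf("g%03d", seq_len(n_genes)))
  expression_compendium(x, scale = "normalized01",
                        gene_min = apply(x, 2, min),
                        gene_max = apply(x, 2, max))
}

# A small trained model shared by simulator/geometry tests (trained once
# per test run; small enough to take a couple of seconds).
shared_small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      comp <- make_factor_compendium(80, 40, seed = 42)
      cfg <- vae_config(hidden_dim = 24L, latent_dim = 4L, epochs = 15L,
                        batch_size = 10L, seed = 7L)
      cache <<- list(model = train_vae(comp, cfg), compendium = comp)
    }
    cache
  }
})

# Write a samples x genes matrix as the TSV layout load_expression_matrix
# expects; returns the path.
write_tsv_matrix <- function(m, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
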
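#' Variational autoencoder configuration
#'
#' Architecture and training settings for the expression VAE:
#' input -> dense(hidden_dim, ReLU) -> (mu, log sigma^2) of size
#' `latent_dim`; the decoder mirrors the encoder with a sigmoid output so
#' decoded values respect the 0-1 per-gene normalization. The loss is
#' binary cross-entropy reconstruction plus a KL term whose weight ramps
#' up from 0 by `kl_warmup_rate` per epoch, capped at 1 (KL warmup, which
#' protects against posterior collapse early in training).
#'
#' @param hidden_dim Hidden layer width (default 2500).
#' @param latent_dim Latent dimensionality (default 30).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 10).
#' @param kl_warmup_rate Per-epoch increment of the KL weight (default 0.01).
#' @param epochs Training epochs.
#' @param train_fraction Training fraction of the 75:25-style split.
#' @param seed Integer seed controlling initialization, the split, epoch
#'   shuffling and the reparameterization noise.
#' @return An object of class `vae_config`.
#' @export
vae_config <- function(hidden_dim = 2500L, latent_dim = 30L,
                       learning_rate = 0.001, batch_size = 10L,
                       kl_warmup_rate = 0.01, epochs = 40L,
                       train_fraction = 0.75, seed = 1L) {
  stopifnot(hidden_dim > latent_dim, latent_dim >= 1,
            kl_warmup_rate > 0, kl_warmup_rate <= 1,
            learning_rate > 0, batch_size >= 1, epochs >= 1,
            train_fraction > 0, train_fraction < 1)
  structure(
    list(hidden_dim = as.integer(hidden_dim),
         latent_dim = as.integer(latent_dim),
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         kl_warmup_rate = kl_warmup_rate,
         epochs = as.integer(epochs),
         train_fraction = train_fraction,
         seed = as.integer(seed)),
    class = "vae_config")
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform initialization for one dense layer
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

vae_init_params <- function(n_genes, hidden, latent) {
  list(W1 = glorot(n_genes, hidden), b1 = numeric(hidden),
       W2 = glorot(hidden, latent), b2 = numeric(latent),
       W3 = glorot(hidden, latent), b3 = numeric(latent),
       W4 = glorot(latent, hidden), b4 = numeric(hidden),
       W5 = glorot(hidden, n_genes), b5 = numeric(n_genes))
}

# forward pass; eps = NULL uses the posterior mean (deterministic)
vae_forward <- function(p, x, eps = NULL) {
  h <- relu(sweep(x %*% p$W1, 2, p$b1, "+"))
  mu <- sweep(h %*% p$W2, 2, p$b2, "+")
  lv <- sweep(h %*% p$W3, 2, p$b3, "+")
  lv <- pmin(pmax(lv, -10), 10) # keep exp(lv) well-conditioned
  z <- if (is.null(eps)) mu else mu + exp(lv / 2) * eps
  h2 <- relu(sweep(z %*% p$W4, 2, p$b4, "+"))
  logits <- sweep(h2 %*% p$W5, 2, p$b5, "+")
  xhat <- sigmoid(logits)
  list(h = h, mu = mu, lv = lv, z = z, h2 = h2, xhat = xhat)
}

# mean per-sample loss: BCE summed over genes + beta * KL
vae_loss_parts <- function(x, fw, beta) {
  ph <- pmin(pmax(fw$xhat, 1e-7), 1 - 1e-7)
  bce <- -sum(x * log(ph) + (1 - x) * log(1 - ph)) / nrow(x)
  kl <- -0.5 * sum(1 + fw$lv - fw$mu^2 - exp(fw$lv)) / nrow(x)
  c(loss = bce + beta * kl, bce = bce, kl = kl)
}

# gradients of the mean loss wrt all parameters
vae_backward <- function(p, x, fw, eps, beta) {
  B <- nrow(x)
  dlogit <- (fw$xhat - x) / B
  gW5 <- crossprod(fw$h2, dlogit); gb5 <- colSums(dlogit)
  dh2 <- tcrossprod(dlogit, p$W5)
  dh2[fw$h2 <= 0] <- 0
  gW4 <- crossprod(fw$z, dh2); gb4 <- colSums(dh2)
  dz <- tcrossprod(dh2, p$W4)
  dmu <- dz + beta * fw$mu / B
  dlv <- dz * eps * 0.5 * exp(fw$lv / 2) + beta * 0.5 * (exp(fw$lv) - 1) / B
  gW2 <- crossprod(fw$h, dmu); gb2 <- colSums(dmu)
  gW3 <- crossprod(fw$h, dlv); gb3 <- colSums(dlv)
  dh <- tcrossprod(dmu, p$W2) + tcrossprod(dlv, p$W3)
  dh[fw$h <= 0] <- 0
  gW1 <- crossprod(x, dh); gb1 <- colSums(dh)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3,
       W4 = gW4, b4 = gb4, W5 = gW5, b5 = gb5)
}

adam_update <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  for (k in names(p)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * g[[k]]^2
    mhat <- st$m[[k]] / (1 - beta1^t)
    vhat <- st$v[[k]] / (1 - beta2^t)
    p[[k]] <- p[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, st = st)
}

#' Train the expression VAE on a normalized compendium
#'
#' Trains on a seeded train/validation split of the compendium and
#' records the deterministic (posterior-mean) training and validation
#' loss after every epoch. Identical compendium, configuration and seed
#' reproduce identical loss traces and parameters.
#'
#' @param c A normalized [expression_compendium()]
#'   (`scale = "normalized01"`).
#' @param config A [vae_config()].
#' @return An object of class `trained_latent_model` with elements
#'   `config`, `params`, `loss` (data frame: epoch, beta, train_loss,
#'   val_loss) and `gene_ids`.
#' @export
train_vae <- function(c, config = vae_config()) {
  stopifnot(inherits(c, "expression_compendium"),
            inherits(config, "vae_config"))
  if (c$scale != "normalized01") {
    stop("train_vae needs a 0-1 normalized compendium; run normalize_per_gene() first")
  }
  n <- nrow(c$values)
  if (n < 2L * config$batch_size) {
    stop("need at least 2 * batch_size samples to train")
  }
  sp <- split_train_validation(c, config$train_fraction, config$seed)
  xtr <- sp$train$values
  xval <- sp$validation$values

  set.seed(config$seed)
  p <- vae_init_params(ncol(xtr), config$hidden_dim, config$latent_dim)
  st <- list(m = lapply(p, function(w) w * 0),
             v = lapply(p, function(w) w * 0))
  trace <- data.frame(epoch = integer(0), beta = numeric(0),
                      train_loss = numeric(0), val_loss = numeric(0))
  t_step <- 0L
  ntr <- nrow(xtr)
  for (epoch in seq_len(config$epochs)) {
    beta <- min(1, (epoch - 1L) * config$kl_warmup_rate)
    ord <- sample.int(ntr)
    starts <- seq(1L, ntr, by = config$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, ntr)]
      xb <- xtr[idx, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(idx) * config$latent_dim),
                    length(idx), config$latent_dim)
      fw <- vae_forward(p, xb, eps)
      g <- vae_backward(p, xb, fw, eps, beta)
      t_step <- t_step + 1L
      upd <- adam_update(p, g, st, config$learning_rate, t_step)
      p <- upd$p; st <- upd$st
    }
    tl <- vae_loss_parts(xtr, vae_forward(p, xtr), beta)[["loss"]]
    vl <- vae_loss_parts(xval, vae_forward(p, xval), beta)[["loss"]]
    if (!is.finite(tl) || !is.finite(vl)) {
      stop("non-finite loss at epoch ", epoch, "; reduce the learning rate")
    }
    trace <- rbind(trace, data.frame(epoch = epoch, beta = beta,
                                     train_loss = tl, val_loss = vl))
  }
  structure(
    list(config = config, params = p, loss = trace, gene_ids = c$gene_ids),
    class = "trained_latent_model")
}

#' @export
print.trained_latent_model <- function(x, ...) {
  cat(sprintf(
    "trained_latent_model: %d genes -> %d hidden -> %d latent; %d epochs (final val loss %.3f)\n",
    length(x$gene_ids), x$config$hidden_dim, x$config$latent_dim,
    nrow(x$loss), utils::tail(x$loss$val_loss, 1)))
  invisible(x)
}

#' Encode samples into the latent space
#'
#' Returns the encoder's posterior mean for each sample, which makes
#' encoding (and hence simulation) deterministic. Set
#' `stochastic = TRUE` to draw from the posterior instead.
#'
#' @param m A [train_vae()] model.
#' @param x Samples x genes matrix on the normalized 0-1 scale whose
#'   columns match the genes the model was trained on.
#' @param stochastic Draw `mu + sigma * eps` instead of `mu`.
#' @param seed Seed for the stochastic draw.
#' @return Matrix with one row per sample and `latent_dim` columns.
#' @export
encode_samples <- function(m, x, stochastic = FALSE, seed = 1L) {
  stopifnot(inherits(m, "trained_latent_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (!identical(colnames(x), m$gene_ids)) {
    stop("columns of 'x' must match the genes the model was trained on")
  }
  if (min(x) < -1e-8 || max(x) > 1 + 1e-8) {
    stop("encode_samples expects values on the normalized 0-1 scale")
  }
  eps <- NULL
  if (stochastic) {
    set.seed(seed)
    eps <- matrix(stats::rnorm(nrow(x) * m$config$latent_dim),
                  nrow(x), m$config$latent_dim)
  }
  fw <- vae_forward(m$params, x, eps)
  z <- fw$z
  rownames(z) <- rownames(x)
  z
}

#' Decode latent points back to expression space
#'
#' @param m A [train_vae()] model.
#' @param z Matrix with `latent_dim` columns.
#' @return Samples x genes matrix with all values in `[0, 1]` (sigmoid
#'   output); deterministic.
#' @export
decode_latent <- function(m, z) {
  stopifnot(inherits(m, "trained_latent_model"))
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  if (ncol(z) != m$config$latent_dim) {
    stop("'z' must have latent_dim = ", m$config$latent_dim, " columns")
  }
  p <- m$params
  h2 <- relu(sweep(z %*% p$W4, 2, p$b4, "+"))
  xhat <- sigmoid(sweep(h2 %*% p$W5, 2, p$b5, "+"))
  colnames(xhat) <- m$gene_ids
  rownames(xhat) <- rownames(z)
  xhat
}

#' Write the per-epoch loss trace as TSV
#'
#' @param m A [train_vae()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loss_trace <- function(m, path) {
  stopifnot(inherits(m, "trained_latent_model"))
  utils::write.table(m$loss, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
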
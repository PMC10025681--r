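---
title: "Separating common from specific differential expression with a generative background"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating common from specific differential expression with a generative background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(despec)
```

## The problem

Some genes respond to almost any perturbation — stress programs, growth
arrest, ribosome biogenesis. A two-group differential expression (DE)
analysis returns these *common* DEGs mixed together with the genes that
are *specific* to the condition under study, and only the specific ones
carry contextual information. Historically, separating the two required
manually curating hundreds of control experiments, re-running DE on each,
and counting how often every gene appears.

despec automates the control set. A variational autoencoder (VAE) is
trained on a large, uncurated expression compendium. The user's *template
experiment* (control vs. perturbed) is encoded into the VAE's latent
space and translated to randomly sampled latent locations — "the same
experimental design, different biology". Decoding each translated copy
yields a simulated background experiment; DE run on template and
background alike turns every gene's background log2 fold changes into an
empirical null.

## The scores

For gene $g$ with template log2 fold change $t_g$ and simulated fold
changes $s_{g1}, \dots, s_{gB}$ over $B$ background experiments
(default $B = 25$):

* **specificity z-score**
  $z_g = \dfrac{t_g - \bar{s}_g}{\max(\mathrm{sd}(s_g), \varepsilon)}$.
  A large $z_g$ means the template moved the gene far beyond anything the
  background produces; a $z_g$ near 0 marks a commonly changed gene.
* **commonness percentile**: genes are ranked ascending by
  $\mathrm{median}_b\,|s_{gb}|$ and the ranks are scaled linearly to
  $[0, 100]$ (average ranks on ties). High percentile = commonly changed.

The z-score denominator deserves a note. The score is sometimes written
with the *variance* of the simulated fold changes in the denominator;
that form is not unit-consistent (the score would change under a simple
rescaling of the data), and it over-rewards genes whose background
variance happens to be tiny: in our spike-in benchmark it visibly
scrambles the ranking of the known specific genes, while the
standard-deviation form recovers them cleanly. despec therefore
standardizes by the standard deviation by default and keeps
`denominator = "variance"` available for comparison. The floor
$\varepsilon$ (`var_floor`, default $10^{-8}$) only protects genes that
are flat across every simulation.

The template's fold changes are computed from the template's *measured*
data (not its VAE reconstruction), so the specificity score compares real
signal against simulated background.

## The generative model

The VAE is deliberately plain: input → dense(ReLU, 2500 units) →
$(\mu, \log\sigma^2)$ of dimension 30, mirrored decoder with a sigmoid
output. The sigmoid matches the per-gene 0–1 normalization applied to the
compendium (each gene mapped by $(x - \min)/(\max - \min)$, constant
genes to 0; the stored minima/maxima make the map invertible, and
simulated experiments are mapped back to the original scale before DE so
template and background fold changes are comparable). Training uses
binary cross-entropy reconstruction plus a KL term, Adam at learning rate
0.001, batch size 10, and a 75:25 train/validation split. The KL weight
warms up by 0.01 per epoch (capped at 1), starting at 0 — warmup protects
against posterior collapse; a per-epoch (rather than per-batch) increment
is the most conservative reading of a "0.01 warmup" and is configurable
via `kl_warmup_rate`. Encoding returns the posterior mean so that
simulation is deterministic; stochastic encoding sits behind a flag.

Latent locations for the background are drawn from an independent
Gaussian per latent dimension, fitted to the encoded compendium
(`sample_latent_location()`); a "resample an encoded real sample" mode is
also provided. The latent translation itself is exact arithmetic: the
shifted centroid equals the sampled target and all pairwise differences
between the template's encoded samples are preserved to machine
precision — the simulation changes *where* the experiment lives, never
its internal geometry.

## Differential expression

Two-group testing uses an empirical-Bayes moderated t: per-gene pooled
variances $s_g^2$ with $d_g = n_1 + n_2 - 2$ degrees of freedom are
shrunk toward a prior $(d_0, s_0^2)$ estimated from all genes by
method-of-moments on $\log s_g^2$ (digamma/trigamma inversion), giving
posterior variances $(d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and $d_0 + d_g$
degrees of freedom for the two-sided p-value; p-values are
Benjamini–Hochberg adjusted and DEGs called at strict `p_adj < 0.05` and
`|log2FC| > 1`. Count-scale inputs (including the denormalized simulated
experiments) are transformed with $\log_2(x + 1)$ first, which keeps one
consistent log-scale path for template and background; count-model
dispersion estimation is out of scope by design. Zero-variance genes are
floored at $10^{-10}$ before pooling so degenerate simulated genes cannot
produce infinite statistics. A `prior = "pooled"` fallback
($s_0^2 = \overline{s^2}$, $d_0 = 10$) exists for very small gene sets
where the moment fit is unstable.

## Pathway level

`gsea_significance()` scores gene sets with the preranked running-sum
enrichment score (hits add $|t|^p/\sum_S |t|^p$, misses subtract
$1/(N - |S|)$; the ES is the signed maximal deviation, with an exact
two-sided tie resolving positive). Significance comes from a *gene-set
permutation* null: random same-size sets are rescored and
$p = (1 + \#\{|ES_\text{null}| \ge |ES_\text{obs}|\})/(B + 1)$. Phenotype
permutation is the textbook alternative, but simulated experiments carry
only a handful of samples (the template's design), which makes label
permutation degenerate; random gene sets keep the null well-defined at
any sample size. `ora_hypergeometric()` provides the upper-tail
hypergeometric over-representation test, and `pathway_percentile()`
ranks sets by their median BH-adjusted p across simulations (smaller
median = more commonly enriched = higher percentile).

## The spike-in benchmark

`generate_benchmark_compendium()` builds the fully self-contained
validation data: 90 experiments × 8 samples (4 control + 4 perturbed) ×
1000 genes of negative-binomial counts, plus one template generated by
the identical recipe. Each gene draws a success rate uniformly from
(0.1, 0.9) (dispersion fixed at size 2 — neither is dictated by anything
beyond realism, so both are configurable spec fields); 100 genes are
*common* (spiked in every experiment) and each experiment additionally
spikes its own 10 *specific* genes drawn independently from the 900
non-common genes. The spike ("scaler") is additive on the count scale in
the perturbed samples only, and equals the 98th quantile of the
experiment's per-gene median expression, computed before spiking.

`run_method_comparison()` runs the whole pipeline on this compendium —
normalize, train a reduced VAE (hidden 250, latent 10, 20 epochs; sized
so one run takes well under a minute on one CPU while the full-size
architecture stays available), simulate 25 background experiments,
moderated-t DE everywhere, z-scores — and ranks every gene by z-score
(specificity ranking) and by template log2FC (traditional ranking). The
ground truth fixes the expectation: the traditional ranking cannot
distinguish common from specific spikes (both received the same scaler),
while the specificity ranking should demote common genes (the background
reproduces their change) and keep specific genes on top.
`compare_benchmark_rankings()` tests both directions with a paired
Wilcoxon signed-rank test (exact null for ≤ 25 untied differences,
tie-corrected normal approximation otherwise).

## Numerical and design choices

* Loading drops genes with missing values before samples; gene-first
  retains more samples.
* A separately generated template is normalized with the *compendium's*
  per-gene ranges, clipped to $[0, 1]$, since a new experiment can fall
  slightly outside the training range.
* One master seed drives each stage; sub-seeds for the per-experiment
  latent draws are derived from it, so any single simulated experiment
  can be regenerated independently.
* The training loss trace is recorded deterministically (posterior mean,
  current KL weight) after every epoch; identical data, configuration
  and seed reproduce identical traces and parameters.
* `vae_config()` validates `hidden_dim > latent_dim ≥ 1` and
  `0 < kl_warmup_rate ≤ 1`; log-variances are clamped to ±10 to keep
  the KL term well-conditioned.

## What the synthetic data does and does not show

The factor-structured compendia used in the unit tests and the
negative-binomial benchmark exercise the full pipeline with known ground
truth, but they are idealized: spikes are purely additive, experiments
are independent (no batch structure, no platform effects), and every
experiment shares one design. Passing them demonstrates that the
machinery — normalization round trips, latent geometry, DE calibration,
the directional separation of common and specific spike-ins — behaves as
specified; it does not demonstrate that a particular real compendium is
large or diverse enough for the VAE to model well. On real data the
validation loss trace, the reconstruction quality and the robustness of
percentiles to `n_sim` (on the benchmark, percentiles from 25 vs. 50
simulations agree with Spearman ρ > 0.95) are the practical diagnostics.

## Problem sizes

The shipped tests train small VAEs (tens of hidden units, ≤ 25 epochs)
on compendia of 40–200 samples, and run the benchmark at its native 720 ×
1000 size with the reduced VAE; the whole suite completes in minutes on a
single CPU. These sizes are the package's own defaults for its synthetic
studies; real compendia (tens of thousands of samples) use the full-size
configuration and simply take longer.

## Known limitations

* Two-group templates only; time courses and multi-factor designs would
  need a different DE layer and a notion of "same design" for the
  simulator.
* The latent shift is a random translation; it cannot target a specific
  axis of variation (tissue, drug class), so the background is "any
  other biology", not a chosen contrast.
* VAEs shrink variance toward the data manifold; genes far outside the
  compendium's distribution can be reconstructed poorly, which is why
  percentile ranks (not raw background fold changes) are the primary
  commonness readout.
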
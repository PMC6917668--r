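---
title: "Integrative variational autoencoders for multi-omic data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative variational autoencoders for multi-omic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intvae)
```

## The problem

Cancer cohorts are increasingly profiled on several scales at once: bulk mRNA
expression, somatic copy-number aberrations (CNA), and clinical covariates.
Each modality alone carries part of the signal that distinguishes disease
subtypes; methods that analyze the silos separately cannot exploit the
dependencies between them. `intvae` implements *full (early) integration* of
such data with variational autoencoders (VAEs): heterogeneous sample-by-feature
blocks are fused into a single low-dimensional latent embedding, learned
without labels, which downstream classifiers (or clustering, survival models,
etc.) then consume.

## The model

A VAE assumes each sample $x$ arises from a latent vector
$z \in \mathbb{R}^{L}$ with standard-normal prior $p(z) = N(0, I)$. An encoder
network outputs the parameters of a diagonal-Gaussian approximate posterior
$q_\phi(z \mid x) = N(\mu(x), \operatorname{diag}(\sigma^2(x)))$, and a decoder
maps $z$ back to a reconstruction of $x$. Per mini-batch the objective is

$$
\mathcal{L} \;=\; \sum_{m} \mathcal{L}^{\text{recon}}_m \;+\; \beta \, D\!\left(q_\phi \,\|\, p\right),
$$

with one reconstruction term per modality $m$ — mean squared error through a
linear output for continuous blocks, binary cross entropy through a sigmoid
output for categorical blocks — and a weighted divergence $D$ that pulls the
encoding distribution toward the prior. Two regularizers are provided:

* **KL**: the closed form for diagonal Gaussians,
  $\tfrac12 \sum_j \left(\mu_j^2 + e^{\lambda_j} - 1 - \lambda_j\right)$ with
  $\lambda_j = \log \sigma_j^2$, averaged over the batch.
* **MMD**: the Maximum Mean Discrepancy between codes
  $z = \mu + \sigma \odot \epsilon$ sampled via the reparameterization trick and
  fresh draws from $N(0, I)$, under the Gaussian kernel
  $k(z, z') = \exp(-\|z - z'\|^2 / 2\sigma_k^2)$. We use the biased V-statistic
  (diagonal terms included), which is nonnegative and exactly zero on identical
  sets.

Ordinal CNA-like states are handled by *label smoothing*: the $S$ ordered
states are mapped to equally spaced values $0, \tfrac{1}{S-1}, \dots, 1$ and
scored by cross entropy as soft Bernoulli targets. This keeps an $S$-state
feature one column wide instead of exploding into $S$ one-hot columns.

## The four architectures

All four share one contract — `encode()` returns the posterior means,
`reconstruct()` per-modality matrices of the original widths,
`sample_generative()` decodes prior draws — and differ only in where
integration happens:

* **CNC-VAE** (`build_cnc_vae`): modalities concatenated at the input; one
  shared hidden block on each side; the wide reconstruction is sliced back
  into modality blocks, each scored by its own loss.
* **X-VAE** (`build_x_vae`): one encoder branch per modality, merged into the
  bottleneck; the decoder runs a shared hidden block and splits into
  per-modality branches.
* **MM-VAE** (`build_mm_vae`): like X, but each branch's *second* hidden layer
  receives the concatenation of all branches' first-layer outputs, so
  higher-level concepts are exchanged across modalities before the bottleneck.
  Its encoder is exactly one layer deeper than X's.
* **H-VAE** (`build_h_vae`, `train_hierarchical`): one low-level VAE per
  modality is trained first; their posterior means are concatenated and a
  high-level VAE is trained on that matrix with a squared-error target,
  yielding the final embedding. Training cost is roughly $(M+1)\times$ a
  single VAE.

Hidden blocks are ordered dense → batch normalization → ELU → dropout; the
bottleneck ($\mu$, $\log\sigma^2$) and output layers are plain dense layers
(plus sigmoid where the modality demands it). The component list is fixed by
the training protocol; their *order* within a block was an open choice and we
use the common "normalize before activation" convention.

## Parameters that matter

| parameter | default | grid | meaning |
|---|---|---|---|
| `latent_size` | 64 | 16 / 32 / 64 | embedding dimension $L$ |
| `dense_size` | 256 | 128 / 256 / 512 | units per hidden dense layer |
| `regularizer` | MMD | KL / MMD | divergence $D$ |
| `beta` | 50 | 1 / 10 / 15 / 25 / 50 / 100 | weight of $D$ |
| `dropout` | 0.2 | — | hidden-layer dropout rate |
| `epochs` | 150 | — | Adam epochs |
| `learning_rate` | 0.001 | — | Adam step size ($\beta_1 = 0.9$, $\beta_2 = 0.999$) |
| `batch_size` | 64 | — | mini-batch size (final short batch kept) |

The full grid is $3 \times 3 \times 2 \times 6 = 108$ configurations per
architecture per task (`enumerate_grid()`), i.e. $4 \times 3 \times 108 = 1296$
for four architectures on three integration tasks. `run_config_grid()` sweeps
it with a Gaussian naive Bayes probe — chosen precisely because it has no
hyperparameters of its own — and `select_configuration()` picks the
test-accuracy argmax with deterministic tie-breaks (smaller latent size, then
smaller dense size, then MMD before KL, then smaller $\beta$).

Numerical choices not fixed by the protocol, and how we resolved them:

* **Reconstruction reduction** is the *mean* over entries, not the sum, so one
  $\beta$ weighs comparably against modalities of different widths.
* **MMD bandwidth** defaults to $\sigma_k^2 = L/2$, the standard latent-scale
  heuristic; the prior sample count equals the batch size, drawn fresh each
  step.
* **Cross-entropy clipping** at $\varepsilon = 10^{-7}$; batch-norm uses
  momentum 0.9 and $\varepsilon = 10^{-3}$; Adam uses $\varepsilon = 10^{-8}$;
  weights are Glorot-uniform initialized from the config seed.
* **Constant columns** min-max scale to all zeros rather than being dropped, so
  feature indexing is stable.
* **Degenerate quantile bins** (ties, constants) collapse to the distinct
  edges with a warning; a constant column becomes a single all-ones indicator.
* **Mini-batch remainder** is kept; shuffling, dropout masks, reparameterization
  noise and prior draws all flow from the single config seed, which makes
  training bitwise-reproducible on one CPU thread.

## Evaluation protocol

Embedding quality is measured by stratified 5-fold cross-validated accuracy of
three fixed downstream classifiers (Gaussian naive Bayes; RBF-SVM with
$C = 1.5$, $\gamma = 1/N_f$; random forest with 50 trees and half the features
per split) against PCA (64 components) and raw-concatenation baselines.
Fold assignment is a pure function of (labels, fold count, seed) and is reused
across all methods, so every comparison sees identical splits.

By default the VAE is re-trained inside each fold on the training rows only
(`refit_per_fold = TRUE`), so no test-row values can influence the learned
representation — the leakage test asserts that corrupting test rows leaves the
trained parameters bit-identical. Whether an unsupervised representation may
be fit once on the whole cohort is a protocol question on which reasonable
studies differ; a `refit_per_fold = FALSE` mode is provided for parity with
the laxer convention, but all shipped results use the per-fold protocol.

## The synthetic generator

Real multi-omic cohorts cannot be redistributed with a package, so all tests
run on synthetic data with a *known* shared-latent structure
(`generate_multiomic()`): latent factors $h \in \mathbb{R}^k$ follow a mixture
of Gaussians whose component is the class; the continuous modality is
$\operatorname{logistic}(W_1 h + \epsilon)$; the categorical modality
thresholds $W_2 h + \epsilon$ into five ordinal states at marginal quantiles
and smooths them; the clinical modality quantile-discretizes
$W_3 h + \epsilon$ factors and one-hot expands them. Default shapes
(500 samples; 100/100/50 features) are one tenth of the emulated cohort scale
(1980 samples; 1000/1000/350); `metabric_scale = TRUE` restores the full
shapes. Loading matrices have normalized columns rescaled by
$\sqrt{d/k_{\text{visible}}}$ so that per-feature signal strength does not
shrink as the modality widens — with strictly unit-norm columns the
generator's difficulty would be an artifact of the chosen width. Class
centers sit $4$ within-class standard deviations apart by default, giving a
latent-space Bayes accuracy around 0.98 at the default noise
(`noise_sd = 0.1`, additive and pre-logistic).

`split_signal_scenario()` partitions the informative latent coordinates
between two modalities (fraction `signal_split` to the first), so each
modality alone supports strictly lower Bayes accuracy than both together —
the construction used to test that integration actually helps.

What the generator does *not* emulate: gene–gene correlation beyond the
low-rank factor structure, batch effects, missingness, survival outcomes, or
realistic marginal distributions of expression data. Passing tests therefore
demonstrate that the machinery is correct and that integration recovers
planted structure — not that any particular accuracy will transfer to a real
cohort.

## Problem sizes used by the shipped tests

The test suite and `scripts/acceptance.R` run at desk scale: contract checks
on $n = 200$, $d = (50, 50, 30)$; embedding-quality checks on $n = 500$,
$d = (100, 100, 50)$, latent size 16, dense size 128, with 25 training epochs
(40 for H-VAE, whose two-stage representation converges more slowly). These
sizes were chosen so the planted structure is comfortably learnable while a
full run stays in the minutes range; the 150-epoch default remains the
recommendation for real data.

## Known limitations

* Pure-R training loop: fine at desk scale and for cohort-scale batch sizes,
  but minutes-per-model at the full 1980 × 2350 scale; no GPU path.
* Two regularizers only (KL, MMD); no flexible priors or flows.
* The hierarchical model trains its stages greedily; no joint fine-tuning.
* Accuracy is plain (unbalanced) accuracy, by protocol; heavily skewed label
  tasks should be read with that in mind.
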
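# intvae

Integrative variational autoencoders (VAEs) for heterogeneous biomedical
data. `intvae` learns a single low-dimensional latent embedding from several
aligned sample-by-feature modalities at once — continuous expression-like
data, ordinal copy-number states, one-hot clinical indicators — and evaluates
how much of the biological signal that embedding retains.

It is aimed at computational biologists who want *early* (full) integration:
instead of modelling each data silo separately and merging conclusions, the
raw modalities are fused before any supervised analysis, and the shared
embedding is what downstream classifiers, clusterings or survival models see.

## The models

Four architectures are provided, all exposing the same contract
(`encode()`, `reconstruct()`, `sample_generative()`):

| id | integration point |
|---|---|
| `CNC` | modalities concatenated at the input layer; one shared objective |
| `X`   | per-modality encoder/decoder branches merged at the bottleneck |
| `MM`  | like X, but encoder branches exchange intermediate outputs one layer before the bottleneck |
| `H`   | one low-level VAE per modality; their embeddings feed a high-level VAE (two-stage training) |

Every model minimizes

```
L = sum_m recon_m  +  beta * D(q(z|x) || N(0, I))
```

with per-modality reconstruction losses (MSE for continuous blocks, binary
cross entropy with label smoothing for categorical blocks) and a weighted
divergence `D`: either the closed-form diagonal-Gaussian KL or the Maximum
Mean Discrepancy under a Gaussian kernel (biased V-statistic). Encoders emit
posterior means and log-variances; training uses the reparameterization
trick, Adam (lr 0.001, batch 64, 150 epochs by default), batch-norm + ELU +
dropout 0.2 hidden blocks, and is bitwise-reproducible from a single seed on
one CPU thread. The hyperparameter grid of the accompanying protocol —
latent size {16, 32, 64} x dense size {128, 256, 512} x {KL, MMD} x
beta {1, 10, 15, 25, 50, 100} — is built in (`enumerate_grid()`,
`run_config_grid()`, `select_configuration()`).

Because real multi-omic cohorts cannot ship with a package, `intvae` includes
a synthetic generator (`generate_multiomic()`) that plants a known
shared-latent class structure across three modalities with cohort-like
shapes, plus a split-signal scenario where no single modality suffices — the
test bed for every claim the package makes. See the vignette
(`vignettes/integrative-vaes.Rmd`) for the full model description and design
choices.

## Worked example

Generate a 500-sample synthetic cohort (100 expression-like, 100 copy-number,
50 clinical features; two classes driven by 4 shared latent factors), train an
X-shaped VAE per cross-validation fold, and compare its 16-d embedding against
PCA on the concatenated raw features:

```r
library(intvae)

gen    <- generate_multiomic(synthetic_spec(seed = 1))
ds     <- gen$dataset
labels <- ds$labels$class
folds  <- make_stratified_folds(labels, n_folds = 5, seed = 1)

cfg <- network_config("X", latent_size = 16, dense_size = 128,
                      regularizer = reg_spec("MMD", beta = 50),
                      epochs = 25, seed = 1)
vae <- cross_validated_accuracy(vae_embed_fn(ds, cfg), labels, folds)
pca <- cross_validated_accuracy(pca_embed_fn(raw_baseline(ds), k = 64),
                                labels, folds)
print(vae)
print(pca)
```

```
<grid_result> task 'task', gaussian-naive-bayes: mean test 0.942 (train 0.949)
<grid_result> task 'task', gaussian-naive-bayes: mean test 0.966 (train 0.971)
```

The 16-dimensional VAE embedding retains almost all of the class signal
carried by the 250 raw features (0.942 held-out accuracy, vs 0.966 for a
64-component PCA). On this generator PCA is a strong baseline — the planted
structure is a logistic transform of a linear factor model, exactly the
regime where a linear projection shines; the VAE matches it with a quarter of
the dimensions. The integrative value shows up in the split-signal scenario
(`split_signal_scenario()`), where neither modality alone suffices: there the
integrated X-VAE embedding scores 0.954 against 0.912 for the best single
modality (numbers from `scripts/acceptance.R --seed 1`).

A command-line wrapper covers the same workflow from a shell
(`inst/cli/intvae simulate | train | grid | evaluate`).

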
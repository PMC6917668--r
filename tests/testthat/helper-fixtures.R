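# Shared fixtures: all test data is generated in code at run time.

# Tiny three-modality dataset for fast contract tests.
tiny_dataset <- function(n = 60L, seed = 7L) {
  generate_multiomic(synthetic_spec(
    n_samples = n, latent_rank = 3L, n_classes = 2L,
    d_continuous = 12L, d_categorical = 10L, d_clinical = 10L,
    clinical_bins = 5L, seed = seed))$dataset
}

# Small, quick network configuration.
quick_config <- function(architecture, epochs = 2L, seed = 11L, ...) {
  network_config(architecture, latent_size = 4L, dense_size = 16L,
                 epochs = epochs, batch_size = 32L, seed = seed, ...)
}

# O(n^2) double-sum reference estimator for the biased MMD, written
# independently of the package implementation.
mmd_oracle <- function(Zq, Zp, sigma) {
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * sigma^2))
  term <- function(A, B) {
    s <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      s <- s + k(A[i, ], B[j, ])
    }
    s / (nrow(A) * nrow(B))
  }
  term(Zq, Zq) + term(Zp, Zp) - 2 * term(Zq, Zp)
}

expect_matrix <- function(x, nrow, ncol) {
  expect_true(is.matrix(x))
  expect_identical(dim(x), c(as.integer(nrow), as.integer(ncol)))
}
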
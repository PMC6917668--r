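archs <- c("CNC", "X", "MM", "H")

test_that("all four builders honour the shared model contract", {
  ds <- tiny_dataset()
  n <- n_samples(ds)
  for (a in archs) {
    cfg <- quick_config(a)
    model <- build_vae(ds$specs, cfg)
    expect_s3_class(model, "integrative_model")
    model <- train_vae(model, ds)

    expect_equal(nrow(model$loss_trace), cfg$epochs)
    emb <- encode(model, ds)
    expect_matrix(emb, n, cfg$latent_size)
    expect_identical(encode(model, ds), emb)  # no sampling at encode time

    rec <- reconstruct(model, ds)
    expect_named(rec, vapply(ds$specs, `[[`, character(1), "name"))
    for (s in ds$specs) {
      expect_matrix(rec[[s$name]], n, s$n_features)
      if (s$output_activation == "sigmoid") {
        expect_true(all(rec[[s$name]] > 0 & rec[[s$name]] < 1))
      }
    }

    # encoding follows input row order
    sub <- dataset_rows(ds, c(5, 1, 9))
    expect_equal(encode(model, sub), emb[c(5, 1, 9), ], ignore_attr = TRUE)
  }
})

test_that("the per-epoch loss trace decomposes into reconstruction and regularizer", {
  ds <- tiny_dataset()
  for (a in c("CNC", "X")) {
    cfg <- quick_config(a, epochs = 3,
                        regularizer = reg_spec("MMD", beta = 25))
    model <- train_vae(build_vae(ds$specs, cfg), ds)
    tr <- model$loss_trace
    mods <- vapply(ds$specs, `[[`, character(1), "name")
    expect_true(all(mods %in% colnames(tr)))
    recon_sum <- rowSums(tr[, mods, drop = FALSE])
    expect_equal(tr$total, recon_sum + 25 * tr$regularizer, tolerance = 1e-10)
  }
})

test_that("training is bitwise-reproducible under a fixed seed", {
  ds <- tiny_dataset()
  for (a in archs) {
    cfg <- quick_config(a, epochs = 2, seed = 123)
    m1 <- train_vae(build_vae(ds$specs, cfg), ds)
    m2 <- train_vae(build_vae(ds$specs, cfg), ds)
    expect_identical(intvae:::model_params(m1), intvae:::model_params(m2))
    expect_identical(m1$loss_trace, m2$loss_trace)
    expect_identical(encode(m1, ds), encode(m2, ds))
  }
})

test_that("architecture shapes follow the construction contracts", {
  ds <- tiny_dataset()
  cfg <- quick_config("X")
  M <- length(ds$specs)

  x <- build_x_vae(ds$specs, cfg)
  # branch outputs concatenate to M * dense_size before the bottleneck
  expect_equal(nrow(x$layers$mu$W), M * cfg$dense_size)

  mm <- build_mm_vae(ds$specs, quick_config("MM"))
  # each second-layer branch sees the concatenation of all first layers
  expect_equal(nrow(mm$layers$enc_h2_mrna$W), M * cfg$dense_size)
  expect_equal(encoder_depth(mm), encoder_depth(x) + 1L)

  cnc <- build_cnc_vae(ds$specs, quick_config("CNC"))
  d_tot <- sum(vapply(ds$specs, `[[`, integer(1), "n_features"))
  expect_equal(nrow(cnc$layers$enc_h$W), d_tot)
  expect_equal(ncol(cnc$layers$dec_out$W), d_tot)

  h <- build_h_vae(ds$specs, quick_config("H"))
  expect_equal(n_submodels(h), M + 1L)
  expect_equal(n_submodels(x), 1L)
  # high-level VAE consumes the concatenated low-level embeddings
  expect_equal(h$high$specs[[1]]$n_features, M * cfg$latent_size)

  expect_error(build_x_vae(ds$specs[1], cfg), ">= 2 modalities")
})

test_that("hierarchical stage two is reproducible on frozen low-level models", {
  ds <- tiny_dataset()
  cfg <- quick_config("H", epochs = 2, seed = 5)
  trained <- train_vae(build_h_vae(ds$specs, cfg), ds)
  # rebuild with the already-trained low-level models; only stage 2 reruns
  rerun <- train_hierarchical(build_h_vae(ds$specs, cfg,
                                          low_level_models = trained$low), ds)
  expect_identical(intvae:::model_params(rerun$high),
                   intvae:::model_params(trained$high))
  expect_identical(encode(rerun, ds), encode(trained, ds))
})

test_that("training reduces the objective on synthetic data", {
  ds <- tiny_dataset(n = 120, seed = 3)
  for (a in c("X", "H")) {
    cfg <- quick_config(a, epochs = 12, seed = 4)
    model <- train_vae(build_vae(ds$specs, cfg), ds)
    expect_lt(model$loss_trace$total[cfg$epochs], model$loss_trace$total[1])
  }
})

test_that("generative sampling respects shapes, bounds and the seed", {
  ds <- tiny_dataset()
  for (a in c("CNC", "H")) {
    model <- train_vae(build_vae(ds$specs, quick_config(a)), ds)
    out <- sample_generative(model, 7, seed = 3)
    for (s in ds$specs) {
      expect_matrix(out[[s$name]], 7, s$n_features)
      if (s$output_activation == "sigmoid") {
        expect_true(all(out[[s$name]] > 0 & out[[s$name]] < 1))
      }
    }
    expect_identical(sample_generative(model, 7, seed = 3), out)
    expect_false(identical(sample_generative(model, 7, seed = 4), out))
    expect_error(sample_generative(model, 0), "positive")
  }
})

test_that("an untrained model refuses to encode and oversized batches are rejected", {
  ds <- tiny_dataset()
  model <- build_vae(ds$specs, quick_config("X"))
  expect_error(encode(model, ds), "not trained")
  cfg <- quick_config("X")
  cfg$batch_size <- 1000L
  expect_error(train_vae(build_vae(ds$specs, cfg), ds), "batch_size")
})

test_that("a diverging objective aborts with a diagnostic naming the term", {
  ds <- tiny_dataset()
  cfg <- quick_config("X", epochs = 30)
  cfg$learning_rate <- 1e4  # force numerical blow-up
  expect_error(train_vae(build_vae(ds$specs, cfg), ds),
               "non-finite loss")
})

test_that("with no regularizer the VAE beats the best lower-rank linear reconstruction", {
  # noiseless linear-Gaussian data of true rank k; a nonlinear autoencoder
  # with latent size k should reconstruct better than the best rank-(k-1)
  # linear map (PCA), demonstrating capacity beyond linear compression
  set.seed(14)
  n <- 200; d <- 20; k <- 3
  H <- matrix(rnorm(n * k), n, k)
  W <- matrix(rnorm(d * k), d, k)
  X <- H %*% t(W)
  X <- (X - min(X)) / (max(X) - min(X))
  specs <- list(modality_spec("a", "continuous", d %/% 2),
                modality_spec("b", "continuous", d - d %/% 2))
  Xs <- list(a = X[, 1:(d %/% 2)], b = X[, (d %/% 2 + 1):d])
  cfg <- network_config("CNC", latent_size = k, dense_size = 32,
                        regularizer = reg_spec("KL", beta = 0),
                        dropout = 0, epochs = 200, batch_size = 64,
                        seed = 2)
  model <- train_vae(build_cnc_vae(specs, cfg), Xs)
  rec <- reconstruct(model, Xs)
  vae_err <- mean((cbind(rec$a, rec$b) - X)^2)

  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = k - 1, nv = k - 1)
  lin <- sv$u %*% diag(sv$d[1:(k - 1)], k - 1) %*% t(sv$v)
  lin_err <- mean((lin - Xc)^2)
  expect_lt(vae_err, lin_err)
})
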
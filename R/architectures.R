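#' Hyperparameter configuration of one integrative VAE
#'
#' One configuration fully determines the built network's shapes and its
#' training schedule. Defaults follow the study protocol: 150 epochs of Adam
#' at learning rate 0.001 (moment decays 0.9 / 0.999), batch size 64, hidden
#' dropout 0.2, dense layers of 128/256/512 units and latent sizes 16/32/64
#' swept on the grid.
#'
#' @param architecture One of `"CNC"`, `"X"`, `"MM"`, `"H"`.
#' @param latent_size Size of the latent embedding (grid values 16, 32, 64).
#' @param dense_size Units in each hidden dense layer (grid values 128, 256,
#'   512).
#' @param regularizer A [reg_spec()]; default MMD with `beta = 50`.
#' @param dropout Hidden-layer dropout rate (default 0.2).
#' @param epochs Training epochs (default 150).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param adam_beta1,adam_beta2 Adam moment decay rates (0.9, 0.999).
#' @param batch_size Mini-batch size (default 64; a final short batch is
#'   kept, not dropped).
#' @param seed Integer seed governing weight initialization, batch
#'   shuffling, dropout masks, reparameterization noise and prior draws.
#' @return An object of class `network_config`.
#' @export
network_config <- function(architecture = c("X", "CNC", "MM", "H"),
                           latent_size = 64L, dense_size = 256L,
                           regularizer = reg_spec("MMD", beta = 50),
                           dropout = 0.2, epochs = 150L,
                           learning_rate = 0.001, adam_beta1 = 0.9,
                           adam_beta2 = 0.999, batch_size = 64L,
                           seed = 42L) {
  architecture <- toupper(architecture)
  architecture <- match.arg(architecture, c("X", "CNC", "MM", "H"))
  stopifnot(inherits(regularizer, "reg_spec"),
            latent_size >= 1, dense_size >= 1, epochs >= 1,
            dropout >= 0, dropout < 1, batch_size >= 1)
  structure(list(architecture = architecture,
                 latent_size = as.integer(latent_size),
                 dense_size = as.integer(dense_size),
                 regularizer = regularizer,
                 dropout = dropout, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(
    "<network_config> %s-VAE: ls=%d ds=%d %s(beta=%g) dropout=%g epochs=%d lr=%g batch=%d seed=%d\n",
    x$architecture, x$latent_size, x$dense_size, x$regularizer$kind,
    x$regularizer$beta, x$dropout, x$epochs, x$learning_rate, x$batch_size,
    x$seed))
  invisible(x)
}

#' Reparameterization of a diagonal-Gaussian posterior
#'
#' `z = mu + exp(logvar / 2) * eps` with `eps ~ N(0, I)` supplied by the
#' caller, so gradients can flow through `mu` and `logvar` while the noise
#' stays exogenous.
#'
#' @param post List (or `latent_posterior`) with matrices `mu` and `logvar`.
#' @param eps Noise matrix of the same shape as `post$mu`.
#' @return Matrix of latent codes `z`.
#' @export
reparameterize <- function(post, eps) {
  if (!identical(dim(as.matrix(post$mu)), dim(as.matrix(eps)))) {
    stop("eps shape must match mu shape")
  }
  post$mu + exp(post$logvar / 2) * eps
}

# ---- construction --------------------------------------------------------

check_specs_for_build <- function(specs) {
  stopifnot_spec_list(specs)
  if (length(specs) < 2L) stop("integrative architectures need >= 2 modalities")
  widths <- vapply(specs, `[[`, integer(1), "n_features")
  if (any(widths < 1L)) stop("zero-width modality")
  invisible(specs)
}

resolve_sigma <- function(config) {
  reg <- config$regularizer
  if (reg$kind == "MMD" && is.null(reg$kernel_sigma)) {
    reg$kernel_sigma <- sqrt(config$latent_size / 2)
  }
  reg
}

new_model <- function(architecture, specs, config, layers, extra = list()) {
  config$architecture <- architecture
  config$regularizer <- resolve_sigma(config)
  structure(c(list(architecture = architecture, specs = specs,
                   config = config, layers = layers, trained = FALSE,
                   loss_trace = NULL),
              extra),
            class = "integrative_model")
}

#' @export
print.integrative_model <- function(x, ...) {
  cat(sprintf("<integrative_model> %s-VAE (%strained)\n", x$architecture,
              if (x$trained) "" else "un"))
  print(x$config)
  for (s in x$specs) cat(sprintf("  %s: %d features (%s)\n", s$name,
                                 s$n_features, s$kind))
  invisible(x)
}

#' Build an integrative VAE with inputs concatenated at the first layer
#'
#' All modality blocks are concatenated into one wide input; a single hidden
#' dense block feeds the bottleneck, and the mirrored decoder emits one wide
#' reconstruction that is sliced back into modality blocks, each scored by
#' its own loss (sigmoid outputs and cross entropy for categorical slices,
#' linear outputs and squared error for continuous ones).
#'
#' @param specs List of [modality_spec()] (at least two).
#' @param config A [network_config()].
#' @return An untrained `integrative_model`.
#' @export
build_cnc_vae <- function(specs, config) {
  check_specs_for_build(specs)
  set.seed(config$seed)
  ds <- config$dense_size; ls <- config$latent_size
  d_tot <- sum(vapply(specs, `[[`, integer(1), "n_features"))
  layers <- list(
    enc_h = new_dense(d_tot, ds, "enc_h"), enc_bn = new_batchnorm(ds),
    mu = new_dense(ds, ls, "mu"), logvar = new_dense(ds, ls, "logvar"),
    dec_h = new_dense(ls, ds, "dec_h"), dec_bn = new_batchnorm(ds),
    dec_out = new_dense(ds, d_tot, "dec_out")
  )
  new_model("CNC", specs, config, layers)
}

#' Build an X-shaped integrative VAE
#'
#' Each modality has its own encoder branch (one hidden dense block); the
#' branch outputs are concatenated into the bottleneck. The decoder runs a
#' shared hidden block from `z`, then splits into per-modality branches
#' producing individual reconstructions; the objective sums one
#' reconstruction term per modality.
#'
#' @inheritParams build_cnc_vae
#' @return An untrained `integrative_model`.
#' @export
build_x_vae <- function(specs, config) {
  check_specs_for_build(specs)
  set.seed(config$seed)
  ds <- config$dense_size; ls <- config$latent_size
  M <- length(specs)
  layers <- list()
  for (s in specs) {
    layers[[paste0("enc_h_", s$name)]] <- new_dense(s$n_features, ds)
    layers[[paste0("enc_bn_", s$name)]] <- new_batchnorm(ds)
  }
  layers$mu <- new_dense(M * ds, ls, "mu")
  layers$logvar <- new_dense(M * ds, ls, "logvar")
  layers$dec_h <- new_dense(ls, ds, "dec_h")
  layers$dec_bn <- new_batchnorm(ds)
  for (s in specs) {
    layers[[paste0("dec_h_", s$name)]] <- new_dense(ds, ds)
    layers[[paste0("dec_bn_", s$name)]] <- new_batchnorm(ds)
    layers[[paste0("dec_out_", s$name)]] <- new_dense(ds, s$n_features)
  }
  new_model("X", specs, config, layers)
}

#' Build a mixed-modal integrative VAE
#'
#' Like the X-shaped design, but integration is more gradual: each encoder
#' branch's second hidden layer receives the concatenation of *all*
#' branches' first-layer outputs, so higher-level concepts are shared across
#' modalities before the bottleneck. The encoder is one hidden layer deeper
#' than the X-shaped encoder; the decoder is identical.
#'
#' @inheritParams build_cnc_vae
#' @return An untrained `integrative_model`.
#' @export
build_mm_vae <- function(specs, config) {
  check_specs_for_build(specs)
  set.seed(config$seed)
  ds <- config$dense_size; ls <- config$latent_size
  M <- length(specs)
  layers <- list()
  for (s in specs) {
    layers[[paste0("enc_h1_", s$name)]] <- new_dense(s$n_features, ds)
    layers[[paste0("enc_bn1_", s$name)]] <- new_batchnorm(ds)
  }
  for (s in specs) {
    layers[[paste0("enc_h2_", s$name)]] <- new_dense(M * ds, ds)
    layers[[paste0("enc_bn2_", s$name)]] <- new_batchnorm(ds)
  }
  layers$mu <- new_dense(M * ds, ls, "mu")
  layers$logvar <- new_dense(M * ds, ls, "logvar")
  layers$dec_h <- new_dense(ls, ds, "dec_h")
  layers$dec_bn <- new_batchnorm(ds)
  for (s in specs) {
    layers[[paste0("dec_h_", s$name)]] <- new_dense(ds, ds)
    layers[[paste0("dec_bn_", s$name)]] <- new_batchnorm(ds)
    layers[[paste0("dec_out_", s$name)]] <- new_dense(ds, s$n_features)
  }
  new_model("MM", specs, config, layers)
}

#' Build a hierarchical integrative VAE
#'
#' One low-level VAE per modality (all sharing the same single-modality
#' architecture) learns a modality-specific embedding; their posterior means
#' are concatenated and fed to a high-level VAE whose squared-error targets
#' are those concatenated means. Training is two-stage
#' ([train_hierarchical()]): low-level models first, then the high-level
#' model on frozen low-level means. Low-level latent size equals the final
#' latent size.
#'
#' @inheritParams build_cnc_vae
#' @param low_level_models Optional list of already-built (possibly trained)
#'   low-level models, one per spec, in spec order.
#' @return An untrained `integrative_model` holding `M + 1` sub-models.
#' @export
build_h_vae <- function(specs, config, low_level_models = NULL) {
  check_specs_for_build(specs)
  ls <- config$latent_size
  M <- length(specs)
  if (is.null(low_level_models)) {
    low_level_models <- lapply(seq_len(M), function(m) {
      cfg <- config
      cfg$seed <- config$seed + m
      build_single_vae(specs[[m]], cfg)
    })
  } else {
    if (length(low_level_models) != M) {
      stop("need one low-level model per modality")
    }
    for (m in seq_len(M)) {
      if (!identical(low_level_models[[m]]$specs[[1]]$name, specs[[m]]$name) ||
          low_level_models[[m]]$specs[[1]]$n_features != specs[[m]]$n_features) {
        stop("low-level models were built for different specs")
      }
    }
  }
  high_spec <- modality_spec("latent", "continuous", M * ls)
  high_cfg <- config
  high_cfg$seed <- config$seed + M + 1L
  high <- build_single_vae(high_spec, high_cfg)
  new_model("H", specs, config, layers = list(),
            extra = list(low = low_level_models, high = high))
}

# Standard single-input VAE; the building block of the hierarchical design.
build_single_vae <- function(spec, config) {
  set.seed(config$seed)
  ds <- config$dense_size; ls <- config$latent_size
  d <- spec$n_features
  layers <- list(
    enc_h = new_dense(d, ds, "enc_h"), enc_bn = new_batchnorm(ds),
    mu = new_dense(ds, ls, "mu"), logvar = new_dense(ds, ls, "logvar"),
    dec_h = new_dense(ls, ds, "dec_h"), dec_bn = new_batchnorm(ds),
    dec_out = new_dense(ds, d, "dec_out")
  )
  new_model("CNC1", list(spec), config, layers)
}

# ---- forward passes ------------------------------------------------------

hidden_block <- function(tp, x_id, dense, bn, dropout, training) {
  id <- tp_dense(tp, x_id, dense)
  id <- tp_batchnorm(tp, id, bn, training)
  id <- tp_elu(tp, id)
  tp_dropout(tp, id, dropout, training)
}

# Encoder: input matrices -> (mu, logvar) node ids.
forward_encoder <- function(model, tp, x_ids, training) {
  ly <- model$layers
  p <- model$config$dropout
  arch <- model$architecture
  if (arch %in% c("CNC", "CNC1")) {
    x <- if (length(x_ids) > 1L) tp_concat(tp, x_ids) else x_ids[[1]]
    h <- hidden_block(tp, x, ly$enc_h, ly$enc_bn, p, training)
    merged <- h
  } else if (arch == "X") {
    hs <- lapply(seq_along(model$specs), function(m) {
      nm <- model$specs[[m]]$name
      hidden_block(tp, x_ids[[m]], ly[[paste0("enc_h_", nm)]],
                   ly[[paste0("enc_bn_", nm)]], p, training)
    })
    merged <- tp_concat(tp, hs)
  } else if (arch == "MM") {
    h1 <- lapply(seq_along(model$specs), function(m) {
      nm <- model$specs[[m]]$name
      hidden_block(tp, x_ids[[m]], ly[[paste0("enc_h1_", nm)]],
                   ly[[paste0("enc_bn1_", nm)]], p, training)
    })
    shared <- tp_concat(tp, h1)
    h2 <- lapply(seq_along(model$specs), function(m) {
      nm <- model$specs[[m]]$name
      hidden_block(tp, shared, ly[[paste0("enc_h2_", nm)]],
                   ly[[paste0("enc_bn2_", nm)]], p, training)
    })
    merged <- tp_concat(tp, h2)
  } else {
    stop(sprintf("no encoder forward for architecture '%s'", arch))
  }
  list(mu = tp_dense(tp, merged, ly$mu),
       logvar = tp_dense(tp, merged, ly$logvar))
}

# Decoder: z node id -> per-modality pre-activation and output node ids.
forward_decoder <- function(model, tp, z_id, training) {
  ly <- model$layers
  p <- model$config$dropout
  arch <- model$architecture
  specs <- model$specs
  pre <- list(); out <- list()
  if (arch %in% c("CNC", "CNC1")) {
    h <- hidden_block(tp, z_id, ly$dec_h, ly$dec_bn, p, training)
    a <- tp_dense(tp, h, ly$dec_out)
    off <- 0L
    for (s in specs) {
      cols <- (off + 1L):(off + s$n_features)
      sl <- tp_slice(tp, a, cols)
      pre[[s$name]] <- sl
      out[[s$name]] <- if (s$output_activation == "sigmoid") {
        tp_sigmoid(tp, sl)
      } else {
        sl
      }
      off <- off + s$n_features
    }
  } else if (arch %in% c("X", "MM")) {
    h <- hidden_block(tp, z_id, ly$dec_h, ly$dec_bn, p, training)
    for (s in specs) {
      hm <- hidden_block(tp, h, ly[[paste0("dec_h_", s$name)]],
                         ly[[paste0("dec_bn_", s$name)]], p, training)
      a <- tp_dense(tp, hm, ly[[paste0("dec_out_", s$name)]])
      pre[[s$name]] <- a
      out[[s$name]] <- if (s$output_activation == "sigmoid") {
        tp_sigmoid(tp, a)
      } else {
        a
      }
    }
  } else {
    stop(sprintf("no decoder forward for architecture '%s'", arch))
  }
  list(pre = pre, out = out)
}

#' Number of hidden layers along one encoder path
#'
#' Counts the dense hidden layers an input block traverses before the
#' bottleneck (the mixed-modal encoder is exactly one layer deeper than the
#' X-shaped one).
#'
#' @param model An `integrative_model`.
#' @return Integer.
#' @export
encoder_depth <- function(model) {
  switch(model$architecture,
         CNC = 1L, CNC1 = 1L, X = 1L, MM = 2L,
         H = 1L + encoder_depth(model$high))
}

#' Number of trainable sub-models
#'
#' 1 for the single-stage architectures; `M + 1` for the hierarchical design
#' (one low-level VAE per modality plus the high-level VAE).
#'
#' @param model An `integrative_model`.
#' @return Integer.
#' @export
n_submodels <- function(model) {
  if (model$architecture == "H") length(model$low) + 1L else 1L
}

# ---- training ------------------------------------------------------------

modality_matrices <- function(model, dataset) {
  if (inherits(dataset, "multiomic_dataset")) {
    Xs <- dataset$modalities[vapply(model$specs, `[[`, character(1), "name")]
  } else if (is.list(dataset) && !is.data.frame(dataset)) {
    Xs <- dataset[vapply(model$specs, `[[`, character(1), "name")]
  } else {
    stop("dataset must be a multiomic_dataset or a named list of matrices")
  }
  for (m in seq_along(model$specs)) {
    if (is.null(Xs[[m]])) {
      stop(sprintf("modality '%s' missing from dataset", model$specs[[m]]$name))
    }
    if (ncol(Xs[[m]]) != model$specs[[m]]$n_features) {
      stop(sprintf("modality '%s' has %d features; model expects %d",
                   model$specs[[m]]$name, ncol(Xs[[m]]),
                   model$specs[[m]]$n_features))
    }
  }
  Xs
}

# Forward pass + analytic gradients for one mini-batch. `eps` (reparam
# noise) and `Zp` (MMD prior draws) default to fresh N(0,1) draws from the
# current RNG stream; passing them explicitly makes the computation a
# deterministic function of the parameters (used by the finite-difference
# gradient tests). Parameter gradients land in the layers' g* fields.
objective_and_grads <- function(model, Xb, eps = NULL, Zp = NULL) {
  cfg <- model$config
  reg <- cfg$regularizer
  nb <- nrow(Xb[[1]])
  ls <- cfg$latent_size
  tp <- tape_new()
  x_ids <- lapply(Xb, function(X) tp_input(tp, X))
  enc <- forward_encoder(model, tp, x_ids, training = TRUE)
  if (is.null(eps)) eps <- matrix(stats::rnorm(nb * ls), nb, ls)
  z_id <- tp_reparam(tp, enc$mu, enc$logvar, eps)
  dec <- forward_decoder(model, tp, z_id, training = TRUE)

  seeds <- list()
  recon <- numeric(0)
  for (s in model$specs) {
    X <- Xb[[s$name]]
    nd <- length(X)
    if (s$recon_loss == "squared-error") {
      xhat <- tp_value(tp, dec$out[[s$name]])
      recon[s$name] <- mean((X - xhat)^2)
      seeds[[length(seeds) + 1L]] <-
        list(id = dec$pre[[s$name]], g = 2 * (xhat - X) / nd)
    } else {
      p <- tp_value(tp, dec$out[[s$name]])
      recon[s$name] <- bce_recon(X, p)
      # gradient w.r.t. the pre-sigmoid activation: (p - t) / (n d)
      seeds[[length(seeds) + 1L]] <-
        list(id = dec$pre[[s$name]], g = (p - X) / nd)
    }
  }

  mu <- tp_value(tp, enc$mu); lv <- tp_value(tp, enc$logvar)
  if (reg$kind == "KL") {
    reg_value <- kl_gaussian(mu, lv)
    seeds[[length(seeds) + 1L]] <-
      list(id = enc$mu, g = reg$beta * mu / nb)
    seeds[[length(seeds) + 1L]] <-
      list(id = enc$logvar, g = reg$beta * 0.5 * (exp(lv) - 1) / nb)
  } else {
    z <- tp_value(tp, z_id)
    if (is.null(Zp)) Zp <- matrix(stats::rnorm(nb * ls), nb, ls)
    sig <- reg$kernel_sigma
    reg_value <- mmd_biased(z, Zp, sig)
    s2 <- 2 * sig^2
    Kqq <- exp(-pairwise_sqdist(z, z) / s2)
    Kqp <- exp(-pairwise_sqdist(z, Zp) / s2)
    gz <- (2 / (nb^2 * sig^2)) * (Kqq %*% z - rowSums(Kqq) * z) -
      (2 / (nb * nrow(Zp) * sig^2)) * (Kqp %*% Zp - rowSums(Kqp) * z)
    seeds[[length(seeds) + 1L]] <- list(id = z_id, g = reg$beta * gz)
  }

  obj <- composite_objective(recon, reg, reg_value)
  zero_grads(model$layers)
  tape_backward(tp, seeds)
  obj
}

# One Adam step on one mini-batch. Returns the objective_value.
train_step <- function(model, Xb, adam) {
  obj <- objective_and_grads(model, Xb)
  if (!is.finite(obj$total)) {
    bad <- c(names(obj$recon_per_modality)[!is.finite(obj$recon_per_modality)],
             if (!is.finite(obj$regularizer)) "regularizer")
    stop(sprintf("non-finite loss (offending term: %s)",
                 paste(bad, collapse = ", ")))
  }
  adam_step(adam, model$layers)
  obj
}

train_core <- function(model, Xs) {
  cfg <- model$config
  n <- nrow(Xs[[1]])
  if (cfg$batch_size > n) {
    stop(sprintf("batch_size %d exceeds sample count %d", cfg$batch_size, n))
  }
  set.seed(cfg$seed + 1000L)
  adam <- adam_new(model$layers, lr = cfg$learning_rate,
                   beta1 = cfg$adam_beta1, beta2 = cfg$adam_beta2)
  trace <- vector("list", cfg$epochs)
  mod_names <- vapply(model$specs, `[[`, character(1), "name")
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    tot <- 0; rec <- stats::setNames(numeric(length(mod_names)), mod_names)
    regv <- 0
    for (st in starts) {
      idx <- perm[st:min(st + cfg$batch_size - 1L, n)]
      Xb <- lapply(Xs, function(X) X[idx, , drop = FALSE])
      obj <- tryCatch(train_step(model, Xb, adam), error = function(e) {
        stop(sprintf("training aborted at epoch %d: %s", epoch,
                     conditionMessage(e)), call. = FALSE)
      })
      w <- length(idx) / n
      tot <- tot + w * obj$total
      rec <- rec + w * obj$recon_per_modality[mod_names]
      regv <- regv + w * obj$regularizer
    }
    if (!is.finite(tot)) {
      bad <- c(names(rec)[!is.finite(rec)],
               if (!is.finite(regv)) "regularizer")
      stop(sprintf("non-finite loss at epoch %d (offending term: %s)",
                   epoch, paste(bad, collapse = ", ")))
    }
    trace[[epoch]] <- c(epoch = epoch, rec, regularizer = regv, total = tot)
  }
  model$loss_trace <- as.data.frame(do.call(rbind, trace))
  model$trained <- TRUE
  model
}

#' Train an integrative VAE
#'
#' Runs mini-batch Adam for `config$epochs` epochs with per-epoch shuffling
#' driven by the config seed. The hierarchical architecture dispatches to
#' the two-stage procedure ([train_hierarchical()]). With a fixed seed and
#' fixed inputs, training is bitwise-reproducible on a single CPU thread.
#'
#' @param model An `integrative_model` from one of the builders.
#' @param dataset A `multiomic_dataset` (or named list of matrices) holding
#'   the training rows only.
#' @return The trained model, with `loss_trace` holding one decomposed
#'   objective row per epoch.
#' @export
train_vae <- function(model, dataset) {
  stopifnot(inherits(model, "integrative_model"))
  if (model$architecture == "H") {
    return(train_hierarchical(model, dataset))
  }
  Xs <- modality_matrices(model, dataset)
  train_core(model, Xs)
}

#' Two-stage training of the hierarchical VAE
#'
#' Stage 1 trains each low-level VAE independently on its own modality (the
#' full epoch budget each). Stage 2 freezes them, encodes the training rows
#' to posterior means, concatenates those means and trains the high-level
#' VAE on that matrix with a squared-error reconstruction target.
#'
#' @param model An `integrative_model` built by [build_h_vae()].
#' @param dataset Training rows, as in [train_vae()].
#' @return The trained model; `loss_trace` is the high-level trace, and each
#'   sub-model keeps its own.
#' @export
train_hierarchical <- function(model, dataset) {
  stopifnot(inherits(model, "integrative_model"),
            model$architecture == "H")
  Xs <- modality_matrices(model, dataset)
  for (m in seq_along(model$low)) {
    if (!model$low[[m]]$trained) {
      nm <- model$specs[[m]]$name
      model$low[[m]] <- train_core(model$low[[m]], Xs[nm])
    }
  }
  H <- encode_low_means(model, Xs)
  model$high <- train_core(model$high, list(latent = H))
  model$loss_trace <- model$high$loss_trace
  model$trained <- TRUE
  model
}

encode_low_means <- function(model, Xs) {
  mats <- lapply(seq_along(model$low), function(m) {
    if (!model$low[[m]]$trained) {
      stop("low-level models must be trained before encoding")
    }
    encode_core(model$low[[m]], Xs[model$specs[[m]]$name])$mu
  })
  do.call(cbind, mats)
}

encode_core <- function(model, Xs) {
  tp <- tape_new()
  x_ids <- lapply(Xs, function(X) tp_input(tp, X))
  enc <- forward_encoder(model, tp, x_ids, training = FALSE)
  list(mu = tp_value(tp, enc$mu), logvar = tp_value(tp, enc$logvar))
}

#' Encode samples to the latent embedding
#'
#' Returns the posterior means (no sampling), so the embedding is
#' deterministic and calling twice gives identical output. For the
#' hierarchical model, low-level means are computed first and passed through
#' the high-level encoder.
#'
#' @param model A trained `integrative_model`.
#' @param dataset A `multiomic_dataset` or named list of matrices with the
#'   modality shapes the model was built for.
#' @return An n-by-latent_size matrix.
#' @export
encode <- function(model, dataset) {
  post <- encode_posterior(model, dataset)
  post$mu
}

#' Encode samples to the full diagonal-Gaussian posterior
#'
#' @inheritParams encode
#' @return A `latent_posterior`: list with matrices `mu` and `logvar`.
#' @export
encode_posterior <- function(model, dataset) {
  stopifnot(inherits(model, "integrative_model"))
  if (!model$trained) stop("model is not trained")
  Xs <- modality_matrices(model, dataset)
  post <- if (model$architecture == "H") {
    H <- encode_low_means(model, Xs)
    encode_core(model$high, list(latent = H))
  } else {
    encode_core(model, Xs)
  }
  structure(post, class = "latent_posterior")
}

decode_core <- function(model, Z) {
  tp <- tape_new()
  z_id <- tp_input(tp, Z)
  dec <- forward_decoder(model, tp, z_id, training = FALSE)
  lapply(dec$out, function(id) tp_value(tp, id))
}

#' Reconstruct the input modalities through the bottleneck
#'
#' Encodes to the posterior mean and decodes deterministically. For the
#' hierarchical model the high-level reconstruction of the concatenated
#' low-level means is sliced per modality and passed through each low-level
#' decoder.
#'
#' @inheritParams encode
#' @return Named list of matrices, one per modality, with the original
#'   feature widths.
#' @export
reconstruct <- function(model, dataset) {
  stopifnot(inherits(model, "integrative_model"))
  if (!model$trained) stop("model is not trained")
  Xs <- modality_matrices(model, dataset)
  if (model$architecture == "H") {
    H <- encode_low_means(model, Xs)
    zh <- encode_core(model$high, list(latent = H))$mu
    hrec <- decode_core(model$high, zh)$latent
    ls <- model$config$latent_size
    out <- list()
    for (m in seq_along(model$specs)) {
      cols <- ((m - 1L) * ls + 1L):(m * ls)
      out[[model$specs[[m]]$name]] <-
        decode_core(model$low[[m]], hrec[, cols, drop = FALSE])[[1]]
    }
    out
  } else {
    Z <- encode_core(model, Xs)$mu
    decode_core(model, Z)
  }
}

#' Draw new samples from the generative model
#'
#' Samples `z ~ N(0, I)` and decodes with the trained decoder; sigmoid
#' modalities are bounded in (0, 1).
#'
#' @param model A trained `integrative_model`.
#' @param n Number of samples (positive).
#' @param seed Integer seed for the latent draws.
#' @return Named list of per-modality matrices with `n` rows.
#' @export
sample_generative <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "integrative_model"))
  if (!model$trained) stop("model is not trained")
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("n must be positive")
  set.seed(as.integer(seed))
  ls <- model$config$latent_size
  Z <- matrix(stats::rnorm(n * ls), n, ls)
  if (model$architecture == "H") {
    hrec <- decode_core(model$high, Z)$latent
    out <- list()
    for (m in seq_along(model$specs)) {
      cols <- ((m - 1L) * ls + 1L):(m * ls)
      out[[model$specs[[m]]$name]] <-
        decode_core(model$low[[m]], hrec[, cols, drop = FALSE])[[1]]
    }
    out
  } else {
    decode_core(model, Z)
  }
}

#' Build an integrative VAE of any architecture
#'
#' Convenience dispatcher over the four builders.
#'
#' @inheritParams build_cnc_vae
#' @return An untrained `integrative_model`.
#' @export
build_vae <- function(specs, config) {
  switch(config$architecture,
         CNC = build_cnc_vae(specs, config),
         X = build_x_vae(specs, config),
         MM = build_mm_vae(specs, config),
         H = build_h_vae(specs, config),
         stop(sprintf("unknown architecture '%s'", config$architecture)))
}

# All trainable parameters (and batch-norm running stats) as one vector.
model_params <- function(model) {
  if (model$architecture == "H") {
    c(unlist(lapply(model$low, model_params)), model_params(model$high))
  } else {
    flatten_params(model$layers)
  }
}
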
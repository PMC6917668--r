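#' Downstream classifier settings
#'
#' Fixed settings of the three embedding-quality classifiers: Gaussian naive
#' Bayes (no hyperparameters), an RBF-kernel SVM with `C = 1.5` and
#' `gamma = 1 / n_features`, and a random forest with 50 trees considering
#' half the features at every split. These are deliberately not tuned: the
#' quantity under study is the representation, not the classifier.
#'
#' @param classifier One of `"gaussian-naive-bayes"`, `"svm-rbf"`,
#'   `"random-forest"`.
#' @param svm_C SVM soft-margin cost (default 1.5).
#' @param rf_trees Random-forest tree count (default 50).
#' @param classifier_seed Seed for the (only) stochastic classifier, the
#'   random forest.
#' @return An object of class `downstream_spec`.
#' @export
downstream_spec <- function(classifier = c("gaussian-naive-bayes", "svm-rbf",
                                           "random-forest"),
                            svm_C = 1.5, rf_trees = 50L,
                            classifier_seed = 42L) {
  classifier <- match.arg(classifier)
  structure(list(classifier = classifier, svm_C = svm_C,
                 rf_trees = as.integer(rf_trees),
                 classifier_seed = as.integer(classifier_seed)),
            class = "downstream_spec")
}

fit_predict_classifier <- function(spec, Xtr, ytr, Xte) {
  ytr <- factor(ytr)
  colnames(Xtr) <- colnames(Xte) <- paste0("V", seq_len(ncol(Xtr)))
  switch(spec$classifier,
    "gaussian-naive-bayes" = {
      fit <- e1071::naiveBayes(as.data.frame(Xtr), ytr)
      list(train = as.character(stats::predict(fit, as.data.frame(Xtr))),
           test = as.character(stats::predict(fit, as.data.frame(Xte))))
    },
    "svm-rbf" = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = spec$svm_C,
                        gamma = 1 / ncol(Xtr), scale = FALSE)
      list(train = as.character(stats::predict(fit, Xtr)),
           test = as.character(stats::predict(fit, Xte)))
    },
    "random-forest" = {
      set.seed(spec$classifier_seed)
      fit <- randomForest::randomForest(
        Xtr, ytr, ntree = spec$rf_trees,
        mtry = max(1L, floor(ncol(Xtr) / 2)))
      list(train = as.character(stats::predict(fit, Xtr)),
           test = as.character(stats::predict(fit, Xte)))
    })
}

#' Cross-validated accuracy of a representation
#'
#' For each fold, `embed_fn` is called with the training and test row
#' indices and must learn the representation **from the training rows
#' only**, returning embeddings for both partitions; a classifier is then
#' fit on the training embedding and scored on both partitions. This
#' contract is what prevents test-fold leakage into representation
#' learning.
#'
#' @param embed_fn `function(train_idx, test_idx)` returning
#'   `list(train = matrix, test = matrix)`.
#' @param labels Class vector over all samples.
#' @param folds A [make_stratified_folds()] assignment over the same
#'   samples.
#' @param spec A [downstream_spec()] (default Gaussian naive Bayes).
#' @param config Optional `network_config` recorded in the result.
#' @return An object of class `grid_result` with per-fold train/test
#'   accuracies and their means.
#' @export
cross_validated_accuracy <- function(embed_fn, labels, folds,
                                     spec = downstream_spec(),
                                     config = NULL) {
  stopifnot(inherits(folds, "fold_assignment"))
  labels <- factor(labels)
  train_acc <- test_acc <- numeric(folds$n_folds)
  for (f in seq_len(folds$n_folds) - 1L) {
    tr <- fold_train_idx(folds, f)
    te <- fold_test_idx(folds, f)
    if (length(unique(labels[tr])) < 2L) {
      stop(sprintf("fold %d has a single class in its training partition", f))
    }
    emb <- embed_fn(tr, te)
    pred <- fit_predict_classifier(spec, emb$train, labels[tr], emb$test)
    train_acc[f + 1L] <- mean(pred$train == as.character(labels[tr]))
    test_acc[f + 1L] <- mean(pred$test == as.character(labels[te]))
  }
  structure(list(config = config, task = folds$task,
                 classifier = spec$classifier,
                 fold_train_accuracy = train_acc,
                 fold_test_accuracy = test_acc,
                 mean_train_accuracy = mean(train_acc),
                 mean_test_accuracy = mean(test_acc)),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> task '%s', %s: mean test %.3f (train %.3f)\n",
              x$task, x$classifier, x$mean_test_accuracy,
              x$mean_train_accuracy))
  invisible(x)
}

#' Embedding function for a VAE architecture
#'
#' Returns an `embed_fn` for [cross_validated_accuracy()] that builds a
#' fresh model per fold, trains it on the training rows only and encodes
#' both partitions. With `refit_per_fold = FALSE` the model is instead
#' trained once on all rows before cross-validation (a laxer protocol that
#' lets the unsupervised representation see test-row inputs; provided for
#' parity with protocols that fit the representation on the full cohort).
#'
#' @param dataset A `multiomic_dataset`.
#' @param config A [network_config()].
#' @param refit_per_fold Train the VAE inside each fold (default `TRUE`).
#' @return `function(train_idx, test_idx)`.
#' @export
vae_embed_fn <- function(dataset, config, refit_per_fold = TRUE) {
  specs <- dataset$specs
  if (!refit_per_fold) {
    model <- train_vae(build_vae(specs, config), dataset)
    return(function(train_idx, test_idx) {
      list(train = encode(model, dataset_rows(dataset, train_idx)),
           test = encode(model, dataset_rows(dataset, test_idx)))
    })
  }
  function(train_idx, test_idx) {
    model <- build_vae(specs, config)
    model <- train_vae(model, dataset_rows(dataset, train_idx))
    list(train = encode(model, dataset_rows(dataset, train_idx)),
         test = encode(model, dataset_rows(dataset, test_idx)))
  }
}

#' PCA baseline embedding
#'
#' Centers on the training rows and projects both partitions onto the top
#' `k` principal axes of the training data.
#'
#' @param train,test Numeric matrices with identical column sets.
#' @param k Number of components, at most `min(nrow(train), ncol(train))`.
#' @return List with matrices `train`, `test`, the `rotation`, and
#'   `explained_variance` per component.
#' @export
pca_baseline <- function(train, test, k = 64L) {
  k <- as.integer(k)
  if (k > min(nrow(train), ncol(train))) {
    stop(sprintf("k = %d exceeds min(n_train, n_features) = %d", k,
                 min(nrow(train), ncol(train))))
  }
  fit <- stats::prcomp(train, center = TRUE, scale. = FALSE, rank. = k)
  list(train = fit$x[, seq_len(k), drop = FALSE],
       test = scale(test, center = fit$center, scale = FALSE) %*%
         fit$rotation[, seq_len(k), drop = FALSE],
       rotation = fit$rotation[, seq_len(k), drop = FALSE],
       center = fit$center,
       explained_variance = fit$sdev[seq_len(k)]^2)
}

#' Embedding function for the PCA baseline
#'
#' @param X Numeric matrix over all samples (e.g. a [raw_baseline()]
#'   concatenation).
#' @param k Number of components (default 64).
#' @return `function(train_idx, test_idx)` fitting PCA on the training rows
#'   only.
#' @export
pca_embed_fn <- function(X, k = 64L) {
  function(train_idx, test_idx) {
    p <- pca_baseline(X[train_idx, , drop = FALSE],
                      X[test_idx, , drop = FALSE], k = k)
    list(train = p$train, test = p$test)
  }
}

#' Raw (uncompressed) feature baseline
#'
#' Column-concatenates the selected preprocessed modalities in spec order.
#'
#' @param dataset A `multiomic_dataset`.
#' @param modalities Character vector of modality names (default: all).
#' @return Numeric matrix.
#' @export
raw_baseline <- function(dataset, modalities = NULL) {
  all_names <- vapply(dataset$specs, `[[`, character(1), "name")
  if (is.null(modalities)) modalities <- all_names
  unknown <- setdiff(modalities, all_names)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown modality name(s): %s", paste(unknown, collapse = ", ")))
  }
  sel <- all_names[all_names %in% modalities]
  do.call(cbind, dataset$modalities[sel])
}

#' Embedding function for a raw-feature baseline
#' @inheritParams raw_baseline
#' @return `function(train_idx, test_idx)`.
#' @export
raw_embed_fn <- function(dataset, modalities = NULL) {
  X <- raw_baseline(dataset, modalities)
  function(train_idx, test_idx) {
    list(train = X[train_idx, , drop = FALSE],
         test = X[test_idx, , drop = FALSE])
  }
}

# ---- hyperparameter grid -------------------------------------------------

#' Default hyperparameter grid axes
#'
#' Latent sizes \{16, 32, 64\} by dense sizes \{128, 256, 512\} by
#' regularizer \{KL, MMD\} by weight beta \{1, 10, 15, 25, 50, 100\}: 108
#' configurations per architecture per task.
#'
#' @return Named list of axis vectors.
#' @export
grid_axes_default <- function() {
  list(latent_size = c(16L, 32L, 64L),
       dense_size = c(128L, 256L, 512L),
       regularizer = c("KL", "MMD"),
       beta = c(1, 10, 15, 25, 50, 100))
}

#' Enumerate all configurations on the grid axes
#'
#' Deterministic lexicographic order over (latent_size, dense_size,
#' regularizer, beta).
#'
#' @param architecture Architecture id for every configuration.
#' @param axes Axis list as in [grid_axes_default()].
#' @param base Base [network_config()] supplying the non-swept parameters.
#' @return List of `network_config` objects.
#' @export
enumerate_grid <- function(architecture, axes = grid_axes_default(),
                           base = network_config(architecture)) {
  cells <- expand.grid(beta = axes$beta, regularizer = axes$regularizer,
                       dense_size = axes$dense_size,
                       latent_size = axes$latent_size,
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$latent_size, cells$dense_size,
                       cells$regularizer, cells$beta), ]
  key <- with(cells, paste(latent_size, dense_size, regularizer, beta))
  if (anyDuplicated(key)) stop("duplicate configurations on the grid axes")
  lapply(seq_len(nrow(cells)), function(i) {
    cfg <- base
    cfg$architecture <- toupper(architecture)
    cfg$latent_size <- cells$latent_size[i]
    cfg$dense_size <- cells$dense_size[i]
    cfg$regularizer <- reg_spec(cells$regularizer[i], beta = cells$beta[i])
    cfg
  })
}

config_row <- function(config, result) {
  data.frame(architecture = config$architecture,
             latent_size = config$latent_size,
             dense_size = config$dense_size,
             regularizer = config$regularizer$kind,
             beta = config$regularizer$beta,
             epochs = config$epochs, seed = config$seed,
             task = result$task, classifier = result$classifier,
             mean_train_accuracy = result$mean_train_accuracy,
             mean_test_accuracy = result$mean_test_accuracy,
             fold_train_accuracy = paste(signif(result$fold_train_accuracy, 6),
                                         collapse = ","),
             fold_test_accuracy = paste(signif(result$fold_test_accuracy, 6),
                                        collapse = ","),
             stringsAsFactors = FALSE)
}

#' Sweep an architecture over the hyperparameter grid
#'
#' Runs [cross_validated_accuracy()] with a Gaussian naive Bayes classifier
#' (chosen because it needs no tuning of its own) for every configuration on
#' the axes, streaming one TSV row per configuration to `store` as results
#' complete. If `store` already holds rows, finished configurations are
#' skipped, making interrupted sweeps resumable.
#'
#' @param architecture One of `"CNC"`, `"X"`, `"MM"`, `"H"`.
#' @param dataset A `multiomic_dataset`.
#' @param task Name of the label task in `dataset$labels`.
#' @param axes Grid axes (default [grid_axes_default()]).
#' @param base Base config for non-swept parameters.
#' @param folds Optional precomputed `fold_assignment` (default: stratified
#'   5-fold from the base config seed).
#' @param store Optional TSV path for streaming/resuming results.
#' @param refit_per_fold Passed to [vae_embed_fn()].
#' @return Data frame with one row per configuration.
#' @export
run_config_grid <- function(architecture, dataset, task = "class",
                            axes = grid_axes_default(),
                            base = network_config(architecture),
                            folds = NULL, store = NULL,
                            refit_per_fold = TRUE) {
  labels <- dataset$labels[[task]]
  if (is.null(labels)) stop(sprintf("unknown label task '%s'", task))
  if (is.null(folds)) {
    folds <- make_stratified_folds(labels, n_folds = 5L, seed = base$seed,
                                   task = task)
  }
  configs <- enumerate_grid(architecture, axes, base)
  done <- NULL
  done_keys <- character(0)
  if (!is.null(store) && file.exists(store)) {
    done <- utils::read.table(store, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    done_keys <- paste(done$architecture, done$latent_size, done$dense_size,
                       done$regularizer, done$beta, done$task, sep = "|")
  }
  rows <- list()
  for (cfg in configs) {
    key <- paste(cfg$architecture, cfg$latent_size, cfg$dense_size,
                 cfg$regularizer$kind, cfg$regularizer$beta, task, sep = "|")
    hit <- which(done_keys == key)
    if (length(hit) > 0L) {
      rows[[key]] <- done[hit[1L], , drop = FALSE]
      next
    }
    res <- cross_validated_accuracy(
      vae_embed_fn(dataset, cfg, refit_per_fold = refit_per_fold),
      labels, folds, downstream_spec("gaussian-naive-bayes"), config = cfg)
    row <- config_row(cfg, res)
    rows[[key]] <- row
    if (!is.null(store)) {
      utils::write.table(row, store, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = !file.exists(store),
                         append = file.exists(store))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (col in c("latent_size", "dense_size", "epochs", "seed")) {
    out[[col]] <- as.integer(out[[col]])
  }
  for (col in c("beta", "mean_train_accuracy", "mean_test_accuracy")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  out
}

#' Select the best configuration from grid results
#'
#' Returns the configuration with the highest mean test accuracy. Ties are
#' broken deterministically in favour of the smaller latent size, then the
#' smaller dense size, then MMD before KL, then the smaller beta.
#'
#' @param results Data frame from [run_config_grid()] (or a list of
#'   `grid_result` objects carrying configs).
#' @return A `network_config`.
#' @export
select_configuration <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r) {
      config_row(r$config, r)
    }))
  }
  if (nrow(results) == 0L) stop("no grid results to select from")
  reg_rank <- ifelse(results$regularizer == "MMD", 0L, 1L)
  ord <- order(-results$mean_test_accuracy, results$latent_size,
               results$dense_size, reg_rank, results$beta)
  best <- results[ord[1L], ]
  network_config(best$architecture, latent_size = best$latent_size,
                 dense_size = best$dense_size,
                 regularizer = reg_spec(best$regularizer, beta = best$beta),
                 epochs = best$epochs, seed = best$seed)
}

#' Export a 2-D t-SNE projection of an embedding
#'
#' Delegates the projection to the Barnes-Hut t-SNE implementation in
#' \pkg{Rtsne}, writes the coordinates as TSV and (optionally) a scatter
#' figure colored by label.
#'
#' @param embedding Numeric matrix (n at least 5, finite entries).
#' @param labels Class vector of length n.
#' @param out Output TSV path; a figure is written alongside with extension
#'   `.png` unless `figure = FALSE`.
#' @param seed Seed for the t-SNE initialization (fixed seed gives
#'   identical coordinates across runs).
#' @param perplexity t-SNE perplexity; default adapts to small n.
#' @param figure Write the scatter figure (default TRUE).
#' @return Invisibly, the coordinate data frame (`tsne1`, `tsne2`, `label`).
#' @export
tsne_export <- function(embedding, labels, out, seed = 42L,
                        perplexity = NULL, figure = TRUE) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) < 5L) stop("t-SNE needs at least 5 samples")
  if (any(!is.finite(embedding))) stop("non-finite entries in embedding")
  if (is.null(perplexity)) {
    perplexity <- max(2, min(30, floor((nrow(embedding) - 1) / 3)))
  }
  set.seed(as.integer(seed))
  fit <- Rtsne::Rtsne(embedding, dims = 2, perplexity = perplexity,
                      check_duplicates = FALSE, pca = FALSE, num_threads = 1)
  coords <- data.frame(tsne1 = fit$Y[, 1], tsne2 = fit$Y[, 2],
                       label = as.character(labels))
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(coords, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (figure) {
    fig <- sub("\\.tsv$", ".png", out)
    if (identical(fig, out)) fig <- paste0(out, ".png")
    grDevices::png(fig, width = 900, height = 700, res = 120)
    cls <- factor(coords$label)
    graphics::plot(coords$tsne1, coords$tsne2, col = as.integer(cls),
                   pch = 19, cex = 0.6, xlab = "tSNE 1", ylab = "tSNE 2",
                   main = "t-SNE of latent embedding")
    graphics::legend("topright", legend = levels(cls),
                     col = seq_len(nlevels(cls)), pch = 19, cex = 0.8)
    grDevices::dev.off()
  }
  invisible(coords)
}
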
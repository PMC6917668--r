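#' Specify a synthetic multi-modal dataset
#'
#' The generator emulates the shapes and value ranges of a breast-cancer
#' multi-omic cohort at desk scale: a continuous expression-like modality in
#' \[0,1\], an ordinal 5-state copy-number-like modality smoothed into
#' \[0,1\], and a one-hot clinical-like block — all driven by a shared
#' latent factor vector whose mixture component defines the class label.
#' Defaults are one tenth of the cohort-scale widths (1000/1000/350 features
#' over 1980 samples) for speed; set `metabric_scale = TRUE` for the full
#' shapes.
#'
#' @param n_samples Number of samples (default 500).
#' @param latent_rank Dimension k of the shared latent factors (default 4).
#' @param n_classes Number of mixture components / classes: 2, 6 or 10.
#' @param d_continuous,d_categorical,d_clinical Feature widths of the three
#'   modalities (defaults 100, 100, 50).
#' @param signal_split Fraction of the class-informative latent coordinates
#'   loading on the first modality; the remainder load on the others.
#'   `1` (default) lets every modality see all factors.
#' @param noise_sd Standard deviation of the additive Gaussian feature noise
#'   applied before the logistic/thresholding step (default 0.1).
#' @param class_sep Euclidean distance scale between class centers in latent
#'   space, in within-class-standard-deviation units (default 4).
#' @param n_states Number of ordinal states in the categorical modality
#'   (default 5, mimicking copy-number calls from deletion to amplification).
#' @param clinical_bins States per underlying clinical factor before one-hot
#'   expansion (default 5).
#' @param seed Integer seed.
#' @param metabric_scale If `TRUE`, override sizes to 1980 samples and
#'   1000/1000/350 features.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 500L, latent_rank = 4L, n_classes = 2L,
                           d_continuous = 100L, d_categorical = 100L,
                           d_clinical = 50L, signal_split = 1,
                           noise_sd = 0.1, class_sep = 4, n_states = 5L,
                           clinical_bins = 5L, seed = 42L,
                           metabric_scale = FALSE) {
  if (metabric_scale) {
    n_samples <- 1980L; d_continuous <- 1000L; d_categorical <- 1000L
    d_clinical <- 350L
  }
  spec <- list(n_samples = as.integer(n_samples),
               latent_rank = as.integer(latent_rank),
               n_classes = as.integer(n_classes),
               d_continuous = as.integer(d_continuous),
               d_categorical = as.integer(d_categorical),
               d_clinical = as.integer(d_clinical),
               signal_split = signal_split, noise_sd = noise_sd,
               class_sep = class_sep, n_states = as.integer(n_states),
               clinical_bins = as.integer(clinical_bins),
               seed = as.integer(seed))
  if (!spec$n_classes %in% c(2L, 6L, 10L)) {
    stop("n_classes must be 2, 6 or 10")
  }
  if (spec$latent_rank >= min(d_continuous, d_categorical, d_clinical)) {
    stop("latent_rank must be below every modality width")
  }
  if (spec$n_classes > spec$n_samples / 10) {
    stop("need at least 10 samples per class")
  }
  if (spec$signal_split <= 0 || spec$signal_split > 1) {
    stop("signal_split must lie in (0, 1]")
  }
  if (spec$noise_sd < 0) stop("noise_sd must be nonnegative")
  class(spec) <- "synthetic_spec"
  spec
}

# Class centers: scaled random directions with guaranteed pairwise
# separation (orthonormalized when k >= n_classes - 1).
class_centers <- function(n_classes, k, sep) {
  if (n_classes == 2L) {
    dir <- rep(1 / sqrt(k), k)
    return(rbind(-sep / 2 * dir, sep / 2 * dir))
  }
  raw <- matrix(stats::rnorm(n_classes * k), n_classes, k)
  centers <- raw / sqrt(rowSums(raw^2)) * sep
  centers
}

# Loading matrix with unit-norm columns; rows = features, cols = k factors.
# `visible` marks which latent coordinates this modality may load on.
loading_matrix <- function(d, k, visible) {
  W <- matrix(stats::rnorm(d * k), d, k)
  W[, !visible] <- 0
  nrm <- sqrt(colSums(W^2))
  nrm[nrm == 0] <- 1
  sweep(W, 2L, nrm, "/") * sqrt(d / sum(visible))
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Generate a synthetic multi-omic dataset with known latent structure
#'
#' Latent factors `h` are drawn from a mixture of `n_classes` Gaussians
#' (unit within-class standard deviation; the component is the class).
#' The continuous modality is `logistic(W1 h + noise)`; the categorical
#' modality thresholds `W2 h + noise` into `n_states` ordinal states at the
#' marginal quantiles, then smooths them into \[0,1\]; the clinical modality
#' discretizes `W3 h + noise` factor columns into `clinical_bins` quantile
#' bins and one-hot expands them. `signal_split < 1` partitions the latent
#' coordinates between the continuous modality and the other two, which
#' makes each modality alone only partially informative about the class.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a [multiomic_dataset()] with label task
#'   `"class"`) and `truth` (list: latent matrix `h`, integer `class`,
#'   per-modality loading matrices, the visibility masks, and the class
#'   centers).
#' @export
generate_multiomic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; k <- spec$latent_rank
  centers <- class_centers(spec$n_classes, k, spec$class_sep)
  cls <- sample.int(spec$n_classes, n, replace = TRUE)
  h <- centers[cls, , drop = FALSE] + matrix(stats::rnorm(n * k), n, k)

  n_vis1 <- max(1L, ceiling(spec$signal_split * k))
  vis1 <- seq_len(k) <= n_vis1
  vis2 <- if (spec$signal_split >= 1) rep(TRUE, k) else !vis1
  if (!any(vis2)) vis2 <- rep(TRUE, k)

  W1 <- loading_matrix(spec$d_continuous, k, vis1)
  W2 <- loading_matrix(spec$d_categorical, k, vis2)
  n_clin_factors <- max(1L, spec$d_clinical %/% spec$clinical_bins)
  W3 <- loading_matrix(n_clin_factors, k, vis2)

  lin1 <- h %*% t(W1) + matrix(stats::rnorm(n * spec$d_continuous,
                                            sd = spec$noise_sd), n)
  X1 <- logistic(lin1)

  lin2 <- h %*% t(W2) + matrix(stats::rnorm(n * spec$d_categorical,
                                            sd = spec$noise_sd), n)
  states <- seq_len(spec$n_states) - 1L
  qs <- stats::quantile(lin2, probs = seq_len(spec$n_states - 1L) / spec$n_states,
                        names = FALSE)
  st <- matrix(findInterval(lin2, qs), n)
  X2 <- smooth_categorical(st, states)

  lin3 <- h %*% t(W3) + matrix(stats::rnorm(n * n_clin_factors,
                                            sd = spec$noise_sd), n)
  blocks <- lapply(seq_len(n_clin_factors), function(j) {
    discretize_and_onehot(lin3[, j], n_bins = spec$clinical_bins,
                          colname_prefix = paste0("f", j, "."))
  })
  X3 <- do.call(cbind, blocks)
  if (ncol(X3) < spec$d_clinical) {  # pad with uninformative indicators
    extra <- matrix(0, n, spec$d_clinical - ncol(X3))
    X3 <- cbind(X3, extra)
  } else if (ncol(X3) > spec$d_clinical) {
    X3 <- X3[, seq_len(spec$d_clinical), drop = FALSE]
  }

  ids <- sprintf("S%04d", seq_len(n))
  colnames(X1) <- sprintf("g%d", seq_len(ncol(X1)))
  colnames(X2) <- sprintf("c%d", seq_len(ncol(X2)))
  colnames(X3) <- sprintf("k%d", seq_len(ncol(X3)))
  specs <- list(modality_spec("mrna", "continuous", ncol(X1)),
                modality_spec("cna", "categorical", ncol(X2)),
                modality_spec("clin", "categorical", ncol(X3)))
  ds <- multiomic_dataset(ids,
                          list(mrna = X1, cna = X2, clin = X3),
                          specs,
                          list(class = factor(paste0("C", cls))))
  list(dataset = ds,
       truth = list(h = h, class = cls, centers = centers,
                    loadings = list(mrna = W1, cna = W2, clin = W3),
                    visible = list(mrna = vis1, cna = vis2, clin = vis2)))
}

#' Split-signal scenario: class signal divided across two modalities
#'
#' Generates a two-modality dataset (continuous + categorical) in which the
#' class-informative latent coordinates are partitioned between the
#' modalities, so that each modality alone supports strictly lower Bayes
#' accuracy than the two together. Used to test the benefit of integration.
#'
#' @param spec A [synthetic_spec()] with `signal_split` strictly inside
#'   (0, 1).
#' @return As [generate_multiomic()], but the dataset holds only the
#'   `mrna` and `cna` modalities, and `truth` additionally reports
#'   `bayes_accuracy`: estimated held-out accuracy of a Gaussian classifier
#'   on the visible latent coordinates of each modality and on all of them.
#' @export
split_signal_scenario <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$signal_split <= 0 || spec$signal_split >= 1) {
    stop("signal_split must lie strictly inside (0, 1)")
  }
  gen <- generate_multiomic(spec)
  ds <- gen$dataset
  specs2 <- ds$specs[1:2]
  ds2 <- multiomic_dataset(ds$sample_ids, ds$modalities[c("mrna", "cna")],
                           specs2, list(class = factor(
                             attr(ds$labels$class, "levels")[ds$labels$class])))
  truth <- gen$truth
  truth$bayes_accuracy <- c(
    mrna = latent_bayes_accuracy(truth$h[, truth$visible$mrna, drop = FALSE],
                                 truth$class, spec$seed),
    cna = latent_bayes_accuracy(truth$h[, truth$visible$cna, drop = FALSE],
                                truth$class, spec$seed),
    joint = latent_bayes_accuracy(truth$h, truth$class, spec$seed))
  list(dataset = ds2, truth = truth)
}

# Held-out accuracy of a Gaussian naive Bayes classifier on (a subset of)
# the true latent coordinates: an upper reference for what any method can
# recover from the corresponding modality.
latent_bayes_accuracy <- function(h, cls, seed = 1L) {
  folds <- make_stratified_folds(cls, n_folds = 2L, seed = seed)
  accs <- vapply(0:1, function(f) {
    tr <- fold_train_idx(folds, f); te <- fold_test_idx(folds, f)
    fit <- e1071::naiveBayes(as.data.frame(h[tr, , drop = FALSE]),
                             factor(cls[tr]))
    mean(as.character(stats::predict(fit,
                                     as.data.frame(h[te, , drop = FALSE]))) ==
           as.character(cls[te]))
  }, numeric(1))
  mean(accs)
}
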
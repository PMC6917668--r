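#' Specify the latent-space regularizer
#'
#' The composite objective adds `beta` times a divergence between the
#' encoding distribution and the standard-normal prior: either the
#' closed-form Kullback-Leibler divergence of the diagonal-Gaussian
#' posterior, or the Maximum Mean Discrepancy between sampled codes and
#' prior draws under a Gaussian kernel. The grid sweep uses
#' `beta` in \{1, 10, 15, 25, 50, 100\}; any positive weight is accepted.
#'
#' @param kind `"MMD"` or `"KL"`.
#' @param beta Positive regularization weight.
#' @param kernel_sigma Gaussian kernel bandwidth for MMD. `NULL` (default)
#'   means the bandwidth heuristic `sigma^2 = latent_size / 2` is applied at
#'   model-build time.
#' @return An object of class `reg_spec`.
#' @export
reg_spec <- function(kind = c("MMD", "KL"), beta = 50, kernel_sigma = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    stop("beta must be a nonnegative real")
  }
  if (!is.null(kernel_sigma) && (!is.numeric(kernel_sigma) || kernel_sigma <= 0)) {
    stop("kernel_sigma must be positive")
  }
  structure(list(kind = kind, beta = beta, kernel_sigma = kernel_sigma),
            class = "reg_spec")
}

#' Mean-squared-error reconstruction loss
#'
#' Mean over all entries (samples and features) of the squared residual.
#' The mean reduction, rather than a sum, keeps the loss comparable across
#' modalities of different widths so a single `beta` weighs the regularizer
#' consistently.
#'
#' @param x,x_hat Numeric matrices (or vectors) of identical shape.
#' @return Nonnegative scalar.
#' @export
mse_recon <- function(x, x_hat) {
  x <- as.matrix(x); x_hat <- as.matrix(x_hat)
  if (!identical(dim(x), dim(x_hat))) stop("shape mismatch in mse_recon")
  mean((x - x_hat)^2)
}

#' Binary cross-entropy reconstruction loss with soft targets
#'
#' Mean over all entries of `-(t log p + (1-t) log(1-p))`. Targets may be
#' soft (label-smoothed ordinal states in \[0,1\]); predictions are clipped
#' to `[eps, 1-eps]` for numerical safety.
#'
#' @param t Target matrix with entries in \[0,1\].
#' @param p Predicted probability matrix, same shape.
#' @param eps Clipping constant (default `1e-7`).
#' @return Nonnegative scalar.
#' @export
bce_recon <- function(t, p, eps = 1e-7) {
  t <- as.matrix(t); p <- as.matrix(p)
  if (!identical(dim(t), dim(p))) stop("shape mismatch in bce_recon")
  if (min(t) < 0 || max(t) > 1) stop("targets must lie in [0,1]")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

#' Closed-form KL divergence of a diagonal Gaussian from N(0, I)
#'
#' For a posterior `N(mu, diag(exp(logvar)))` the divergence from the
#' standard-normal prior is
#' `0.5 * sum_j (mu_j^2 + exp(logvar_j) - 1 - logvar_j)`.
#' Given matrices (one row per sample) the per-sample divergences are
#' averaged over the batch.
#'
#' @param mu Mean vector, or samples-by-latent matrix.
#' @param logvar Log-variance vector/matrix of the same shape.
#' @return Nonnegative scalar; zero iff `mu = 0` and `logvar = 0`.
#' @export
kl_gaussian <- function(mu, logvar) {
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1L)
  if (is.null(dim(logvar))) logvar <- matrix(logvar, nrow = 1L)
  mu <- as.matrix(mu); logvar <- as.matrix(logvar)
  if (!identical(dim(mu), dim(logvar))) stop("shape mismatch in kl_gaussian")
  if (any(!is.finite(mu)) || any(!is.finite(logvar))) {
    stop("non-finite inputs to kl_gaussian")
  }
  per_sample <- 0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
  mean(per_sample)
}

#' Gaussian (RBF) kernel between two vectors
#'
#' `k(z, z') = exp(-||z - z'||^2 / (2 sigma^2))`; symmetric, in (0, 1],
#' and equal to 1 iff the vectors coincide.
#'
#' @param z,z_prime Numeric vectors of equal length.
#' @param sigma Positive bandwidth.
#' @return Scalar in (0, 1\].
#' @export
gaussian_kernel <- function(z, z_prime, sigma = 1) {
  if (length(z) != length(z_prime)) stop("length mismatch in gaussian_kernel")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  exp(-sum((z - z_prime)^2) / (2 * sigma^2))
}

# All pairwise squared Euclidean distances between rows of A and B.
pairwise_sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Biased Maximum Mean Discrepancy between two sample sets
#'
#' The biased V-statistic under the Gaussian kernel:
#' `mean(K(Zq, Zq)) + mean(K(Zp, Zp)) - 2 mean(K(Zq, Zp))`,
#' diagonal terms included. This estimator is nonnegative and exactly zero
#' when the two sets coincide. At training time `Zq` holds codes sampled
#' from the encoder and `Zp` fresh draws from the standard-normal prior.
#'
#' @param Zq n-by-d matrix of codes.
#' @param Zp m-by-d matrix of prior draws.
#' @param sigma Positive kernel bandwidth.
#' @return Nonnegative scalar.
#' @export
mmd_biased <- function(Zq, Zp, sigma = 1) {
  Zq <- as.matrix(Zq); Zp <- as.matrix(Zp)
  if (ncol(Zq) != ncol(Zp)) stop("dimension mismatch in mmd_biased")
  if (nrow(Zq) < 1L || nrow(Zp) < 1L) stop("empty sample set in mmd_biased")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  s2 <- 2 * sigma^2
  kqq <- mean(exp(-pairwise_sqdist(Zq, Zq) / s2))
  kpp <- mean(exp(-pairwise_sqdist(Zp, Zp) / s2))
  kqp <- mean(exp(-pairwise_sqdist(Zq, Zp) / s2))
  max(kqq + kpp - 2 * kqp, 0)
}

#' Combine per-modality reconstruction terms with a weighted regularizer
#'
#' `total = sum(recon_terms) + beta * reg_value`. The per-term breakdown is
#' retained so training traces can be decomposed.
#'
#' @param recon_terms Named numeric vector or list, one reconstruction loss
#'   per modality.
#' @param reg A [reg_spec()].
#' @param reg_value Scalar value of the regularizer.
#' @return An object of class `objective_value` with fields `total`,
#'   `recon_per_modality`, `regularizer`, `beta`.
#' @export
composite_objective <- function(recon_terms, reg, reg_value) {
  recon <- unlist(recon_terms)
  structure(list(total = sum(recon) + reg$beta * reg_value,
                 recon_per_modality = recon,
                 regularizer = reg_value,
                 beta = reg$beta),
            class = "objective_value")
}

#' @export
print.objective_value <- function(x, ...) {
  cat(sprintf("<objective_value> total %.6g = [%s] + %.6g * %.6g\n",
              x$total, paste(sprintf("%s %.6g", names(x$recon_per_modality),
                                     x$recon_per_modality), collapse = " + "),
              x$beta, x$regularizer))
  invisible(x)
}
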
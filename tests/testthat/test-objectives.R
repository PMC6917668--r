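test_that("squared-error reconstruction matches an element-loop oracle", {
  x <- matrix(c(0, 1), 1)
  expect_equal(mse_recon(x, x), 0)
  expect_equal(mse_recon(matrix(c(0, 1), 1), matrix(c(1, 0), 1)), 1)
  set.seed(12)
  a <- matrix(rnorm(35), 5, 7)
  b <- matrix(rnorm(35), 5, 7)
  acc <- 0
  for (i in 1:5) for (j in 1:7) acc <- acc + (a[i, j] - b[i, j])^2
  expect_equal(mse_recon(a, b), acc / 35, tolerance = 1e-12)
  expect_error(mse_recon(a, b[, 1:3]), "shape")
})

test_that("cross entropy scores soft targets correctly", {
  expect_equal(bce_recon(matrix(0.5), matrix(0.5)), log(2), tolerance = 1e-12)
  # perfect prediction limit: loss vanishes with the clipping epsilon
  expect_lt(bce_recon(matrix(1), matrix(1)), 1e-6)
  expect_equal(bce_recon(matrix(0.25), matrix(0.25)),
               -(0.25 * log(0.25) + 0.75 * log(0.75)), tolerance = 1e-12)
  expect_error(bce_recon(matrix(1.5), matrix(0.5)), "\\[0,1\\]")
})

test_that("closed-form KL matches hand values and is nonnegative", {
  expect_equal(kl_gaussian(rep(0, 4), rep(0, 4)), 0)
  expect_equal(kl_gaussian(1, 0), 0.5)
  # N(0, 4) vs N(0, 1): 0.5 * (4 - 1 - log 4)
  expect_equal(kl_gaussian(0, log(4)), 0.5 * (4 - 1 - log(4)),
               tolerance = 1e-12)
  set.seed(8)
  for (rep in 1:20) {
    d <- sample(1:4, 1)
    mu <- rnorm(d); lv <- rnorm(d, sd = 0.7)
    expect_gte(kl_gaussian(mu, lv), 0)
  }
  expect_error(kl_gaussian(c(1, Inf), c(0, 0)), "finite")
})

test_that("KL averages per-sample divergences over a batch", {
  mu <- rbind(c(0, 0), c(1, 2))
  lv <- rbind(c(0, 0), c(0.3, -0.2))
  per <- c(kl_gaussian(mu[1, ], lv[1, ]), kl_gaussian(mu[2, ], lv[2, ]))
  expect_equal(kl_gaussian(mu, lv), mean(per), tolerance = 1e-12)
})

test_that("the Gaussian kernel is symmetric, bounded and exact at zero distance", {
  set.seed(4)
  z <- rnorm(6)
  expect_equal(gaussian_kernel(z, z, 2), 1)
  expect_equal(gaussian_kernel(0, 1, 1), exp(-0.5), tolerance = 1e-12)
  for (rep in 1:5) {
    a <- rnorm(4); b <- rnorm(4); s <- runif(1, 0.5, 3)
    k <- gaussian_kernel(a, b, s)
    expect_equal(k, gaussian_kernel(b, a, s))
    expect_true(k > 0 && k <= 1)
    expect_equal(k, exp(-sum((a - b)^2) / (2 * s^2)))
  }
  expect_error(gaussian_kernel(1, 2, 0), "positive")
})

test_that("biased MMD matches the hand-expanded single-pair case and is zero on identical sets", {
  expect_equal(mmd_biased(matrix(0), matrix(1), 1), 2 - 2 * exp(-0.5),
               tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:5) {
    Z <- matrix(rnorm(24), 6, 4)
    expect_identical(mmd_biased(Z, Z, runif(1, 0.5, 3)), 0)
  }
})

test_that("biased MMD is permutation-invariant and vanishes for large same-distribution samples", {
  set.seed(13)
  Zq <- matrix(rnorm(40), 10, 4); Zp <- matrix(rnorm(40), 10, 4)
  v1 <- mmd_biased(Zq, Zp, 1.5)
  v2 <- mmd_biased(Zq[sample(10), ], Zp[sample(10), ], 1.5)
  expect_equal(v1, v2, tolerance = 1e-12)

  vals <- vapply(c(10, 100, 1000), function(n) {
    set.seed(99)
    mmd_biased(matrix(rnorm(n * 3), n, 3), matrix(rnorm(n * 3), n, 3), 1)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[3], 0.01)
})

test_that("the composite objective decomposes exactly", {
  expect_equal(composite_objective(c(a = 1, b = 2), reg_spec("KL", beta = 0),
                                   0.7)$total, 3)
  expect_equal(composite_objective(c(a = 1, b = 2), reg_spec("MMD", beta = 50),
                                   0.1)$total, 8)
  set.seed(6)
  for (rep in 1:10) {
    rec <- runif(3, 0, 5)
    names(rec) <- c("x", "y", "z")
    beta <- sample(c(1, 10, 15, 25, 50, 100), 1)
    regv <- runif(1)
    obj <- composite_objective(rec, reg_spec("MMD", beta = beta), regv)
    expect_equal(obj$total, sum(obj$recon_per_modality) +
                   obj$beta * obj$regularizer, tolerance = 1e-12)
  }
})
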
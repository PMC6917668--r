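# Embedding that is trivially linearly separable by class.
separable_embed_fn <- function(labels, gap = 10) {
  y <- as.integer(factor(labels))
  X <- cbind(y * gap + rnorm(length(y), sd = 0.1),
             rnorm(length(y)))
  function(train_idx, test_idx) {
    list(train = X[train_idx, , drop = FALSE],
         test = X[test_idx, , drop = FALSE])
  }
}

test_that("all three classifiers recover a separable embedding perfectly", {
  set.seed(2)
  labels <- factor(rep(c("a", "b"), 40))
  folds <- make_stratified_folds(labels, 5, seed = 1)
  fn <- separable_embed_fn(labels)
  for (cl in c("gaussian-naive-bayes", "svm-rbf", "random-forest")) {
    res <- cross_validated_accuracy(fn, labels, folds, downstream_spec(cl))
    expect_equal(res$mean_test_accuracy, 1.0)
    expect_equal(res$mean_test_accuracy, mean(res$fold_test_accuracy))
    expect_equal(res$mean_train_accuracy, mean(res$fold_train_accuracy))
    expect_true(all(res$fold_test_accuracy >= 0 &
                      res$fold_test_accuracy <= 1))
  }
})

test_that("labels shuffled independently of features score at the majority rate", {
  set.seed(8)
  n <- 100
  X <- matrix(rnorm(n * 3), n, 3)
  fn <- function(tr, te) list(train = X[tr, , drop = FALSE],
                              test = X[te, , drop = FALSE])
  rates <- vapply(1:20, function(s) {
    set.seed(s)
    labels <- factor(sample(rep(c("a", "b"), c(60, 40))))
    folds <- make_stratified_folds(labels, 5, seed = s)
    cross_validated_accuracy(fn, labels, folds)$mean_test_accuracy
  }, numeric(1))
  majority <- 0.6
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - majority), 3 * max(se, 0.02))
})

test_that("a fold whose training partition is single-class is rejected", {
  labels <- factor(c(rep("a", 10), rep("b", 10)))
  folds <- make_stratified_folds(labels, 5, seed = 1)
  folds$fold_of <- c(rep(0:4, 2), rep(0, 10))  # degenerate hand-made folds
  fn <- separable_embed_fn(labels)
  expect_error(cross_validated_accuracy(fn, labels, folds), "single class")
})

test_that("grid enumeration covers the cartesian product exactly once", {
  expect_equal(length(enumerate_grid("X")), 108L)
  axes <- list(latent_size = c(16L, 32L), dense_size = 128L,
               regularizer = "MMD", beta = c(1, 50))
  small <- enumerate_grid("CNC", axes)
  expect_equal(length(small), 4L)
  keys <- vapply(small, function(c) {
    paste(c$latent_size, c$dense_size, c$regularizer$kind, c$regularizer$beta)
  }, character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("configuration selection maximizes accuracy with documented tie-breaks", {
  row <- function(ls, ds, reg, beta, acc) {
    data.frame(architecture = "X", latent_size = ls, dense_size = ds,
               regularizer = reg, beta = beta, epochs = 10L, seed = 1L,
               task = "class", classifier = "gaussian-naive-bayes",
               mean_train_accuracy = acc, mean_test_accuracy = acc)
  }
  single <- row(16, 128, "KL", 1, 0.8)
  expect_equal(select_configuration(single)$latent_size, 16L)

  res <- rbind(row(16, 128, "KL", 1, 0.7), row(32, 256, "MMD", 50, 0.9),
               row(64, 512, "KL", 100, 0.85))
  best <- select_configuration(res)
  expect_equal(best$latent_size, 32L)
  expect_identical(best$regularizer$kind, "MMD")

  # exhaustive tie-break oracle: smaller ls, then ds, then MMD first,
  # then smaller beta
  tied <- rbind(row(64, 128, "KL", 1, 0.9), row(16, 512, "KL", 10, 0.9),
                row(16, 128, "KL", 50, 0.9), row(16, 128, "MMD", 100, 0.9),
                row(16, 128, "MMD", 25, 0.9))
  want <- tied[order(tied$latent_size, tied$dense_size,
                     ifelse(tied$regularizer == "MMD", 0, 1), tied$beta), ][1, ]
  got <- select_configuration(tied)
  expect_equal(got$latent_size, want$latent_size)
  expect_equal(got$dense_size, want$dense_size)
  expect_identical(got$regularizer$kind, want$regularizer)
  expect_equal(got$regularizer$beta, want$beta)
})

test_that("PCA baseline is exact at full rank and ordered in variance", {
  set.seed(6)
  X <- matrix(rnorm(30 * 8), 30, 8)
  p <- pca_baseline(X, X, k = 8)
  back <- p$train %*% t(p$rotation)
  back <- sweep(back, 2, p$center, "+")
  expect_lt(max(abs(back - X)), 1e-8)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_error(pca_baseline(X, X, k = 20), "exceeds")
})

test_that("PCA recovers a planted two-factor subspace", {
  set.seed(9)
  n <- 200
  W <- qr.Q(qr(matrix(rnorm(12 * 2), 12, 2)))  # orthonormal true loadings
  H <- matrix(rnorm(n * 2), n, 2) %*% diag(c(4, 2))
  X <- H %*% t(W) + matrix(rnorm(n * 12, sd = 0.02), n, 12)
  p <- pca_baseline(X, X, k = 2)
  # principal angles between estimated and true subspaces
  sv <- svd(t(W) %*% p$rotation)$d
  angles <- acos(pmin(1, sv)) * 180 / pi
  expect_true(all(angles < 5))
})

test_that("raw baselines concatenate modalities in spec order", {
  ds <- tiny_dataset()
  one <- raw_baseline(ds, "cna")
  expect_identical(unname(one), unname(ds$modalities$cna))
  both <- raw_baseline(ds, c("mrna", "cna"))
  expect_equal(ncol(both), 22L)
  expect_identical(unname(both[, 1:12]), unname(ds$modalities$mrna))
  all3 <- raw_baseline(ds)
  expect_equal(ncol(all3), 32L)
  expect_error(raw_baseline(ds, "methylation"), "unknown modality")
})

test_that("a reduced grid sweep runs, streams to disk and resumes from it", {
  ds <- tiny_dataset()
  axes <- list(latent_size = 4L, dense_size = 8L, regularizer = "MMD",
               beta = c(1, 50))
  base <- quick_config("X", epochs = 2, seed = 1)
  store <- withr::local_tempfile(fileext = ".tsv")
  res <- run_config_grid("X", ds, axes = axes, base = base, store = store)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$mean_test_accuracy >= 0 & res$mean_test_accuracy <= 1))
  expect_true(file.exists(store))

  # poison the stored accuracy; a resumed run must reuse, not recompute
  tab <- read.delim(store)
  tab$mean_test_accuracy <- c(0.123, 0.456)
  write.table(tab, store, sep = "\t", quote = FALSE, row.names = FALSE)
  res2 <- run_config_grid("X", ds, axes = axes, base = base, store = store)
  expect_equal(sort(res2$mean_test_accuracy), c(0.123, 0.456))
})

test_that("t-SNE export writes coordinates that separate planted clusters", {
  set.seed(10)
  n <- 60
  emb <- rbind(matrix(rnorm(n / 2 * 4, mean = 0, sd = 0.3), n / 2, 4),
               matrix(rnorm(n / 2 * 4, mean = 6, sd = 0.3), n / 2, 4))
  labels <- rep(c("lo", "hi"), each = n / 2)
  out <- withr::local_tempfile(fileext = ".tsv")
  coords <- tsne_export(emb, labels, out, seed = 4, figure = FALSE)
  expect_equal(nrow(coords), n)
  expect_named(coords, c("tsne1", "tsne2", "label"))
  expect_true(file.exists(out))

  coords2 <- tsne_export(emb, labels, out, seed = 4, figure = FALSE)
  expect_equal(coords, coords2)

  xy <- as.matrix(coords[, 1:2])
  d <- as.matrix(dist(xy))
  same <- outer(labels, labels, "==")
  intra <- mean(d[same & upper.tri(d)])
  inter <- mean(d[!same & upper.tri(d)])
  expect_gt(inter, intra)

  expect_error(tsne_export(matrix(c(1, NA, 3, 4, 5, 6, 7, 8, 9, 10), 5, 2),
                           rep("a", 5), out), "non-finite")
})
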
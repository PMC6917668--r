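make_tables <- function(ids1, ids2) {
  set.seed(3)
  list(
    expr = data.frame(id = ids1,
                      g1 = seq_along(ids1), g2 = rev(seq_along(ids1))),
    cna = data.frame(id = ids2,
                     c1 = rep_len(c(-2L, 0L, 2L), length(ids2)),
                     c2 = rep_len(c(-1L, 1L), length(ids2)))
  )
}

specs2 <- list(modality_spec("expr", "continuous", 2),
               modality_spec("cna", "categorical", 2))

test_that("assembly inner-joins on sample IDs and preprocesses per spec", {
  tabs <- make_tables(c("a", "b", "c"), c("b", "c", "d"))
  labels <- data.frame(id = c("a", "b", "c", "d"),
                       cls = c("x", "x", "y", "y"))
  ds <- assemble_dataset(tabs, specs2, labels)
  expect_identical(ds$sample_ids, c("b", "c"))
  expect_equal(n_samples(ds), 2L)
  for (m in ds$modalities) {
    expect_equal(nrow(m), 2L)
    expect_true(all(m >= 0 & m <= 1))
  }
  expect_equal(length(ds$labels$cls), 2L)
})

test_that("assembly is invariant to input row order", {
  ids <- c("s1", "s2", "s3", "s4")
  tabs <- make_tables(ids, ids)
  labels <- data.frame(id = ids, cls = c("x", "y", "x", "y"))
  ds1 <- assemble_dataset(tabs, specs2, labels)
  perm <- c(3, 1, 4, 2)
  tabs2 <- lapply(tabs, function(t) t[perm, ])
  ds2 <- assemble_dataset(tabs2, specs2, labels[rev(perm), ])
  expect_identical(ds1$sample_ids, ds2$sample_ids)
  expect_equal(ds1$modalities, ds2$modalities)
  expect_identical(ds1$labels, ds2$labels)
})

test_that("assembly rejects duplicate and disjoint ID sets", {
  tabs <- make_tables(c("a", "a", "b"), c("a", "b", "c"))
  labels <- data.frame(id = c("a", "b"), cls = c("x", "y"))
  expect_error(assemble_dataset(tabs, specs2, labels), "duplicate")
  tabs2 <- make_tables(c("a", "b", "c"), c("d", "e", "f"))
  expect_error(assemble_dataset(tabs2, specs2, labels), "no sample IDs")
})

test_that("modality specs enforce the loss/activation pairing", {
  sp <- modality_spec("cna", "categorical", 10)
  expect_identical(sp$recon_loss, "cross-entropy")
  expect_identical(sp$output_activation, "sigmoid")
  sp <- modality_spec("expr", "continuous", 10)
  expect_identical(sp$recon_loss, "squared-error")
  expect_identical(sp$output_activation, "linear")
  expect_error(modality_spec("x", "continuous", 0), "positive")
})

test_that("dataset container validates alignment, range and class counts", {
  ids <- paste0("s", 1:4)
  m <- matrix(runif(8), 4, 2)
  expect_error(multiomic_dataset(ids, list(a = m[1:3, ]),
                                 list(modality_spec("a", "continuous", 2)),
                                 list(y = factor(c(1, 2, 1, 2)))),
               "rows")
  expect_error(multiomic_dataset(ids, list(a = m * 3),
                                 list(modality_spec("a", "continuous", 2)),
                                 list(y = factor(c(1, 2, 1, 2)))),
               "\\[0,1\\]")
  expect_error(multiomic_dataset(ids, list(a = m),
                                 list(modality_spec("a", "continuous", 2)),
                                 list(y = factor(rep(1, 4)))),
               "classes")
})

test_that("datasets round-trip through the TSV/YAML format", {
  ds <- tiny_dataset(n = 30)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "mrna.tsv")))
  expect_true(file.exists(file.path(dir, "labels.tsv")))
  ds2 <- read_dataset(dir)
  expect_identical(ds2$sample_ids, ds$sample_ids)
  for (nm in names(ds$modalities)) {
    expect_equal(unname(ds2$modalities[[nm]]), unname(ds$modalities[[nm]]),
                 tolerance = 1e-8)
  }
  expect_equal(unclass(ds2$labels$class), unclass(ds$labels$class),
               ignore_attr = TRUE)
})
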
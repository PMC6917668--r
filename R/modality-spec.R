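#' Describe one data modality
#'
#' A modality spec records what kind of data a sample-by-feature block holds
#' and, consequently, which reconstruction loss and output activation the
#' decoder branch for that block must use. Continuous blocks (e.g. normalized
#' mRNA expression scaled to \[0,1\]) are scored with squared error through a
#' linear output; categorical blocks (e.g. ordinal copy-number states smoothed
#' into \[0,1\], or one-hot clinical indicators) are scored with binary cross
#' entropy through a sigmoid output, treating the smoothed values as soft
#' Bernoulli targets.
#'
#' @param name Short identifier, e.g. `"mrna"`, `"cna"`, `"clin"`.
#' @param kind One of `"continuous"` or `"categorical"`.
#' @param n_features Positive integer; width of the block.
#' @return An object of class `modality_spec` with fields `name`, `kind`,
#'   `n_features`, `recon_loss` (`"squared-error"` or `"cross-entropy"`) and
#'   `output_activation` (`"linear"` or `"sigmoid"`).
#' @examples
#' modality_spec("mrna", "continuous", 1000)
#' modality_spec("cna", "categorical", 1000)
#' @export
modality_spec <- function(name, kind = c("continuous", "categorical"),
                          n_features) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_features <- as.integer(n_features)
  if (length(n_features) != 1L || is.na(n_features) || n_features < 1L) {
    stop("n_features must be a positive integer")
  }
  spec <- list(
    name = name,
    kind = kind,
    n_features = n_features,
    recon_loss = if (kind == "categorical") "cross-entropy" else "squared-error",
    output_activation = if (kind == "categorical") "sigmoid" else "linear"
  )
  class(spec) <- "modality_spec"
  spec
}

#' @export
print.modality_spec <- function(x, ...) {
  cat(sprintf("<modality_spec> %s: %s, %d features, %s loss, %s output\n",
              x$name, x$kind, x$n_features, x$recon_loss,
              x$output_activation))
  invisible(x)
}

stopifnot_spec_list <- function(specs) {
  if (!is.list(specs) || length(specs) < 1L ||
      !all(vapply(specs, inherits, logical(1), "modality_spec"))) {
    stop("`specs` must be a non-empty list of modality_spec objects")
  }
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("modality names must be unique")
  invisible(specs)
}

#' Construct a multi-omic dataset container
#'
#' Bundles aligned per-modality matrices with one or more label vectors. All
#' matrices must have one row per sample, in the order of `sample_ids`, and
#' (after preprocessing) entries in \[0,1\]. Labels are stored as integer
#' class codes with a `levels` attribute.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param modalities Named list of numeric matrices, names matching the specs.
#' @param specs List of [modality_spec()] objects, one per modality, in the
#'   same order as `modalities`.
#' @param labels Named list of factors or integer vectors (one per
#'   classification task), each of length `length(sample_ids)` with at least
#'   two distinct classes.
#' @return An object of class `multiomic_dataset`.
#' @export
multiomic_dataset <- function(sample_ids, modalities, specs, labels) {
  stopifnot_spec_list(specs)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  n <- length(sample_ids)
  spec_names <- vapply(specs, `[[`, character(1), "name")
  if (!identical(sort(names(modalities)), sort(spec_names))) {
    stop("modality names must match spec names")
  }
  modalities <- modalities[spec_names]
  for (i in seq_along(specs)) {
    m <- modalities[[i]]
    if (!is.matrix(m) || !is.numeric(m)) {
      stop(sprintf("modality '%s' is not a numeric matrix", spec_names[i]))
    }
    if (nrow(m) != n) {
      stop(sprintf("modality '%s' has %d rows; expected %d",
                   spec_names[i], nrow(m), n))
    }
    if (ncol(m) != specs[[i]]$n_features) {
      stop(sprintf("modality '%s' has %d columns; spec says %d",
                   spec_names[i], ncol(m), specs[[i]]$n_features))
    }
    if (anyNA(m) || any(!is.finite(m))) {
      stop(sprintf("modality '%s' contains non-finite values", spec_names[i]))
    }
    if (min(m) < 0 || max(m) > 1) {
      stop(sprintf("modality '%s' has entries outside [0,1]; preprocess first",
                   spec_names[i]))
    }
    rownames(modalities[[i]]) <- sample_ids
  }
  if (!is.list(labels) || is.null(names(labels)) || !all(nzchar(names(labels)))) {
    stop("`labels` must be a named list")
  }
  labels <- lapply(labels, function(y) {
    f <- if (is.factor(y)) droplevels(y) else factor(y)
    if (length(f) != n) stop("label vector length does not match sample count")
    if (nlevels(f) < 2L) stop("each label vector needs at least 2 classes")
    code <- as.integer(f)
    attr(code, "levels") <- levels(f)
    code
  })
  structure(list(sample_ids = sample_ids, modalities = modalities,
                 specs = specs, labels = labels),
            class = "multiomic_dataset")
}

#' @export
print.multiomic_dataset <- function(x, ...) {
  cat(sprintf("<multiomic_dataset> %d samples\n", length(x$sample_ids)))
  for (s in x$specs) {
    cat(sprintf("  %s: %s, %d features\n", s$name, s$kind, s$n_features))
  }
  for (nm in names(x$labels)) {
    cat(sprintf("  label '%s': %d classes\n", nm,
                length(attr(x$labels[[nm]], "levels"))))
  }
  invisible(x)
}

#' Number of samples in a dataset
#' @param dataset A `multiomic_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(dataset) length(dataset$sample_ids)

#' Subset a multi-omic dataset by row
#'
#' @param dataset A `multiomic_dataset`.
#' @param idx Integer row indices (may repeat or reorder).
#' @return A `multiomic_dataset` restricted to those rows. Labels keep their
#'   original level sets so class codes remain comparable across subsets.
#' @export
dataset_rows <- function(dataset, idx) {
  mods <- lapply(dataset$modalities, function(m) m[idx, , drop = FALSE])
  labs <- lapply(dataset$labels, function(y) {
    out <- y[idx]
    attr(out, "levels") <- attr(y, "levels")
    out
  })
  structure(list(sample_ids = dataset$sample_ids[idx], modalities = mods,
                 specs = dataset$specs, labels = labs),
            class = "multiomic_dataset")
}
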
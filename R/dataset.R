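#' Assemble aligned, preprocessed modalities into a dataset
#'
#' Inner-joins per-modality tables and a label table on their sample-ID
#' column, orders samples lexicographically by ID, and applies per-spec
#' preprocessing: min-max scaling for continuous modalities and ordinal
#' smoothing for categorical ones (binary 0/1 matrices pass through
#' unchanged). Mixed clinical tables should be expanded with
#' [preprocess_clinical()] beforehand and declared categorical.
#'
#' @param tables Named list of data frames (names matching spec names), each
#'   with the sample ID in its first column and one feature per remaining
#'   column.
#' @param specs List of [modality_spec()] objects, one per table. A spec's
#'   `n_features` may be `NA` to be filled from the table width.
#' @param labels Data frame: sample ID in the first column, one column per
#'   classification task.
#' @param categorical_states Ordered state list used to smooth categorical
#'   modalities whose values are not already within \[0,1\]; default `-2:2`
#'   (copy-number style). Ignored for tables already in \[0,1\].
#' @param preprocess Apply per-spec preprocessing (default `TRUE`). Set to
#'   `FALSE` for tables that already hold preprocessed \[0,1\] values, e.g.
#'   when re-reading a dataset written by [write_dataset()]; values are then
#'   validated but left untouched.
#' @return A [multiomic_dataset()].
#' @export
assemble_dataset <- function(tables, specs, labels, categorical_states = -2:2,
                             preprocess = TRUE) {
  stopifnot_spec_list(specs)
  spec_names <- vapply(specs, `[[`, character(1), "name")
  if (!is.list(tables) || !identical(sort(names(tables)), sort(spec_names))) {
    stop("`tables` must be a named list matching the spec names")
  }
  if (!is.data.frame(labels) || ncol(labels) < 2L) {
    stop("`labels` must be a data frame with an ID column and >=1 label column")
  }
  ids_of <- function(df, what) {
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) {
      stop(sprintf("duplicate sample IDs in %s", what))
    }
    ids
  }
  id_sets <- c(lapply(spec_names, function(nm) ids_of(tables[[nm]], nm)),
               list(ids_of(labels, "labels")))
  common <- Reduce(intersect, id_sets)
  if (length(common) == 0L) stop("no sample IDs shared across all tables")
  common <- sort(common)

  mods <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    df <- tables[[spec$name]]
    m <- as.matrix(df[match(common, as.character(df[[1L]])), -1L, drop = FALSE])
    storage.mode(m) <- "double"
    if (anyNA(m) || any(!is.finite(m))) {
      stop(sprintf("modality '%s' contains non-finite values", spec$name))
    }
    if (preprocess) {
      if (spec$kind == "continuous") {
        m <- apply(m, 2L, scale_minmax)
      } else if (min(m) < 0 || max(m) > 1) {
        m <- smooth_categorical(m, states = categorical_states)
      }
    }
    if (is.na(spec$n_features)) {
      specs[[i]] <- modality_spec(spec$name, spec$kind, ncol(m))
    }
    rownames(m) <- common
    mods[[spec$name]] <- m
  }

  lab_rows <- labels[match(common, as.character(labels[[1L]])), -1L, drop = FALSE]
  lab_list <- as.list(lab_rows)
  multiomic_dataset(common, mods, specs, lab_list)
}

#' Write a dataset to delimited text files
#'
#' One TSV per modality (`<name>.tsv`, first column `sample_id`), a
#' `labels.tsv`, and a YAML manifest recording the modality specs.
#'
#' @param dataset A `multiomic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (spec in dataset$specs) {
    m <- dataset$modalities[[spec$name]]
    df <- data.frame(sample_id = dataset$sample_ids, m, check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(spec$name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  labs <- data.frame(sample_id = dataset$sample_ids)
  for (nm in names(dataset$labels)) {
    labs[[nm]] <- attr(dataset$labels[[nm]], "levels")[dataset$labels[[nm]]]
  }
  utils::write.table(labs, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    modalities = lapply(dataset$specs, function(s) {
      list(name = s$name, kind = s$kind, n_features = s$n_features)
    }),
    n_samples = n_samples(dataset),
    label_tasks = names(dataset$labels),
    preprocessed = TRUE
  )
  path <- file.path(dir, "dataset.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory holding `<modality>.tsv`, `labels.tsv` and
#'   `dataset.yaml`.
#' @return A `multiomic_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "dataset.yaml"))
  specs <- lapply(manifest$modalities, function(m) {
    modality_spec(m$name, m$kind, m$n_features)
  })
  tables <- lapply(specs, function(s) {
    utils::read.table(file.path(dir, paste0(s$name, ".tsv")), header = TRUE,
                      sep = "\t", check.names = FALSE,
                      colClasses = NA, stringsAsFactors = FALSE)
  })
  names(tables) <- vapply(specs, `[[`, character(1), "name")
  labels <- utils::read.table(file.path(dir, "labels.tsv"), header = TRUE,
                              sep = "\t", check.names = FALSE,
                              stringsAsFactors = FALSE)
  assemble_dataset(tables, specs, labels,
                   preprocess = !isTRUE(manifest$preprocessed))
}
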
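#' Build stratified cross-validation folds
#'
#' Assigns every sample to exactly one of `n_folds` folds so that, within
#' each class, fold counts differ from exact proportional allocation by at
#' most one sample. The assignment is a pure function of
#' `(labels, n_folds, seed)`: class members are shuffled with a private RNG
#' stream seeded from `seed` and dealt round-robin, with the dealing start
#' rotated per class so the oversized folds are spread across classes. Reusing
#' the same assignment for every experiment keeps all methods comparable on
#' identical splits.
#'
#' @param labels Factor or integer class vector.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed (default 42); recorded in the result.
#' @param task Optional task name carried in the result.
#' @return An object of class `fold_assignment` with fields `task`,
#'   `n_folds`, `fold_of` (integer vector in `0:(n_folds-1)`), `seed`.
#' @export
make_stratified_folds <- function(labels, n_folds = 5L, seed = 42L,
                                  task = "task") {
  f <- if (is.factor(labels)) labels else factor(labels)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  counts <- table(f)
  too_small <- names(counts)[counts < n_folds]
  if (length(too_small) > 0L) {
    stop(sprintf("class(es) with fewer members than folds: %s",
                 paste(too_small, collapse = ", ")))
  }
  fold_of <- integer(length(f))
  rng <- local_rng(seed)
  for (ci in seq_along(levels(f))) {
    idx <- which(f == levels(f)[ci])
    idx <- idx[rng$sample_perm(length(idx))]
    # rotate the round-robin start so remainder samples spread across folds
    start <- (ci - 1L) %% n_folds
    fold_of[idx] <- (start + seq_along(idx) - 1L) %% n_folds
  }
  structure(list(task = task, n_folds = n_folds, fold_of = fold_of,
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> task '%s': %d samples, %d folds, seed %d\n",
              x$task, length(x$fold_of), x$n_folds, x$seed))
  print(table(fold = x$fold_of))
  invisible(x)
}

#' Indices of the test partition of one fold
#' @param folds A `fold_assignment`.
#' @param fold Fold number in `0:(n_folds-1)`.
#' @return Integer indices.
#' @export
fold_test_idx <- function(folds, fold) which(folds$fold_of == fold)

#' Indices of the training partition of one fold
#' @inheritParams fold_test_idx
#' @return Integer indices.
#' @export
fold_train_idx <- function(folds, fold) which(folds$fold_of != fold)

# Private RNG stream that does not disturb the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  with_state <- function(expr_fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    expr_fn()
  }
  list(
    sample_perm = function(n) with_state(function() sample.int(n)),
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd))
  )
}
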
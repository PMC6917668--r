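#' Min-max scale a numeric vector to \[0,1\]
#'
#' Maps `x` to `(x - min) / (max - min)`. A constant column maps to all zeros
#' rather than being dropped, so feature indexing is preserved. Idempotent:
#' scaling an already-scaled column leaves it unchanged.
#'
#' @param column Numeric vector with finite entries.
#' @return Numeric vector in \[0,1\], same length.
#' @examples
#' scale_minmax(c(2, 4, 6))   # 0, 0.5, 1
#' scale_minmax(c(5, 5, 5))   # 0, 0, 0
#' @export
scale_minmax <- function(column) {
  if (length(column) == 0L) stop("cannot scale an empty column")
  if (!is.numeric(column) || any(!is.finite(column))) {
    stop("column must be numeric with finite values")
  }
  rng <- range(column)
  if (rng[1] == rng[2]) return(rep(0, length(column)))
  (column - rng[1]) / (rng[2] - rng[1])
}

#' Smooth ordinal categorical states into \[0,1\]
#'
#' Maps each integer state to its equally spaced position over the ordered
#' state list, so an S-state variable becomes values
#' `0, 1/(S-1), ..., 1`. The smoothed matrix is scored by binary cross
#' entropy as soft Bernoulli targets (label smoothing), which keeps an
#' S-state copy-number feature one column wide instead of S one-hot columns.
#'
#' @param matrix Integer-state matrix (or vector).
#' @param states Ordered vector of admissible states, e.g. `-2:2`.
#' @return Numeric matrix of the same shape with entries in \[0,1\].
#' @examples
#' smooth_categorical(matrix(c(-2, 0, 2), 1), states = -2:2)  # 0, 0.5, 1
#' @export
smooth_categorical <- function(matrix, states) {
  if (length(states) < 2L || anyDuplicated(states)) {
    stop("`states` must list at least two distinct states")
  }
  x <- as.matrix(matrix)
  pos <- match(x, states)
  if (anyNA(pos)) {
    bad <- unique(x[is.na(pos)])
    stop(sprintf("entries outside the state list: %s",
                 paste(bad, collapse = ", ")))
  }
  out <- (pos - 1) / (length(states) - 1)
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Invert ordinal smoothing
#'
#' Recovers the original states from a smoothed matrix by nearest state
#' position; exact for any matrix produced by [smooth_categorical()].
#'
#' @param smoothed Numeric matrix in \[0,1\].
#' @param states The ordered state list used for smoothing.
#' @return Matrix of states, same shape.
#' @export
unsmooth_categorical <- function(smoothed, states) {
  x <- as.matrix(smoothed)
  grid <- seq(0, 1, length.out = length(states))
  idx <- vapply(as.vector(x), function(v) which.min(abs(grid - v)), integer(1))
  out <- states[idx]
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Discretize a numeric column and one-hot encode the bins
#'
#' Bins are delimited by quantile edges so that (for continuous data) counts
#' are near-equal across bins. If the column has fewer distinct quantile
#' edges than requested — e.g. heavily tied data or a constant column — the
#' bins collapse to the distinct edges with a warning; a constant column
#' yields a single all-ones column.
#'
#' @param column Numeric vector with finite entries.
#' @param n_bins Number of bins, at least 2.
#' @param colname_prefix Prefix for the emitted indicator column names.
#' @return Binary matrix with one row per entry, one column per realized bin;
#'   every row sums to exactly 1.
#' @examples
#' discretize_and_onehot(c(1, 2, 3), n_bins = 3)
#' @export
discretize_and_onehot <- function(column, n_bins = 5L, colname_prefix = "bin") {
  if (length(column) == 0L) stop("cannot discretize an empty column")
  if (!is.numeric(column) || any(!is.finite(column))) {
    stop("column must be numeric with finite values")
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be at least 2")
  edges <- stats::quantile(column, probs = seq(0, 1, length.out = n_bins + 1L),
                           names = FALSE, type = 7)
  uedges <- unique(edges)
  if (length(uedges) < 2L) {
    warning("constant column: collapsing to a single bin")
    out <- matrix(1, nrow = length(column), ncol = 1L,
                  dimnames = list(NULL, paste0(colname_prefix, 1L)))
    return(out)
  }
  if (length(uedges) < length(edges)) {
    warning(sprintf("fewer distinct quantile edges than bins: %d bins collapsed to %d",
                    n_bins, length(uedges) - 1L))
  }
  bin <- cut(column, breaks = uedges, include.lowest = TRUE, labels = FALSE)
  k <- length(uedges) - 1L
  out <- matrix(0, nrow = length(column), ncol = k,
                dimnames = list(NULL, paste0(colname_prefix, seq_len(k))))
  out[cbind(seq_along(column), bin)] <- 1
  out
}

#' Preprocess a clinical-style mixed table into a binary matrix
#'
#' Numeric columns are quantile-discretized ([discretize_and_onehot()]) and
#' character/factor columns are one-hot encoded; the indicator blocks are
#' concatenated in column order. The result is a binary matrix suitable for a
#' categorical (cross-entropy) modality.
#'
#' @param table Data frame of numeric and categorical columns (no sample-ID
#'   column).
#' @param n_bins Bins per numeric column (default 5).
#' @return Binary matrix, one row per input row.
#' @export
preprocess_clinical <- function(table, n_bins = 5L) {
  stopifnot(is.data.frame(table), ncol(table) >= 1L)
  blocks <- lapply(names(table), function(nm) {
    col <- table[[nm]]
    if (is.numeric(col)) {
      discretize_and_onehot(col, n_bins = n_bins,
                            colname_prefix = paste0(nm, "."))
    } else {
      f <- factor(col)
      out <- matrix(0, nrow = length(f), ncol = nlevels(f),
                    dimnames = list(NULL, paste0(nm, ".", levels(f))))
      out[cbind(seq_along(f), as.integer(f))] <- 1
      out
    }
  })
  do.call(cbind, blocks)
}
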
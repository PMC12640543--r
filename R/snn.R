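#' Hudson's nearest-neighbour statistic
#'
#' For each sequence `i`, the nearest-neighbour set is *all* other
#' sequences at the minimal distance from `i` (ties, including exact
#' duplicates at distance zero, are kept and weighted fractionally).
#' `x_i` is the fraction of that set sharing `i`'s location label and
#' `Snn` is the mean of the `x_i`. `Snn = 1` means nearest neighbours
#' always come from the same location (complete geographic structure);
#' values near the null expectation mean geography is uninformative.
#' Because only within-row distance ranks matter, the statistic is
#' invariant under any strictly increasing transform of the distances.
#'
#' Pairs with missing distances (e.g. TN93 saturation) are ignored within
#' a row; a sequence with more than `max_row_missing` of its row missing
#' is dropped entirely with a warning.
#'
#' @param d Distance-mode matrix (symmetric, zero diagonal), e.g. from
#'   [distance_matrix()].
#' @param labels Location label per sequence, in matrix order (or named
#'   by sequence id).
#' @param max_row_missing Fraction of a row that may be missing before
#'   the sequence is dropped (default 0.10).
#' @return The Snn statistic in `[0, 1]`.
#' @export
snn_statistic <- function(d, labels, max_row_missing = 0.10) {
  prep <- snn_prepare(d, labels, max_row_missing)
  snn_from_sets(prep$nn_sets, prep$labels)
}

# Validate inputs, drop rows with too many missing distances, and return
# the per-sequence nearest-neighbour index sets (computed once; they do
# not depend on the labels, so permutation tests reuse them).
snn_prepare <- function(d, labels, max_row_missing = 0.10) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (length(labels) != n) {
    if (!is.null(names(labels)) && !is.null(rownames(m)) &&
        all(rownames(m) %in% names(labels))) {
      labels <- labels[rownames(m)]
    } else {
      abort("labels must have one entry per matrix row")
    }
  }
  labels <- as.character(labels)
  if (anyNA(labels)) abort("labels contain NA")
  if (n < 2) abort("need at least 2 sequences")

  diag(m) <- NA # diagonal never counts as missing or as a neighbour
  frac_missing <- (rowSums(is.na(m)) - 1) / (n - 1)
  drop <- frac_missing > max_row_missing
  if (any(drop)) {
    warn(paste0(sum(drop), " sequence(s) dropped: > ",
                round(100 * max_row_missing), "% of distances missing"))
    m <- m[!drop, !drop, drop = FALSE]
    labels <- labels[!drop]
    diag(m) <- NA
    n <- nrow(m)
    if (n < 2) abort("fewer than 2 sequences remain after dropping")
  }
  if (length(unique(labels)) < 2) {
    warn("all sequences share one label: Snn is trivially 1")
  }
  nn_sets <- lapply(seq_len(n), function(i) {
    row <- m[i, ]
    mn <- min(row, na.rm = TRUE)
    which(row == mn)
  })
  list(nn_sets = nn_sets, labels = labels)
}

snn_from_sets <- function(nn_sets, labels) {
  mean(vapply(seq_along(nn_sets), function(i) {
    mean(labels[nn_sets[[i]]] == labels[i])
  }, numeric(1)))
}

#' Permutation test for geographic structure via Snn
#'
#' Location labels are permuted without replacement `n_permutations`
#' times; the one-sided p-value is
#' `(1 + #permutations with Snn* >= observed) / (1 + n_permutations)`,
#' so the smallest attainable p is `1/(n_permutations + 1)`.
#'
#' @inheritParams snn_statistic
#' @param n_permutations Number of label permutations (default 5000).
#' @param seed Optional integer seed for reproducibility.
#' @param keep_permutations Keep the permuted Snn values in the result?
#' @return An object of class `snn_result`: a list with `snn`, `n`,
#'   `p_value`, `n_permutations`, `per_label_counts`, `seed` and
#'   (optionally) `permuted_values`.
#' @export
snn_permutation_test <- function(d, labels, n_permutations = 5000, seed = NULL,
                                 max_row_missing = 0.10, keep_permutations = FALSE) {
  if (!is.numeric(n_permutations) || n_permutations < 1) {
    abort("n_permutations must be >= 1")
  }
  n_permutations <- as.integer(n_permutations)
  if (!is.null(seed)) set.seed(seed)
  prep <- snn_prepare(d, labels, max_row_missing)
  obs <- snn_from_sets(prep$nn_sets, prep$labels)
  perm <- vapply(seq_len(n_permutations), function(b) {
    snn_from_sets(prep$nn_sets, sample(prep$labels))
  }, numeric(1))
  p <- (1 + sum(perm >= obs)) / (1 + n_permutations)
  structure(
    list(
      snn = obs,
      n = length(prep$labels),
      p_value = p,
      n_permutations = n_permutations,
      per_label_counts = table(prep$labels),
      seed = seed,
      permuted_values = if (keep_permutations) perm else NULL
    ),
    class = "snn_result"
  )
}

#' @export
print.snn_result <- function(x, ...) {
  cat(sprintf("Snn = %.3f over %d sequences, %d locations\n",
              x$snn, x$n, length(x$per_label_counts)))
  cat(sprintf("permutation p = %.4g (%d permutations)\n",
              x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
tidy.snn_result <- function(x, ...) {
  tibble(
    statistic = x$snn,
    p_value = x$p_value,
    n = x$n,
    n_locations = length(x$per_label_counts),
    n_permutations = x$n_permutations
  )
}

#' @export
glance.snn_result <- function(x, ...) tidy(x)
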
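#' @section Distances:
#' Pairwise comparisons are computed over *comparable columns* only:
#' alignment columns where both sequences carry an unambiguous base
#' (A, C, G or T). Columns with a gap, N or any ambiguity code in either
#' sequence are excluded from numerator and denominator alike.
#' @name viropop-distances
NULL

# Encode a residue string as integers A=1, C=2, G=3, T=4; anything else
# (gaps, N, ambiguity codes) becomes NA and is excluded from comparisons.
encode_residues <- function(x) {
  match(strsplit(toupper(x), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

vp_abort <- function(msg, class) {
  abort(msg, class = c(class, "viropop_error"))
}

#' Percent nucleotide identity between two aligned sequences
#'
#' Identity is `100 * matches / (matches + mismatches)` over comparable
#' columns (both sequences unambiguous A/C/G/T). Gap or ambiguity in
#' either sequence removes the column from the comparison entirely.
#'
#' @param a,b Aligned residue strings of equal length.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  ea <- if (is.integer(a)) a else encode_residues(a)
  eb <- if (is.integer(b)) b else encode_residues(b)
  if (length(ea) != length(eb)) {
    vp_abort("sequences have unequal aligned lengths", "viropop_error_length")
  }
  ok <- !is.na(ea) & !is.na(eb)
  n <- sum(ok)
  if (n == 0L) {
    vp_abort("no comparable columns: identity undefined", "viropop_error_undefined_identity")
  }
  100 * sum(ea[ok] == eb[ok]) / n
}

#' Tamura-Nei (1993) distance between two aligned sequences
#'
#' The TN93 model distinguishes the two transition classes (A<->G and
#' C<->T) from transversions and allows unequal base frequencies. Base
#' frequencies are estimated from the two sequences pooled, over their
#' comparable columns. With `P1` and `P2` the observed proportions of
#' A<->G and C<->T differences, `Q` the transversion proportion and
#' `piR = piA + piG`, `piY = piC + piT`:
#'
#' \deqn{d = -k_1 \log w_1 - k_2 \log w_2 - k_3 \log w_3}
#'
#' with \eqn{k_1 = 2\pi_A\pi_G/\pi_R}, \eqn{k_2 = 2\pi_T\pi_C/\pi_Y},
#' \eqn{k_3 = 2(\pi_R\pi_Y - \pi_A\pi_G\pi_Y/\pi_R - \pi_T\pi_C\pi_R/\pi_Y)},
#' \eqn{w_1 = 1 - P_1/k_1 - Q/(2\pi_R)}, \eqn{w_2 = 1 - P_2/k_2 - Q/(2\pi_Y)}
#' and \eqn{w_3 = 1 - Q/(2\pi_R\pi_Y)}.
#'
#' Saturated pairs (any log argument not positive) raise an error of class
#' `viropop_error_saturation` rather than returning a capped value, so
#' that downstream nearest-neighbour computations never see silently
#' truncated distances.
#'
#' @param a,b Aligned residue strings of equal length.
#' @return The TN93 distance (substitutions per site), with the estimated
#'   model quantities attached as attribute `"params"` (a list with
#'   `P1`, `P2`, `Q`, `pi`, `piR`, `piY`, `n_sites`).
#' @export
tn93_distance <- function(a, b) {
  ea <- if (is.integer(a)) a else encode_residues(a)
  eb <- if (is.integer(b)) b else encode_residues(b)
  if (length(ea) != length(eb)) {
    vp_abort("sequences have unequal aligned lengths", "viropop_error_length")
  }
  ok <- !is.na(ea) & !is.na(eb)
  n <- sum(ok)
  if (n == 0L) {
    vp_abort("no comparable columns: distance undefined", "viropop_error_undefined_identity")
  }
  xa <- ea[ok]
  xb <- eb[ok]

  # pooled base frequencies over comparable columns
  counts <- tabulate(xa, 4L) + tabulate(xb, 4L)
  pi <- counts / (2 * n)
  names(pi) <- c("A", "C", "G", "T")
  piR <- pi[["A"]] + pi[["G"]]
  piY <- pi[["C"]] + pi[["T"]]
  if (piR == 0 || piY == 0) {
    vp_abort("degenerate base composition: piR or piY is zero", "viropop_error_degenerate")
  }

  diff <- xa != xb
  pair_min <- pmin(xa, xb)
  pair_max <- pmax(xa, xb)
  P1 <- sum(diff & pair_min == 1L & pair_max == 3L) / n # A<->G
  P2 <- sum(diff & pair_min == 2L & pair_max == 4L) / n # C<->T
  Q <- sum(diff) / n - P1 - P2

  k1 <- 2 * pi[["A"]] * pi[["G"]] / piR
  k2 <- 2 * pi[["T"]] * pi[["C"]] / piY
  k3 <- 2 * (piR * piY - pi[["A"]] * pi[["G"]] * piY / piR - pi[["T"]] * pi[["C"]] * piR / piY)

  w1 <- 1 - (if (k1 > 0) P1 / k1 else 0) - Q / (2 * piR)
  w2 <- 1 - (if (k2 > 0) P2 / k2 else 0) - Q / (2 * piY)
  w3 <- 1 - Q / (2 * piR * piY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
    vp_abort("saturated pair: TN93 distance undefined (log argument <= 0)",
             "viropop_error_saturation")
  }

  d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  if (P1 + P2 + Q == 0) d <- 0
  structure(
    max(d, 0),
    params = list(P1 = P1, P2 = P2, Q = Q, pi = pi, piR = piR, piY = piY, n_sites = n)
  )
}

#' Pairwise distance or identity matrix for an aligned sequence set
#'
#' @param sequences A tibble with columns `seq_id` and `residues`
#'   (aligned, equal lengths), e.g. from [read_aligned_fasta()].
#' @param mode `"tn93"` for Tamura-Nei distances or `"identity"` for
#'   percent identity.
#' @param max_missing Maximum tolerated fraction of failed (saturated or
#'   undefined) pairs before the matrix is declared unusable. Failed pairs
#'   are recorded as `NA` with a warning and listed in the
#'   `"failed_pairs"` attribute.
#' @return A symmetric numeric matrix with `seq_id` dimnames, diagonal 0
#'   (tn93) or 100 (identity), class `pairwise_matrix` and attribute
#'   `mode`.
#' @export
distance_matrix <- function(sequences, mode = c("tn93", "identity"), max_missing = 0.10) {
  mode <- match.arg(mode)
  check_alignment(sequences, min_n = 2L)
  ids <- sequences$seq_id
  if (anyDuplicated(ids)) abort("duplicate seq_id in sequence table")
  n <- length(ids)
  enc <- lapply(sequences$residues, encode_residues)
  fun <- if (mode == "tn93") tn93_distance else pairwise_identity

  m <- matrix(if (mode == "tn93") 0 else 100, n, n, dimnames = list(ids, ids))
  failed <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- tryCatch(as.numeric(fun(enc[[i]], enc[[j]])), viropop_error = function(e) {
        failed[[length(failed) + 1L]] <<- tibble(
          id1 = ids[i], id2 = ids[j], reason = conditionMessage(e)
        )
        NA_real_
      })
      m[i, j] <- m[j, i] <- v
    }
  }
  n_pairs <- n * (n - 1L) / 2L
  n_failed <- length(failed)
  if (n_failed > 0) {
    warn(paste0(n_failed, " of ", n_pairs, " pairs undefined (recorded as NA)"))
    if (n_failed / n_pairs > max_missing) {
      vp_abort(
        paste0("matrix unusable: ", n_failed, "/", n_pairs, " pairs undefined (> ",
               round(100 * max_missing), "%)"),
        "viropop_error_matrix"
      )
    }
  }
  structure(
    m,
    mode = mode,
    failed_pairs = if (n_failed) bind_rows(failed) else NULL,
    class = c("pairwise_matrix", class(m))
  )
}

#' @export
tidy.pairwise_matrix <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(
    id1 = ids[idx[, 1]],
    id2 = ids[idx[, 2]],
    value = x[idx],
    mode = attr(x, "mode")
  )
}

#' Distribution of pairwise percent identities
#'
#' Computes all `n(n-1)/2` pairwise identities for an aligned set, the
#' summary the segment-diversity comparisons are built on. Identities are
#' conventionally reported to 0.1 percentage point; full precision is
#' retained in the returned values.
#'
#' @param sequences Aligned sequence tibble (`seq_id`, `residues`).
#' @return A tibble `id1, id2, identity` with attributes `median` and
#'   `n_pairs`. Undefined pairs propagate as `NA` with a warning.
#' @export
identity_distribution <- function(sequences) {
  m <- distance_matrix(sequences, mode = "identity", max_missing = 1)
  out <- tidy(m) |>
    select("id1", "id2", identity = "value")
  structure(
    out,
    median = median(out$identity, na.rm = TRUE),
    n_pairs = nrow(out)
  )
}

#' Median pairwise identity of an aligned set
#'
#' @inheritParams identity_distribution
#' @return A single percent value.
#' @export
median_pairwise_identity <- function(sequences) {
  attr(identity_distribution(sequences), "median")
}
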
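# Small deterministic fixtures built in code.

BASES <- c("A", "C", "G", "T")

random_sequence <- function(len, prob = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(BASES, len, replace = TRUE, prob = prob), collapse = "")
}

# mutate `k` distinct positions of a residue string to a different base
mutate_sequence <- function(x, k) {
  chars <- strsplit(x, "")[[1]]
  idx <- sample(length(chars), k)
  for (i in idx) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# a planted two-cluster alignment: `n_per` sequences per cluster,
# ~within_mut mutations inside clusters, ~between_mut between them
planted_two_clusters <- function(n_per = 3, len = 400, within_mut = 4,
                                 between_mut = 80, seed = 101) {
  set.seed(seed)
  root1 <- random_sequence(len)
  root2 <- mutate_sequence(root1, between_mut)
  tibble::tibble(
    seq_id = c(paste0("a", seq_len(n_per)), paste0("b", seq_len(n_per))),
    residues = c(
      vapply(seq_len(n_per), function(i) mutate_sequence(root1, within_mut), character(1)),
      vapply(seq_len(n_per), function(i) mutate_sequence(root2, within_mut), character(1))
    )
  )
}

# a small fast simulation configuration
small_sim_config <- function(seed, n_samples = 30, ...) {
  sim_config(
    n_samples = n_samples,
    segment_lengths = c(RNA1 = 800, RNA2 = 700, RNA3 = 600, chaq = 700),
    seed = seed,
    ...
  )
}

# independent Fisher two-sided oracle: full hypergeometric enumeration
fisher_enumeration_p <- function(tbl) {
  a <- tbl[1, 1]
  r1 <- sum(tbl[1, ])
  c1 <- sum(tbl[, 1])
  n <- sum(tbl)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# identity matrix for a set of per-sample sequences keyed by sample id
sample_identity_matrix <- function(dataset, seg) {
  sub <- dplyr::filter(
    dataset$sequences, .data$segment == seg, endsWith(.data$seq_id, "_1")
  )
  sub$seq_id <- sub$sample_id
  distance_matrix(sub, mode = "identity")
}

# single-segment sample map for discordance screens
galbut_sample_map <- function(samples, seg_x, seg_y) {
  tibble::tibble(
    sample_id = samples,
    seq_id_x = paste(samples, seg_x, "1", sep = "_"),
    seq_id_y = paste(samples, seg_y, "1", sep = "_")
  )
}
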
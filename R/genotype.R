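#' Assign genotypes by identity clustering plus monophyly
#'
#' Genotypes (major clades) are groups of sequences sharing at least
#' `threshold` percent pairwise nucleotide identity under single-linkage
#' clustering, checked for monophyly on the tree. Non-monophyletic
#' identity clusters are flagged, never silently merged or split.
#' Within each major clade, subclades are assigned by re-clustering at
#' `subclade_threshold` (a heuristic refinement; major-clade membership
#' is the primary result).
#'
#' @param identity An identity-mode [distance_matrix()] result.
#' @param tree Optional rooted tree whose tip labels are a subset of the
#'   matrix ids (unrooted trees are midpoint rooted first). When `NULL`,
#'   monophyly is not checked and flags are `NA`.
#' @param threshold Major-clade identity threshold in percent
#'   (default 95).
#' @param subclade_threshold Subclade identity threshold (default 97).
#' @return A tibble `seq_id, clade, subclade, monophyletic` of class
#'   `genotype_assignment`. Clade labels `G1, G2, ...` are ordered by
#'   decreasing clade size (ties broken by smallest member id, so labels
#'   do not depend on input order). Attributes: `clade_summary` (per
#'   clade: size, minimum within-clade identity, monophyly),
#'   `max_between_identity`, `threshold`.
#' @export
assign_genotypes <- function(identity, tree = NULL, threshold = 95,
                             subclade_threshold = 97) {
  if (is.null(attr(identity, "mode")) || attr(identity, "mode") != "identity") {
    abort("assign_genotypes needs an identity-mode matrix")
  }
  m <- unclass(identity)
  ids <- rownames(m)
  if (!is.null(tree)) {
    extra <- setdiff(tree$tip.label, ids)
    if (length(extra) > 0) {
      abort(paste0("tree tips absent from identity matrix: ",
                   paste(head(extra, 5), collapse = ", ")))
    }
    if (!ape::is.rooted(tree)) tree <- midpoint_root(tree)
  }

  cl <- cluster_by_identity(m, threshold)
  # deterministic labels: by size, then smallest member id
  members <- split(ids, cl)
  ord <- order(-lengths(members), vapply(members, min, character(1)))
  members <- members[ord]
  labels <- paste0("G", seq_along(members))
  names(members) <- labels
  clade_of <- setNames(rep(labels, lengths(members)), unlist(members))

  clade_summary <- imap(members, function(ms, lab) {
    sub <- m[ms, ms, drop = FALSE]
    within_min <- if (length(ms) > 1) min(sub[upper.tri(sub)], na.rm = TRUE) else NA_real_
    other <- setdiff(ids, ms)
    between_max <- if (length(other) > 0) {
      max(m[ms, other, drop = FALSE], na.rm = TRUE)
    } else {
      NA_real_
    }
    mono <- if (is.null(tree)) {
      NA
    } else {
      in_tree <- intersect(ms, tree$tip.label)
      if (length(in_tree) == 0) NA else is_monophyletic(tree, in_tree)
    }
    tibble(clade = lab, n = length(ms), min_within_identity = within_min,
           max_between_identity = between_max, monophyletic = mono)
  }) |>
    bind_rows()

  # subclades: re-cluster within each major clade at the higher threshold
  subclade_of <- clade_of
  for (lab in labels) {
    ms <- members[[lab]]
    if (length(ms) < 2) next
    sub_cl <- cluster_by_identity(m[ms, ms, drop = FALSE], subclade_threshold)
    sub_members <- split(ms, sub_cl)
    if (length(sub_members) < 2) next
    sord <- order(-lengths(sub_members), vapply(sub_members, min, character(1)))
    sub_members <- sub_members[sord]
    for (k in seq_along(sub_members)) {
      subclade_of[sub_members[[k]]] <- paste0(lab, ".", k)
    }
  }

  out <- tibble(
    seq_id = ids,
    clade = unname(clade_of[ids]),
    subclade = unname(subclade_of[ids]),
    monophyletic = clade_summary$monophyletic[match(unname(clade_of[ids]), clade_summary$clade)]
  )
  structure(
    out,
    clade_summary = clade_summary,
    max_between_identity = suppressWarnings(max(c(clade_summary$max_between_identity, -Inf),
                                                na.rm = TRUE)),
    threshold = threshold,
    class = c("genotype_assignment", class(out))
  )
}

# Single-linkage clustering of an identity matrix: sequences join a
# cluster when their identity is >= threshold. NA identities are treated
# as fully divergent.
cluster_by_identity <- function(m, threshold) {
  n <- nrow(m)
  if (n == 1L) {
    return(setNames(1L, rownames(m)))
  }
  d <- 100 - m
  d[is.na(d)] <- 100
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "single")
  cutree(hc, h = 100 - threshold)
}

#' @export
glance.genotype_assignment <- function(x, ...) {
  cs <- attr(x, "clade_summary")
  tibble(
    n_sequences = nrow(x),
    n_clades = nrow(cs),
    n_monophyletic = sum(cs$monophyletic, na.rm = TRUE),
    min_within_identity = suppressWarnings(min(cs$min_within_identity, na.rm = TRUE)),
    max_between_identity = attr(x, "max_between_identity"),
    threshold = attr(x, "threshold")
  )
}

#' Coinfection profile: distinct genotypes per sample and segment
#'
#' Within each sample-by-segment group, coding-complete sequences that
#' share at least `distinct_threshold` percent identity are treated as
#' one genotype (single linkage); the genotype count is the number of
#' such groups. A sample is *coinfected* when any segment carries two or
#' more distinct genotypes, and a *complete coinfection* when all three
#' genome segments do. The chaq satellite is counted per segment like
#' the others but is not required for completeness.
#'
#' @param records Tibble with `seq_id`, `sample_id`, `segment`,
#'   `residues` (sequences aligned within each segment).
#' @param distinct_threshold Identity above which two sequences are the
#'   same genotype (default 99).
#' @return A tibble `sample_id, segment, n_genotypes` of class
#'   `coinfection_profile`, with attributes `samples` (per-sample
#'   `coinfected` / `complete_coinfection` flags) and
#'   `coinfection_rate` (= coinfected samples / samples profiled).
#' @export
coinfection_profile <- function(records, distinct_threshold = 99) {
  needed <- c("seq_id", "sample_id", "segment", "residues")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("records lack columns: ", paste(missing, collapse = ", ")))
  }
  counts <- records |>
    group_by(.data$sample_id, .data$segment) |>
    summarise(
      n_genotypes = count_distinct_genotypes(.data$residues, distinct_threshold),
      .groups = "drop"
    )
  samples <- counts |>
    group_by(.data$sample_id) |>
    summarise(
      coinfected = any(.data$n_genotypes >= 2),
      complete_coinfection = all(GALBUT_SEGMENTS %in% .data$segment) &&
        all(.data$n_genotypes[.data$segment %in% GALBUT_SEGMENTS] >= 2),
      .groups = "drop"
    )
  structure(
    counts,
    samples = samples,
    coinfection_rate = mean(samples$coinfected),
    distinct_threshold = distinct_threshold,
    class = c("coinfection_profile", class(counts))
  )
}

count_distinct_genotypes <- function(residues, threshold) {
  k <- length(residues)
  if (k == 1L) {
    return(1L)
  }
  m <- matrix(100, k, k, dimnames = list(seq_len(k), seq_len(k)))
  enc <- lapply(residues, encode_residues)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      m[i, j] <- m[j, i] <- pairwise_identity(enc[[i]], enc[[j]])
    }
  }
  max(cluster_by_identity(m, threshold))
}

#' @export
glance.coinfection_profile <- function(x, ...) {
  s <- attr(x, "samples")
  tibble(
    n_samples = nrow(s),
    n_coinfected = sum(s$coinfected),
    coinfection_rate = attr(x, "coinfection_rate"),
    n_complete_coinfection = sum(s$complete_coinfection),
    distinct_threshold = attr(x, "distinct_threshold")
  )
}

#' Cross-tabulate satellite presence against helper-virus clade
#'
#' For singly infected samples, tabulates the major galbut clade against
#' presence of the chaq satellite. Samples whose clade appears in
#' `restricted_clades` (clades where the satellite is expected absent)
#' but that carry chaq are reported as violations. Coinfected samples
#' are excluded: their chaq cannot be attributed to one helper clade.
#'
#' @param samples Tibble with `sample_id`, `clade` (major galbut clade),
#'   `has_chaq` (logical) and `coinfected` (logical).
#' @param restricted_clades Character vector of clades in which chaq is
#'   expected absent; `NULL` reports the contingency table with no
#'   violations assessed.
#' @return A list of class `chaq_association` with elements
#'   `contingency` (tibble clade x chaq counts), `violations` (tibble of
#'   offending samples) and `n_excluded_coinfected`.
#' @export
chaq_association_check <- function(samples, restricted_clades = NULL) {
  no_clade <- is.na(samples$clade)
  if (any(no_clade)) {
    warn(paste0(sum(no_clade), " sample(s) without a galbut clade skipped"))
    samples <- samples[!no_clade, , drop = FALSE]
  }
  excluded <- sum(samples$coinfected)
  single <- filter(samples, !.data$coinfected)
  contingency <- single |>
    count(.data$clade, .data$has_chaq, name = "n") |>
    arrange(.data$clade, .data$has_chaq)
  violations <- if (is.null(restricted_clades)) {
    single[0, c("sample_id", "clade", "has_chaq")]
  } else {
    single |>
      filter(.data$has_chaq, .data$clade %in% restricted_clades) |>
      select("sample_id", "clade", "has_chaq")
  }
  structure(
    list(
      contingency = contingency,
      violations = violations,
      n_excluded_coinfected = excluded,
      restricted_clades = restricted_clades
    ),
    class = "chaq_association"
  )
}

#' @export
print.chaq_association <- function(x, ...) {
  cat("Satellite-clade association\n")
  print(x$contingency)
  cat(x$n_excluded_coinfected, "coinfected sample(s) excluded\n")
  if (nrow(x$violations) > 0) {
    cat(nrow(x$violations), "violation(s) of the expected restriction:\n")
    print(x$violations)
  } else {
    cat("no violations of the expected restriction\n")
  }
  invisible(x)
}
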
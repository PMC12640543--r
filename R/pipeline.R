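#' Run the full population-structure analysis
#'
#' Executes the whole pipeline on either a synthetic configuration or a
#' set of input files: per-segment identity and TN93 matrices,
#' neighbour-joining trees (midpoint rooted, short branches collapsed),
#' genotype assignment, Snn geographic-structure tests, diversity
#' medians with bootstrap comparisons, coinfection profiling,
#' reassortment discordance screens, clade concordance and the
#' satellite-association table. Every threshold used is recorded in the
#' report so the operationalized criteria are auditable.
#'
#' @param input Either a [sim_config()] (the dataset is simulated) or a
#'   list with `fasta` (named character vector of per-segment FASTA
#'   paths) and `metadata` (path to the metadata TSV).
#' @param clade_threshold Major-genotype identity threshold (default 95).
#' @param distinct_threshold Coinfection distinct-genotype identity
#'   threshold (default 99).
#' @param collapse_epsilon Branch-length threshold for polytomy collapse
#'   (default 0.001).
#' @param discordance_high,discordance_low Identity-gap thresholds for
#'   the reassortment screen (defaults 98.5 and 95).
#' @param n_permutations Snn permutations (default 5000).
#' @param restricted_chaq_clades Clades in which the satellite is
#'   expected absent (optional; used for the association check).
#' @param seed Seed for the permutation tests (and the simulation, when
#'   `input` is a configuration the seed inside it is used for data).
#' @param out_dir Optional directory: JSON + TSV report files are
#'   written there.
#' @return A list of class `analysis_report`.
#' @export
run_pipeline <- function(input,
                         clade_threshold = 95,
                         distinct_threshold = 99,
                         collapse_epsilon = 0.001,
                         discordance_high = 98.5,
                         discordance_low = 95,
                         n_permutations = 5000,
                         restricted_chaq_clades = NULL,
                         seed = 1,
                         out_dir = NULL) {
  if (inherits(input, "sim_config")) {
    dataset <- simulate_dataset(input)
    sequences <- left_join(
      dataset$sequences,
      select(dataset$metadata, "seq_id", "location", "collection_date", "species"),
      by = "seq_id"
    )
  } else {
    if (is.null(input$fasta) || is.null(input$metadata)) {
      abort("input must be a sim_config or list(fasta = <named paths>, metadata = <path>)")
    }
    for (p in c(unname(input$fasta), input$metadata)) {
      if (!file.exists(p)) abort(paste0("input file missing: ", p))
    }
    md <- read_metadata(input$metadata)
    sequences <- bind_rows(lapply(unname(input$fasta), read_aligned_fasta)) |>
      join_sequence_metadata(md)
    dataset <- NULL
  }

  segments <- intersect(segment_levels(), unique(sequences$segment))
  per_segment <- list()
  clade_tables <- list()
  for (i in seq_along(segments)) {
    seg <- segments[i]
    sub <- filter(sequences, .data$segment == seg)
    identity <- distance_matrix(sub, mode = "identity")
    tn93 <- distance_matrix(sub, mode = "tn93")
    tree <- nj_tree(tn93) |>
      midpoint_root() |>
      collapse_short_branches(collapse_epsilon)
    genotypes <- assign_genotypes(identity, tree, threshold = clade_threshold)
    idist <- identity_distribution(sub)
    snn <- snn_permutation_test(
      tn93, setNames(sub$location, sub$seq_id),
      n_permutations = n_permutations, seed = seed + i
    )
    per_segment[[seg]] <- list(
      identity = identity, tn93 = tn93, tree = tree,
      genotypes = genotypes, identity_distribution = idist, snn = snn
    )
    clade_tables[[seg]] <- genotypes |>
      as_tibble() |>
      mutate(segment = seg) |>
      left_join(select(sub, "seq_id", "sample_id"), by = "seq_id")
  }

  # diversity comparisons between segments
  diversity <- tibble(
    segment = segments,
    median_identity = map_dbl(segments, ~ attr(per_segment[[.x]]$identity_distribution, "median"))
  )
  seg_pairs <- if (length(segments) > 1) combn(segments, 2, simplify = FALSE) else list()
  diversity_tests <- map(seg_pairs, function(pr) {
    x <- per_segment[[pr[1]]]$identity_distribution$identity
    y <- per_segment[[pr[2]]]$identity_distribution$identity
    bt <- bootstrap_t_test(x, y, n_boot = 10000, seed = seed)
    tibble(segment_a = pr[1], segment_b = pr[2],
           statistic = bt$statistic, p_value = bt$p_value)
  }) |>
    bind_rows()

  # coinfection
  profile <- coinfection_profile(sequences, distinct_threshold = distinct_threshold)
  sample_flags <- attr(profile, "samples")

  # per-sample clade table (singly infected, primary sequences),
  # with labels harmonized across segments
  clades_long <- bind_rows(clade_tables) |>
    filter(!.data$sample_id %in% sample_flags$sample_id[sample_flags$coinfected])
  clades_long <- clades_long |>
    group_by(.data$sample_id, .data$segment) |>
    filter(n() == 1) |>
    ungroup()
  clades_long <- harmonize_clade_labels(clades_long, reference = segments[1])
  concordance <- clade_concordance_table(clades_long)

  # reassortment screens: every segment pair
  singly <- sample_flags$sample_id[!sample_flags$coinfected]
  discordance <- map(seg_pairs, function(pr) {
    map_x <- filter(sequences, .data$segment == pr[1], .data$sample_id %in% singly)
    map_y <- filter(sequences, .data$segment == pr[2], .data$sample_id %in% singly)
    sm <- inner_join(
      select(map_x, "sample_id", seq_id_x = "seq_id"),
      select(map_y, "sample_id", seq_id_y = "seq_id"),
      by = "sample_id"
    )
    genos <- clades_long |>
      filter(.data$segment %in% pr) |>
      select("seq_id", "clade")
    segment_discordance_pairs(
      per_segment[[pr[1]]]$identity, per_segment[[pr[2]]]$identity, sm,
      high = discordance_high, low = discordance_low,
      tree_x = per_segment[[pr[1]]]$tree, tree_y = per_segment[[pr[2]]]$tree,
      genotypes = genos, segment_x = pr[1], segment_y = pr[2]
    )
  })
  names(discordance) <- map_chr(seg_pairs, paste, collapse = "_vs_")

  # satellite association
  chaq_samples <- sequences |>
    filter(.data$segment == "chaq") |>
    pull(.data$sample_id) |>
    unique()
  rna1_clades <- clades_long |>
    filter(.data$segment == segments[1]) |>
    select("sample_id", "clade")
  assoc_input <- sample_flags |>
    left_join(rna1_clades, by = "sample_id") |>
    mutate(has_chaq = .data$sample_id %in% chaq_samples) |>
    select("sample_id", "clade", "has_chaq", "coinfected")
  chaq_assoc <- suppressWarnings(
    chaq_association_check(assoc_input, restricted_clades = restricted_chaq_clades)
  )

  report <- structure(
    list(
      segments = segments,
      per_segment = per_segment,
      clade_table = clades_long,
      diversity = diversity,
      diversity_tests = diversity_tests,
      coinfection = profile,
      concordance = concordance,
      discordance = discordance,
      chaq_association = chaq_assoc,
      dataset = dataset,
      parameters = list(
        clade_threshold = clade_threshold,
        distinct_threshold = distinct_threshold,
        collapse_epsilon = collapse_epsilon,
        discordance_high = discordance_high,
        discordance_low = discordance_low,
        n_permutations = n_permutations,
        seed = seed
      )
    ),
    class = "analysis_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @importFrom dplyr inner_join
NULL

# Relabel clades of every segment to the reference segment's labels by
# maximal shared-sample overlap (greedy), so per-sample clade labels are
# comparable across segments.
harmonize_clade_labels <- function(clades_long, reference) {
  ref <- filter(clades_long, .data$segment == reference)
  out <- list(ref)
  for (seg in setdiff(unique(clades_long$segment), reference)) {
    sub <- filter(clades_long, .data$segment == seg)
    overlap <- inner_join(
      select(sub, "sample_id", seg_clade = "clade"),
      select(ref, "sample_id", ref_clade = "clade"),
      by = "sample_id"
    ) |>
      count(.data$seg_clade, .data$ref_clade, sort = TRUE)
    mapping <- character()
    used <- character()
    for (k in seq_len(nrow(overlap))) {
      sc <- overlap$seg_clade[k]
      rc <- overlap$ref_clade[k]
      if (!sc %in% names(mapping) && !rc %in% used) {
        mapping[sc] <- rc
        used <- c(used, rc)
      }
    }
    unmapped <- setdiff(unique(sub$clade), names(mapping))
    if (length(unmapped) > 0) {
      mapping[unmapped] <- paste0(seg, ".", unmapped)
    }
    sub$clade <- unname(mapping[sub$clade])
    out[[length(out) + 1L]] <- sub
  }
  bind_rows(out)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Segmented-virus population structure report\n")
  cat("segments:", paste(x$segments, collapse = ", "), "\n\n")
  for (seg in x$segments) {
    g <- glance(x$per_segment[[seg]]$genotypes)
    s <- x$per_segment[[seg]]$snn
    cat(sprintf(
      "%-5s  clades: %d  median identity: %.1f%%  Snn = %.3f (p = %.3g)\n",
      seg, g$n_clades, x$diversity$median_identity[x$diversity$segment == seg],
      s$snn, s$p_value
    ))
  }
  gc <- glance(x$coinfection)
  cat(sprintf(
    "\ncoinfection: %d/%d samples (%.1f%%)\n",
    gc$n_coinfected, gc$n_samples, 100 * gc$coinfection_rate
  ))
  cc <- glance(x$concordance)
  cat(sprintf("between-clade discordant samples: %d of %d\n",
              cc$n_discordant, cc$n_samples))
  n_events <- sum(map_dbl(x$discordance, ~ nrow(attr(.x, "events"))))
  cat(sprintf("reassortment-consistent discordance events: %d\n", n_events))
  invisible(x)
}

# Serialize the report: JSON summary plus TSV tables.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    parameters = report$parameters,
    snn = lapply(report$per_segment, function(p) {
      list(snn = p$snn$snn, p_value = p$snn$p_value, n = p$snn$n,
           n_permutations = p$snn$n_permutations)
    }),
    diversity = report$diversity,
    diversity_tests = report$diversity_tests,
    coinfection = glance(report$coinfection),
    concordance = glance(report$concordance),
    n_discordance_events = sum(map_dbl(report$discordance, ~ nrow(attr(.x, "events")))),
    chaq_violations = nrow(report$chaq_association$violations)
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  readr::write_tsv(report$clade_table, file.path(out_dir, "genotypes.tsv"))
  readr::write_tsv(as_tibble(report$coinfection), file.path(out_dir, "coinfection.tsv"))
  readr::write_tsv(as_tibble(report$concordance), file.path(out_dir, "concordance.tsv"))
  events <- bind_rows(lapply(names(report$discordance), function(nm) {
    ev <- attr(report$discordance[[nm]], "events")
    if (nrow(ev) > 0) mutate(ev, segment_pair = nm) else NULL
  }))
  if (nrow(events) == 0) {
    events <- tibble(event_id = integer(), n_pairs = integer(), samples = character(),
                     segment_low = character(), clade_context = character(),
                     segment_pair = character())
  }
  readr::write_tsv(events, file.path(out_dir, "reassortment_events.tsv"))
  readr::write_tsv(report$chaq_association$contingency,
                   file.path(out_dir, "chaq_association.tsv"))
  invisible(out_dir)
}
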
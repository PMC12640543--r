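#' Detect segment discordance consistent with reassortment
#'
#' Operationalizes tanglegram discordance with an identity-gap rule: a
#' pair of singly infected samples is flagged when their sequences are
#' near-clonal on one segment (identity `>= high`) yet clearly divergent
#' on the other (identity `<= low`, below the genotype threshold). When
#' collapsed trees are supplied, the two divergent-segment sequences must
#' additionally sit apart in the tree (they must not share a parent node
#' after short branches have been collapsed into polytomies), which
#' suppresses flags driven by near-zero branches.
#'
#' Flagged pairs that share a sequence typically reflect one underlying
#' reassortment event; they are merged into events via connected
#' components (`event_id`).
#'
#' @param identity_x,identity_y Identity-mode matrices for the two
#'   segments.
#' @param sample_map Tibble with columns `sample_id`, `seq_id_x`,
#'   `seq_id_y`: exactly one sequence per segment per sample. Samples
#'   appearing more than once (coinfections) are excluded with a warning.
#' @param high Identity at or above which a pair is near-clonal
#'   (default 98.5, low enough to capture published worked examples of
#'   discordance at 98.7%).
#' @param low Identity at or below which a pair is divergent
#'   (default 95).
#' @param tree_x,tree_y Optional trees for the two segments, already
#'   collapsed with [collapse_short_branches()].
#' @param genotypes Optional tibble `seq_id, clade` covering both
#'   segments, used to label each pair `within-clade` or `between-clade`.
#' @param segment_x,segment_y Names used for the two segments in the
#'   output.
#' @return Tibble of flagged pairs (class `discordance_pairs`) with
#'   columns `sample_a`, `sample_b`, `segment_high`, `segment_low`,
#'   `identity_high`, `identity_low`, `clade_context`, `event_id`, and
#'   attribute `events` (one row per merged event). The thresholds used
#'   are recorded in attributes `high` and `low`.
#' @export
segment_discordance_pairs <- function(identity_x, identity_y, sample_map,
                                      high = 98.5, low = 95,
                                      tree_x = NULL, tree_y = NULL,
                                      genotypes = NULL,
                                      segment_x = "X", segment_y = "Y") {
  if (high <= low) abort("high threshold must exceed low threshold")
  dup <- unique(sample_map$sample_id[duplicated(sample_map$sample_id)])
  if (length(dup) > 0) {
    warn(paste0("excluding ", length(dup),
                " sample(s) with multiple sequences per segment (coinfection): ",
                paste(head(dup, 5), collapse = ", ")))
    sample_map <- filter(sample_map, !.data$sample_id %in% dup)
  }
  for (col in c("seq_id_x", "seq_id_y")) {
    mat <- if (col == "seq_id_x") identity_x else identity_y
    missing <- setdiff(sample_map[[col]], rownames(mat))
    if (length(missing) > 0) {
      abort(paste0("sequence ids absent from identity matrix: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  n <- nrow(sample_map)
  if (n < 2) {
    return(empty_discordance(high, low))
  }

  pairs <- as_tibble(t(combn(n, 2)), .name_repair = ~ c("i", "j"))
  ax <- sample_map$seq_id_x[pairs$i]; bx <- sample_map$seq_id_x[pairs$j]
  ay <- sample_map$seq_id_y[pairs$i]; by <- sample_map$seq_id_y[pairs$j]
  id_x <- identity_x[cbind(ax, bx)]
  id_y <- identity_y[cbind(ay, by)]

  x_high <- !is.na(id_x) & !is.na(id_y) & id_x >= high & id_y <= low
  y_high <- !is.na(id_x) & !is.na(id_y) & id_y >= high & id_x <= low

  # tree confirmation: divergent-segment sequences must not share a
  # parent node in the collapsed tree
  if (!is.null(tree_y)) {
    x_high <- x_high & !share_parent(tree_y, ay, by)
  }
  if (!is.null(tree_x)) {
    y_high <- y_high & !share_parent(tree_x, ax, bx)
  }

  keep <- which(x_high | y_high)
  if (length(keep) == 0) {
    return(empty_discordance(high, low))
  }
  xh <- x_high[keep]
  out <- tibble(
    sample_a = sample_map$sample_id[pairs$i[keep]],
    sample_b = sample_map$sample_id[pairs$j[keep]],
    segment_high = ifelse(xh, segment_x, segment_y),
    segment_low = ifelse(xh, segment_y, segment_x),
    identity_high = ifelse(xh, id_x[keep], id_y[keep]),
    identity_low = ifelse(xh, id_y[keep], id_x[keep]),
    seq_low_a = ifelse(xh, ay[keep], ax[keep]),
    seq_low_b = ifelse(xh, by[keep], bx[keep])
  )
  out$clade_context <- if (is.null(genotypes)) {
    NA_character_
  } else {
    ca <- genotypes$clade[match(out$seq_low_a, genotypes$seq_id)]
    cb <- genotypes$clade[match(out$seq_low_b, genotypes$seq_id)]
    ifelse(is.na(ca) | is.na(cb), NA_character_,
           ifelse(ca == cb, "within-clade", "between-clade"))
  }

  # merge pairs sharing a sample into events
  out$event_id <- connected_components(out$sample_a, out$sample_b)

  events <- out |>
    group_by(.data$event_id) |>
    summarise(
      n_pairs = n(),
      samples = paste(sort(unique(c(.data$sample_a, .data$sample_b))), collapse = ","),
      segment_low = paste(sort(unique(.data$segment_low)), collapse = ","),
      clade_context = paste(sort(unique(.data$clade_context)), collapse = ","),
      .groups = "drop"
    )
  out <- select(out, -"seq_low_a", -"seq_low_b")
  structure(
    out,
    events = events,
    high = high,
    low = low,
    class = c("discordance_pairs", class(out))
  )
}

empty_discordance <- function(high, low) {
  out <- tibble(
    sample_a = character(), sample_b = character(),
    segment_high = character(), segment_low = character(),
    identity_high = numeric(), identity_low = numeric(),
    clade_context = character(), event_id = integer()
  )
  structure(out,
    events = tibble(event_id = integer(), n_pairs = integer(),
                    samples = character(), segment_low = character(),
                    clade_context = character()),
    high = high, low = low,
    class = c("discordance_pairs", class(out))
  )
}

# TRUE where tips a[k] and b[k] share a parent node in the tree; tips not
# in the tree never share a parent (the check is then non-restrictive).
share_parent <- function(tree, a, b) {
  parent_of <- function(tips) {
    idx <- match(tips, tree$tip.label)
    out <- rep(NA_integer_, length(tips))
    has <- !is.na(idx)
    out[has] <- tree$edge[match(idx[has], tree$edge[, 2]), 1]
    out
  }
  pa <- parent_of(a)
  pb <- parent_of(b)
  !is.na(pa) & !is.na(pb) & pa == pb
}

# Union-find connected components over sample pairs.
connected_components <- function(a, b) {
  nodes <- unique(c(a, b))
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  for (k in seq_along(a)) {
    ra <- find(match(a[k], nodes))
    rb <- find(match(b[k], nodes))
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  comp <- match(roots, unique(roots))
  comp_a <- comp[match(a, nodes)]
  comp_a
}

#' Per-sample clade concordance across segments
#'
#' Lists every singly infected sample with its major-clade label on each
#' segment; samples whose segments carry different major clades are the
#' candidate between-clade reassortants. Zero discordant samples is the
#' expected result when reassortment is confined within clades.
#'
#' @param clades Long tibble with `sample_id`, `segment`, `clade`
#'   (one row per sample-segment; singly infected samples only).
#' @return Wide tibble, one row per sample, one column per segment,
#'   plus `discordant` (class `clade_concordance`). Attribute
#'   `discordant_samples` holds the offending sample ids.
#' @export
clade_concordance_table <- function(clades) {
  wide <- clades |>
    select("sample_id", "segment", "clade") |>
    tidyr::pivot_wider(names_from = "segment", values_from = "clade")
  seg_cols <- setdiff(names(wide), "sample_id")
  # concordance is judged on the genome segments; the satellite column
  # is carried for display but its sparser sampling must not create
  # spurious discordance
  galbut_cols <- intersect(seg_cols, GALBUT_SEGMENTS)
  if (length(galbut_cols) > 0) seg_cols <- galbut_cols
  wide$discordant <- apply(wide[seg_cols], 1, function(r) {
    r <- r[!is.na(r)]
    length(unique(r)) > 1
  })
  structure(
    wide,
    discordant_samples = wide$sample_id[wide$discordant],
    class = c("clade_concordance", class(wide))
  )
}

#' @export
glance.clade_concordance <- function(x, ...) {
  tibble(
    n_samples = nrow(x),
    n_discordant = sum(x$discordant)
  )
}
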
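#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the statistical structure of a wild segmented-virus
#' survey: three major clades (two from *D. melanogaster*-like hosts,
#' one from a *D. simulans*-like host) with between-clade identity near
#' 80%; each clade is a chain of tight subclades (within-subclade
#' identity ~99%, adjacent subclades ~96.5%), so major clades cohere
#' under single-linkage clustering at the 95% genotype threshold while
#' distant subclades within a clade (~93%) supply the divergent lineage
#' pairs among which reassortment is resolvable; a chaq-like satellite
#' restricted to two of the clades; ~11% coinfection biased toward
#' RNA 3; within-clade-only reassortment; geographic label clustering;
#' and bimodal relative RNA levels with modes at 4.1 and 1/3907 copies
#' per reference mRNA.
#'
#' @param n_samples Number of host individuals (default 118).
#' @param clades Tibble with `clade`, `proportion`, `chaq_allowed`.
#' @param n_subclades Subclades per major clade (default 3; clades with
#'   fewer samples use fewer).
#' @param within_subclade_identity Expected percent identity within a
#'   subclade (default 99).
#' @param subclade_adjacent_identity Expected identity between tips of
#'   adjacent subclades on the chain (default 96.5; must exceed the
#'   genotype threshold for clades to cohere).
#' @param between_clade_identity Expected identity between major clades
#'   (default 80; must be lower than the within-clade identities).
#' @param segment_lengths Named lengths (nt) for RNA1, RNA2, RNA3, chaq.
#' @param kappa Transition/transversion rate ratio of the simulation
#'   substitution process (default 4).
#' @param n_locations,geographic_mixing Number of location labels and
#'   the per-sample probability of a random (rather than
#'   lineage-determined) location; 0 gives perfect structure (Snn = 1).
#'   With mixing fraction `f` and `L` locations the expected Snn is
#'   approximately `(1-f)(1-f+f/L)`; the default 0.06 with 5 locations
#'   places the emitted data in the 0.85-0.91 band typical of strongly
#'   but incompletely structured wild populations.
#' @param reassortment_rate Per-sample probability of one within-clade
#'   reassortment event (default 0.05).
#' @param allow_between_clade Permit between-clade reassortment
#'   (default `FALSE`; the generator refuses between-clade events
#'   without this override).
#' @param coinfection_fraction Fraction of coinfected samples
#'   (default 0.11).
#' @param coinfection_segment_weights Named sampling weights for which
#'   segment carries the extra genotype (RNA3-biased by default).
#' @param complete_coinfection_prob Probability a coinfection carries a
#'   full extra set of all three genome segments (default 0.15).
#' @param p_chaq Probability a sample in a chaq-allowed clade carries
#'   the satellite (default 0.6).
#' @param abundance_mode1,abundance_mode2,abundance_mode1_weight,abundance_log10_sd
#'   Two-mode log-normal mixture for relative RNA levels (copies per
#'   reference mRNA): modes 4.1 and 1/3907, high-mode weight 0.7,
#'   log10 standard deviation 0.5.
#' @param clade_level_factor Named multiplicative factors on
#'   sequencing-based abundance per clade (melB-like clades replicate
#'   lower; default melB = 1/4.9).
#' @param rpm_per_level Reads per million host reads per unit relative
#'   level (default 1000).
#' @param strand_ratio_by_segment Named plus/minus strand read ratios
#'   (RNA1 lowest).
#' @param detect_low Identity ceiling used when picking reassortment
#'   donor lineages so planted events are resolvable (default 95).
#' @param seed Integer seed (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    n_samples = 118,
    clades = tibble(
      clade = c("melA", "melB", "simA"),
      proportion = c(0.5, 0.3, 0.2),
      chaq_allowed = c(TRUE, FALSE, TRUE)
    ),
    n_subclades = 3,
    within_subclade_identity = 99,
    subclade_adjacent_identity = 96.5,
    between_clade_identity = 80,
    segment_lengths = c(RNA1 = 1600, RNA2 = 1500, RNA3 = 1300, chaq = 1400),
    kappa = 4,
    n_locations = 5,
    geographic_mixing = 0.06,
    reassortment_rate = 0.05,
    allow_between_clade = FALSE,
    coinfection_fraction = 0.11,
    coinfection_segment_weights = c(RNA1 = 0.1, RNA2 = 0.2, RNA3 = 0.5, chaq = 0.2),
    complete_coinfection_prob = 0.15,
    p_chaq = 0.6,
    abundance_mode1 = 4.1,
    abundance_mode2 = 1 / 3907,
    abundance_mode1_weight = 0.7,
    abundance_log10_sd = 0.5,
    clade_level_factor = c(melA = 1, melB = 1 / 4.9, simA = 1),
    rpm_per_level = 1000,
    strand_ratio_by_segment = c(RNA1 = 5, RNA2 = 20, RNA3 = 20, chaq = 20),
    detect_low = 95,
    seed = 1) {
  if (abs(sum(clades$proportion) - 1) > 1e-8) abort("clade proportions must sum to 1")
  if (subclade_adjacent_identity >= within_subclade_identity) {
    abort("infeasible divergence settings: adjacent-subclade identity must be below within-subclade identity")
  }
  if (between_clade_identity >= subclade_adjacent_identity) {
    abort("infeasible divergence settings: between-clade identity must be below within-clade identities")
  }
  if (geographic_mixing < 0 || geographic_mixing > 1) abort("geographic_mixing must be in [0, 1]")
  if (!all(segment_levels() %in% names(segment_lengths))) {
    abort("segment_lengths must name RNA1, RNA2, RNA3 and chaq")
  }
  structure(as.list(environment()), class = "sim_config")
}

# ---- substitution-model calibration -----------------------------------

# Expected mismatch proportion between two sequences separated by path
# length d (substitutions/site) under the two-rate (K80-type) process.
k80_expected_mismatch <- function(d, kappa) {
  b <- 1 / (kappa + 2)
  a <- kappa * b
  0.75 - 0.25 * exp(-4 * b * d) - 0.5 * exp(-2 * (a + b) * d)
}

# Invert the mismatch curve: path length that yields a target percent
# identity in expectation.
identity_to_divergence <- function(identity_pct, kappa) {
  m <- 1 - identity_pct / 100
  if (m <= 0) {
    return(0)
  }
  if (m >= 0.75) abort("target identity at or below the saturation floor (75%)")
  stats::uniroot(
    function(d) k80_expected_mismatch(d, kappa) - m,
    lower = 0, upper = 50, tol = 1e-12
  )$root
}

# Evolve an encoded sequence along one branch of length d.
mutate_k80 <- function(seq, d, kappa) {
  if (d <= 0) {
    return(seq)
  }
  b <- 1 / (kappa + 2)
  a <- kappa * b
  e4 <- exp(-4 * b * d)
  e2 <- exp(-2 * (a + b) * d)
  p_same <- 0.25 + 0.25 * e4 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e4 - 0.5 * e2
  p_tv <- (1 - e4) / 4
  u <- runif(length(seq))
  ts_map <- c(3L, 4L, 1L, 2L)
  tv1_map <- c(2L, 1L, 2L, 1L)
  tv2_map <- c(4L, 3L, 4L, 3L)
  out <- seq
  i <- u > p_same & u <= p_same + p_ts
  out[i] <- ts_map[seq[i]]
  i <- u > p_same + p_ts & u <= p_same + p_ts + p_tv
  out[i] <- tv1_map[seq[i]]
  i <- u > p_same + p_ts + p_tv
  out[i] <- tv2_map[seq[i]]
  out
}

# ---- clade phylogeny ---------------------------------------------------

#' Simulate the clade-structured sample phylogeny
#'
#' Each major clade is built as a chain of subclades: every subclade is
#' a coalescent tree rescaled so its mean pairwise tip distance matches
#' the within-subclade divergence, and subclades hang off a linear
#' backbone whose steps place adjacent subclades at the configured
#' adjacent-subclade divergence (distant subclades on the chain
#' accumulate proportionally more). The clades are then joined on a
#' star backbone realising the between-clade divergence. This chained
#' structure is what lets single-linkage identity clustering recover
#' one cluster per clade even though the most divergent within-clade
#' pairs fall below the genotype threshold.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return List with `tree` (tips = sample ids), `sample_table`
#'   (tibble `sample_id`, `clade`, `subclade`, `chaq_allowed`) and the
#'   calibrated divergences `d_sub`, `d_adjacent`, `d_between`.
#' @export
simulate_clade_phylogeny <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_samples
  k <- nrow(config$clades)
  n_tips <- floor(config$clades$proportion * n)
  rem <- n - sum(n_tips)
  if (rem > 0) {
    extra <- order(config$clades$proportion * n - n_tips, decreasing = TRUE)[seq_len(rem)]
    n_tips[extra] <- n_tips[extra] + 1L
  }
  if (any(n_tips < 2)) {
    abort("each clade needs at least 2 samples; increase n_samples or proportions")
  }
  sample_ids <- sprintf("S%03d", seq_len(n))
  clade_of <- rep(config$clades$clade, n_tips)
  subclade_of <- character(n)

  d_sub <- identity_to_divergence(config$within_subclade_identity, config$kappa)
  d_adj <- identity_to_divergence(config$subclade_adjacent_identity, config$kappa)
  d_between <- identity_to_divergence(config$between_clade_identity, config$kappa)

  # one ultrametric coalescent subtree per subclade, mean pairwise
  # distance d_sub; returns the newick (no trailing ';') and its height
  make_subclade <- function(tips) {
    if (length(tips) == 1L) {
      return(list(newick = paste0(tips, ":0"), height = 0))
    }
    tr <- ape::rcoal(length(tips), tip.label = tips)
    coph <- cophenetic(tr)
    tr$edge.length <- tr$edge.length * d_sub / mean(coph[upper.tri(coph)])
    list(
      newick = sub(";$", "", ape::write.tree(tr)),
      height = max(ape::node.depth.edgelength(tr))
    )
  }

  offsets <- c(0L, cumsum(n_tips))
  clade_newicks <- character(k)
  clade_mean_depth <- numeric(k)
  for (i in seq_len(k)) {
    tips <- sample_ids[(offsets[i] + 1L):offsets[i + 1L]]
    m <- min(config$n_subclades, length(tips))
    groups <- split(tips, rep(seq_len(m), length.out = length(tips)) |> sort())
    subclade_of[match(unlist(groups), sample_ids)] <-
      rep(paste0(config$clades$clade[i], ".", seq_len(m)), lengths(groups))
    subs <- lapply(groups, make_subclade)
    # chain from the last subclade backwards; backbone step c_j places
    # adjacent subclade tips at distance d_adj
    cur <- subs[[m]]$newick
    depths <- subs[[m]]$height
    for (j in rev(seq_len(m - 1L))) {
      c_j <- max(d_adj - subs[[j]]$height - subs[[j + 1L]]$height, d_adj / 10)
      cur <- paste0("(", subs[[j]]$newick, ":0,", cur, ":",
                    format(c_j, digits = 12), ")")
      depths <- c(subs[[j]]$height, depths + c_j)
    }
    clade_newicks[i] <- cur
    clade_mean_depth[i] <- sum(depths * lengths(groups)) / length(tips)
  }
  stems <- d_between / 2 - clade_mean_depth
  if (any(stems <= 0)) {
    abort("infeasible divergence settings: within-clade depth exceeds half the between-clade divergence")
  }
  full <- paste0(
    "(",
    paste(paste0(clade_newicks, ":", format(stems, digits = 12)), collapse = ","),
    ");"
  )
  tree <- read_newick(text = full)
  sample_table <- tibble(
    sample_id = sample_ids,
    clade = clade_of,
    subclade = subclade_of,
    chaq_allowed = config$clades$chaq_allowed[match(clade_of, config$clades$clade)]
  )
  list(tree = tree, sample_table = sample_table,
       d_sub = d_sub, d_adjacent = d_adj, d_between = d_between)
}

#' Evolve per-segment sequences along the sample phylogeny
#'
#' All segments evolve independently on the *same* tree (segment
#' concordance is the null state; reassortment is planted afterwards)
#' under the two-rate transition/transversion process, producing gapless
#' alignments.
#'
#' @param phylo Result of [simulate_clade_phylogeny()].
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed + 1`).
#' @return Long tibble `seq_id, sample_id, segment, residues` with one
#'   sequence per sample per segment (chaq included for every sample;
#'   presence is decided later).
#' @export
evolve_sequences <- function(phylo, config, seed = config$seed + 1) {
  set.seed(seed)
  tree <- ape::reorder.phylo(phylo$tree, "cladewise")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  out <- vector("list", length(segment_levels()))
  names(out) <- segment_levels()
  for (seg in segment_levels()) {
    len <- config$segment_lengths[[seg]]
    if (len <= 0) abort("segment lengths must be positive")
    nodes <- vector("list", n_tip + tree$Nnode)
    nodes[[root]] <- sample.int(4L, len, replace = TRUE)
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]
      ch <- tree$edge[e, 2]
      nodes[[ch]] <- mutate_k80(nodes[[p]], tree$edge.length[e], config$kappa)
    }
    bases <- c("A", "C", "G", "T")
    out[[seg]] <- tibble(
      seq_id = paste(tree$tip.label, seg, "1", sep = "_"),
      sample_id = tree$tip.label,
      segment = seg,
      residues = vapply(
        seq_len(n_tip),
        function(i) paste(bases[nodes[[i]]], collapse = ""),
        character(1)
      )
    )
  }
  bind_rows(out)
}

# ---- reassortment and coinfection -------------------------------------

#' Plant reassortment events and coinfections
#'
#' Reassortment: a recipient sample's chosen segment is replaced by an
#' exact copy of a divergent donor lineage's segment from the *same*
#' clade (between-clade donors require `allow_between_clade = TRUE`,
#' guarding the expected negative result). Donors are chosen so the
#' unswapped genome segments stay at or below `detect_low` percent
#' identity, making every planted event resolvable in principle.
#' Coinfection: selected samples receive an extra genotype (a different
#' clade's sequence) on segments drawn by the configured RNA3-biased
#' weights, or a complete extra segment set. Satellite (chaq) presence
#' is assigned per sample, restricted to chaq-allowed clades.
#'
#' @param sequences Output of [evolve_sequences()].
#' @param phylo Output of [simulate_clade_phylogeny()].
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed + 2`).
#' @param n_reassortment_events Override the binomial draw with an exact
#'   event count.
#' @return List with `sequences` (long tibble including extra
#'   coinfection genotypes and with chaq restricted to carriers) and
#'   `truth` (list: `sample_table` with `has_chaq`/`coinfected`,
#'   `reassortment_events`, `coinfections`).
#' @export
apply_reassortment_and_coinfection <- function(sequences, phylo, config,
                                               seed = config$seed + 2,
                                               n_reassortment_events = NULL) {
  set.seed(seed)
  st <- phylo$sample_table
  n <- nrow(st)

  st$has_chaq <- st$chaq_allowed & runif(n) < config$p_chaq

  # coinfected samples (chosen first; reassortment recipients must be
  # singly infected, as only those enter discordance screens)
  n_coinf <- round(config$coinfection_fraction * n)
  coinf_samples <- if (n_coinf > 0) sample(st$sample_id, n_coinf) else character()
  st$coinfected <- st$sample_id %in% coinf_samples

  # planted reassortment events: recipient and donor are chosen jointly
  # so the donor lineage is divergent (identity <= detect_low) from the
  # recipient on every unswapped genome segment, making the event
  # resolvable by the identity-gap rule. Pre-swap identities are cached
  # per clade and segment; prior recipients are excluded from both roles
  # so cached identities stay valid.
  n_events <- n_reassortment_events %||% rbinom(1, n, config$reassortment_rate)
  events <- list()
  seqs <- sequences
  get_seq <- function(sample, seg) {
    seqs$residues[seqs$sample_id == sample & seqs$segment == seg & endsWith(seqs$seq_id, "_1")]
  }
  if (n_events > 0) {
    if (config$allow_between_clade && nrow(config$clades) < 2) {
      abort("between-clade reassortment needs at least 2 clades")
    }
    ident_cache <- list()
    clade_ident <- function(clade, seg) {
      key <- paste(clade, seg)
      if (is.null(ident_cache[[key]])) {
        ids <- st$sample_id[st$clade == clade & !st$coinfected]
        sub <- filter(sequences, .data$segment == seg, .data$sample_id %in% ids,
                      endsWith(.data$seq_id, "_1"))
        m <- unclass(distance_matrix(
          mutate(sub, seq_id = .data$sample_id), mode = "identity"
        ))
        ident_cache[[key]] <<- m
      }
      ident_cache[[key]]
    }
    used <- character() # prior recipients: out of both roles
    for (ev in seq_len(n_events)) {
      planted <- FALSE
      for (seg in sample(segment_levels())) {
        ref_segs <- setdiff(GALBUT_SEGMENTS, seg)
        for (clade in sample(config$clades$clade)) {
          pool <- st$sample_id[st$clade == clade & !st$coinfected]
          pool <- setdiff(pool, used)
          if (seg == "chaq") pool <- intersect(pool, st$sample_id[st$has_chaq])
          if (length(pool) < 2) next
          # max identity over unswapped segments for every sample pair
          mm <- clade_ident(clade, ref_segs[1])[pool, pool, drop = FALSE]
          for (s2 in ref_segs[-1]) {
            mm <- pmax(mm, clade_ident(clade, s2)[pool, pool, drop = FALSE])
          }
          donor_clade <- clade
          if (config$allow_between_clade) {
            # between-clade override: donor from a different clade
            dpool <- st$sample_id[st$clade != clade & !st$coinfected]
            dpool <- setdiff(dpool, used)
            if (seg == "chaq") dpool <- intersect(dpool, st$sample_id[st$has_chaq])
            if (length(dpool) == 0) next
            r <- sample(pool, 1)
            donor <- if (length(dpool) == 1) dpool else sample(dpool, 1)
            donor_clade <- st$clade[st$sample_id == donor]
            max_unswapped <- max(vapply(ref_segs, function(s) {
              pairwise_identity(get_seq(r, s), get_seq(donor, s))
            }, numeric(1)))
          } else {
            diag(mm) <- 100
            ok <- which(mm <= config$detect_low, arr.ind = TRUE)
            if (nrow(ok) == 0) next
            pick <- ok[sample(nrow(ok), 1), ]
            r <- pool[pick[1]]
            donor <- pool[pick[2]]
            max_unswapped <- mm[pick[1], pick[2]]
          }
          row <- seqs$sample_id == r & seqs$segment == seg & endsWith(seqs$seq_id, "_1")
          if (!any(row)) next # e.g. chaq row already absent
          seqs$residues[row] <- get_seq(donor, seg)
          used <- c(used, r)
          events[[length(events) + 1L]] <- tibble(
            sample_id = r, segment = seg, donor = donor,
            donor_clade = donor_clade,
            max_unswapped_identity = max_unswapped,
            resolvable = max_unswapped <= config$detect_low
          )
          planted <- TRUE
          break
        }
        if (planted) break
      }
      if (!planted) {
        warn("could not plant a resolvable reassortment event; fewer events than requested")
      }
    }
  }
  events <- if (length(events)) bind_rows(events) else
    tibble(sample_id = character(), segment = character(), donor = character(),
           donor_clade = character(), max_unswapped_identity = numeric(),
           resolvable = logical())

  # coinfections: extra genotypes copied from a donor in another clade
  coinfs <- list()
  w <- config$coinfection_segment_weights[segment_levels()]
  for (s in coinf_samples) {
    s_clade <- st$clade[st$sample_id == s]
    other <- st$sample_id[st$clade != s_clade]
    if (length(other) == 0) next
    donor <- if (length(other) == 1) other else sample(other, 1)
    donor_clade <- st$clade[st$sample_id == donor]
    if (runif(1) < config$complete_coinfection_prob) {
      extra_segs <- GALBUT_SEGMENTS
    } else {
      ww <- w
      donor_chaq_ok <- config$clades$chaq_allowed[config$clades$clade == donor_clade]
      # an extra chaq genotype is only observable (and only biologically
      # sensible as a *co*infection) when the sample itself carries chaq
      if (!donor_chaq_ok || !st$has_chaq[st$sample_id == s]) ww[["chaq"]] <- 0
      if (sum(ww) == 0) ww <- w * c(1, 1, 1, 0)[match(names(w), segment_levels())]
      extra_segs <- sample(names(ww), 1, prob = ww)
    }
    for (seg in extra_segs) {
      extra <- tibble(
        seq_id = paste(s, seg, "2", sep = "_"),
        sample_id = s,
        segment = seg,
        residues = get_seq(donor, seg)
      )
      seqs <- bind_rows(seqs, extra)
    }
    coinfs[[length(coinfs) + 1L]] <- tibble(
      sample_id = s, donor = donor, donor_clade = donor_clade,
      segments = paste(extra_segs, collapse = ",")
    )
  }
  coinfs <- if (length(coinfs)) bind_rows(coinfs) else
    tibble(sample_id = character(), donor = character(),
           donor_clade = character(), segments = character())

  # drop chaq for non-carriers (the satellite is optional)
  drop <- seqs$segment == "chaq" &
    !st$has_chaq[match(seqs$sample_id, st$sample_id)] &
    endsWith(seqs$seq_id, "_1")
  seqs <- seqs[!drop, , drop = FALSE]
  seqs <- arrange(seqs, .data$segment, .data$seq_id)

  list(
    sequences = seqs,
    truth = list(
      sample_table = st,
      reassortment_events = events,
      coinfections = coinfs
    )
  )
}

# ---- geography and abundance ------------------------------------------

#' Assign geographic labels and abundance measurements
#'
#' Locations are assigned by lineage: connected components of the
#' nearest-neighbour graph (union over the four segments' realised TN93
#' nearest-neighbour sets, primary sequences only) are distributed over
#' `n_locations` labels, so with `geographic_mixing = 0` every
#' sequence's nearest neighbours share its label and Snn is exactly 1.
#' With probability `geographic_mixing`, a sample's label is drawn
#' uniformly at random instead. Relative RNA levels come from the
#' two-mode log-normal mixture; Ct values are back-computed from the
#' levels; strand-specific read counts follow the per-segment
#' plus/minus ratios, with clade-specific abundance factors applied to
#' the sequencing counts.
#'
#' @param dataset Result of [apply_reassortment_and_coinfection()].
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed + 3`).
#' @return The dataset list extended with `metadata` (per sequence),
#'   `qpcr` (per sample), `read_counts` (per sample, segment, strand)
#'   and the location assignment recorded in `truth`.
#' @export
assign_geography_and_abundance <- function(dataset, config, seed = config$seed + 3) {
  if (config$n_locations < 2) abort("need at least 2 locations")
  set.seed(seed)
  st <- dataset$truth$sample_table
  n <- nrow(st)
  seqs <- dataset$sequences

  # nearest-neighbour components over all segments' realised distances
  primary <- filter(seqs, endsWith(.data$seq_id, "_1"))
  edges_a <- character()
  edges_b <- character()
  for (seg in segment_levels()) {
    sub <- filter(primary, .data$segment == seg)
    if (nrow(sub) < 2) next
    m <- distance_matrix(sub, mode = "tn93")
    mm <- unclass(m)
    diag(mm) <- NA
    for (i in seq_len(nrow(mm))) {
      nn <- which(mm[i, ] == min(mm[i, ], na.rm = TRUE))
      edges_a <- c(edges_a, rep(sub$sample_id[i], length(nn)))
      edges_b <- c(edges_b, sub$sample_id[nn])
    }
  }
  comp <- connected_components(c(edges_a, st$sample_id), c(edges_b, st$sample_id))
  comp <- comp[match(st$sample_id, c(edges_a, st$sample_id))]

  # distribute components over locations, largest first onto the
  # currently smallest location
  loc_names <- c("CO", "ME", "PA", "OH", "CA", "NY", "TX", "WA", "AU", "CN")
  loc_names <- if (config$n_locations <= length(loc_names)) {
    loc_names[seq_len(config$n_locations)]
  } else {
    paste0("L", seq_len(config$n_locations))
  }
  comp_sizes <- sort(table(comp), decreasing = TRUE)
  loc_fill <- setNames(rep(0L, length(loc_names)), loc_names)
  comp_loc <- character(length(comp_sizes))
  names(comp_loc) <- names(comp_sizes)
  for (cmp in names(comp_sizes)) {
    target <- names(loc_fill)[which.min(loc_fill)]
    comp_loc[cmp] <- target
    loc_fill[target] <- loc_fill[target] + comp_sizes[[cmp]]
  }
  st$location <- unname(comp_loc[as.character(comp)])
  mix <- runif(n) < config$geographic_mixing
  st$location[mix] <- sample(loc_names, sum(mix), replace = TRUE)

  # abundance: bimodal relative levels, clade factor on sequencing counts
  high_mode <- runif(n) < config$abundance_mode1_weight
  mode <- ifelse(high_mode, config$abundance_mode1, config$abundance_mode2)
  level <- 10^rnorm(n, log10(mode), config$abundance_log10_sd)
  ct_reference <- rnorm(n, 20, 1)
  ct_target <- ct_reference - log2(level)
  qpcr <- tibble(
    sample_id = st$sample_id,
    ct_target = round(ct_target, 2),
    ct_reference = round(ct_reference, 2),
    detected = TRUE
  )

  clade_factor <- config$clade_level_factor[st$clade]
  clade_factor[is.na(clade_factor)] <- 1
  host_reads <- round(10^rnorm(n, 6.3, 0.2))
  rpm <- level * unname(clade_factor) * config$rpm_per_level
  seg_presence <- distinct(seqs, .data$sample_id, .data$segment)
  ratios <- config$strand_ratio_by_segment
  read_counts <- seg_presence |>
    mutate(
      host_reads = host_reads[match(.data$sample_id, st$sample_id)],
      virus_reads = pmax(
        10L,
        round(rpm[match(.data$sample_id, st$sample_id)] *
                .data$host_reads / 1e6 * runif(n(), 0.8, 1.25))
      ),
      ratio = ratios[.data$segment]
    ) |>
    mutate(
      minus_reads = pmax(1L, round(.data$virus_reads / (1 + .data$ratio))),
      plus_reads = .data$virus_reads - .data$minus_reads
    ) |>
    tidyr::pivot_longer(c("plus_reads", "minus_reads"),
                        names_to = "strand", values_to = "strand_reads") |>
    mutate(strand = ifelse(.data$strand == "plus_reads", "plus", "minus")) |>
    select("sample_id", "segment", "strand", "strand_reads",
           "virus_reads", "host_reads")

  dates <- seq(as.Date("2023-06-15"), as.Date("2023-09-30"), by = "day")
  st$collection_date <- sample(dates, n, replace = TRUE)
  st$species <- ifelse(startsWith(st$clade, "sim"), "D. simulans", "D. melanogaster")

  metadata <- seqs |>
    select("seq_id", "sample_id", "segment") |>
    left_join(
      select(st, "sample_id", "location", "collection_date", "species"),
      by = "sample_id"
    )

  dataset$truth$sample_table <- st
  dataset$metadata <- metadata
  dataset$qpcr <- qpcr
  dataset$read_counts <- read_counts
  dataset
}

#' Run the full synthetic generator
#'
#' Convenience wrapper chaining [simulate_clade_phylogeny()],
#' [evolve_sequences()], [apply_reassortment_and_coinfection()] and
#' [assign_geography_and_abundance()], each on a sub-seed derived from
#' `config$seed`, so the whole dataset is a deterministic function of
#' the configuration.
#'
#' @param config A [sim_config()].
#' @param n_reassortment_events Optional exact event count.
#' @return List: `sequences`, `metadata`, `qpcr`, `read_counts`,
#'   `truth`, `phylo`.
#' @export
simulate_dataset <- function(config = sim_config(), n_reassortment_events = NULL) {
  phylo <- simulate_clade_phylogeny(config)
  seqs <- evolve_sequences(phylo, config)
  dataset <- apply_reassortment_and_coinfection(
    seqs, phylo, config,
    n_reassortment_events = n_reassortment_events
  )
  dataset <- assign_geography_and_abundance(dataset, config)
  dataset$phylo <- phylo
  dataset
}

#' Write a synthetic dataset to disk
#'
#' Emits one FASTA per segment, a metadata TSV, qPCR and read-count
#' TSVs, and a ground-truth JSON whose sequence ids match the FASTA.
#' Re-reading with [read_aligned_fasta()] / [read_metadata()] reproduces
#' the in-memory tables.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
emit_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (seg in segment_levels()) {
    sub <- filter(dataset$sequences, .data$segment == seg)
    path <- file.path(out_dir, paste0(seg, ".fasta"))
    write_fasta(sub, path)
    files[paste0("fasta_", seg)] <- path
  }
  md_path <- file.path(out_dir, "metadata.tsv")
  readr::write_tsv(dataset$metadata, md_path)
  files["metadata"] <- md_path
  qpcr_path <- file.path(out_dir, "qpcr.tsv")
  readr::write_tsv(dataset$qpcr, qpcr_path)
  files["qpcr"] <- qpcr_path
  rc_path <- file.path(out_dir, "read_counts.tsv")
  readr::write_tsv(dataset$read_counts, rc_path)
  files["read_counts"] <- rc_path
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(
    list(
      sample_table = dataset$truth$sample_table,
      reassortment_events = dataset$truth$reassortment_events,
      coinfections = dataset$truth$coinfections,
      seq_ids = dataset$sequences$seq_id
    ),
    truth_path,
    dataframe = "rows"
  )
  files["truth"] <- truth_path
  invisible(files)
}
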
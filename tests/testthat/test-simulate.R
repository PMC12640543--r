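test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 5)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$metadata, d2$metadata)
  expect_identical(d1$qpcr, d2$qpcr)
  expect_identical(d1$truth$reassortment_events, d2$truth$reassortment_events)
  d3 <- simulate_dataset(small_sim_config(seed = 6))
  expect_false(identical(d1$sequences$residues, d3$sequences$residues))
})

test_that("infeasible divergence settings are rejected", {
  expect_error(sim_config(between_clade_identity = 99),
               "infeasible divergence")
  expect_error(sim_config(subclade_adjacent_identity = 99.5),
               "infeasible divergence")
  expect_error(sim_config(clades = tibble::tibble(
    clade = c("a", "b"), proportion = c(0.7, 0.4), chaq_allowed = TRUE
  )), "sum to 1")
})

test_that("clade phylogeny realises the configured divergence scales", {
  cfg <- small_sim_config(seed = 7, n_samples = 45)
  ph <- simulate_clade_phylogeny(cfg)
  expect_equal(length(ph$tree$tip.label), 45)
  st <- ph$sample_table
  coph <- cophenetic(ph$tree)
  within_sub <- c(); between_clade <- c()
  for (i in 1:44) {
    for (j in (i + 1):45) {
      d <- coph[st$sample_id[i], st$sample_id[j]]
      if (st$subclade[i] == st$subclade[j]) within_sub <- c(within_sub, d)
      if (st$clade[i] != st$clade[j]) between_clade <- c(between_clade, d)
    }
  }
  expect_equal(mean(within_sub), ph$d_sub, tolerance = 0.15)
  expect_equal(mean(between_clade), ph$d_between, tolerance = 0.1)
})

test_that("doubling the backbone depth lowers between-clade identity", {
  base <- small_sim_config(seed = 8, n_samples = 30)
  deep <- small_sim_config(seed = 8, n_samples = 30, between_clade_identity = 72)
  mean_between <- function(cfg) {
    ds <- simulate_dataset(cfg)
    st <- ds$truth$sample_table
    m <- sample_identity_matrix(ds, "RNA1")
    cl <- setNames(st$clade, st$sample_id)
    ids <- rownames(m)
    cross <- outer(cl[ids], cl[ids], "!=") & upper.tri(m)
    mean(m[cross])
  }
  expect_gt(mean_between(base), mean_between(deep))
})

test_that("evolved identities land near their configured targets", {
  # averaged over replicates, realised within-subclade identity sits
  # within two points of the configured expectation
  meds <- vapply(1:3, function(s) {
    ds <- simulate_dataset(small_sim_config(seed = 300 + s, n_samples = 24,
                                            coinfection_fraction = 0))
    st <- ds$truth$sample_table
    m <- sample_identity_matrix(ds, "RNA1")
    ids <- rownames(m)
    sc <- setNames(st$subclade, st$sample_id)
    same <- outer(sc[ids], sc[ids], "==") & upper.tri(m)
    median(m[same])
  }, numeric(1))
  expect_equal(mean(meds), 99, tolerance = 0.02)
})

test_that("zero branch lengths yield identical sequences", {
  cfg <- small_sim_config(seed = 9, n_samples = 10)
  ph <- simulate_clade_phylogeny(cfg)
  ph$tree$edge.length[] <- 0
  seqs <- evolve_sequences(ph, cfg)
  for (seg in segment_levels()) {
    sub <- dplyr::filter(seqs, segment == seg)
    expect_equal(length(unique(sub$residues)), 1)
  }
})

test_that("the transition bias shows up in the estimated TN93 rate classes", {
  ds <- simulate_dataset(small_sim_config(seed = 10, n_samples = 20,
                                          coinfection_fraction = 0))
  sub <- dplyr::filter(ds$sequences, segment == "RNA1")
  set.seed(1)
  idx <- t(utils::combn(nrow(sub), 2))
  idx <- idx[sample(nrow(idx), 30), ]
  ratios <- apply(idx, 1, function(k) {
    p <- attr(tn93_distance(sub$residues[k[1]], sub$residues[k[2]]), "params")
    if (p$Q == 0) NA else (p$P1 + p$P2) / p$Q
  })
  # kappa = 4 with equal frequencies: transitions should clearly
  # outnumber transversions on average
  expect_gt(mean(ratios, na.rm = TRUE), 1)
})

test_that("reassortment truth is empty at rate zero and within-clade by default", {
  ds <- simulate_dataset(small_sim_config(seed = 11, reassortment_rate = 0))
  expect_equal(nrow(ds$truth$reassortment_events), 0)
  ds2 <- simulate_dataset(small_sim_config(seed = 12, n_samples = 40),
                          n_reassortment_events = 4)
  ev <- ds2$truth$reassortment_events
  st <- ds2$truth$sample_table
  expect_equal(nrow(ev), 4)
  expect_equal(ev$donor_clade,
               st$clade[match(ev$sample_id, st$sample_id)])
  # between-clade donors only under the explicit override
  ds3 <- simulate_dataset(small_sim_config(seed = 12, n_samples = 40,
                                           allow_between_clade = TRUE),
                          n_reassortment_events = 2)
  ev3 <- ds3$truth$reassortment_events
  st3 <- ds3$truth$sample_table
  expect_true(all(ev3$donor_clade != st3$clade[match(ev3$sample_id, st3$sample_id)]))
})

test_that("the coinfection fraction is recovered within binomial error", {
  ds <- simulate_dataset(sim_config(seed = 13)) # default 118 samples, 11%
  prof <- coinfection_profile(ds$sequences)
  k <- glance(prof)$n_coinfected
  bounds <- qbinom(c(0.005, 0.995), 118, 0.11)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
  # truth flags match the planting
  expect_equal(sum(ds$truth$sample_table$coinfected), round(0.11 * 118))
})

test_that("chaq is restricted to permitted clades and melB-style violations are plantable", {
  ds <- simulate_dataset(small_sim_config(seed = 14, n_samples = 40))
  st <- ds$truth$sample_table
  chaq_carriers <- unique(
    dplyr::filter(ds$sequences, segment == "chaq", endsWith(seq_id, "_1"))$sample_id
  )
  expect_true(all(st$chaq_allowed[match(chaq_carriers, st$sample_id)]))
  chk <- chaq_association_check(
    tibble::tibble(sample_id = st$sample_id, clade = st$clade,
                   has_chaq = st$sample_id %in% chaq_carriers,
                   coinfected = st$coinfected),
    restricted_clades = "melB"
  )
  expect_equal(nrow(chk$violations), 0)

  # flipping the flag plants violations
  cfg2 <- small_sim_config(
    seed = 14, n_samples = 40,
    clades = tibble::tibble(clade = c("melA", "melB", "simA"),
                            proportion = c(0.5, 0.3, 0.2),
                            chaq_allowed = TRUE)
  )
  ds2 <- simulate_dataset(cfg2)
  st2 <- ds2$truth$sample_table
  carriers2 <- unique(
    dplyr::filter(ds2$sequences, segment == "chaq", endsWith(seq_id, "_1"))$sample_id
  )
  chk2 <- chaq_association_check(
    tibble::tibble(sample_id = st2$sample_id, clade = st2$clade,
                   has_chaq = st2$sample_id %in% carriers2,
                   coinfected = st2$coinfected),
    restricted_clades = "melB"
  )
  expect_gt(nrow(chk2$violations), 0)
})

test_that("perfect geographic structure yields Snn of exactly one", {
  ds <- simulate_dataset(small_sim_config(seed = 15, n_samples = 30,
                                          geographic_mixing = 0,
                                          coinfection_fraction = 0,
                                          reassortment_rate = 0))
  for (seg in c("RNA1", "chaq")) {
    sub <- dplyr::filter(ds$sequences, segment == seg)
    if (nrow(sub) < 4) next
    tn <- distance_matrix(sub, mode = "tn93")
    labs <- setNames(ds$metadata$location, ds$metadata$seq_id)[sub$seq_id]
    expect_equal(snn_statistic(tn, labs), 1)
  }
})

test_that("Snn decreases monotonically along a mixing sweep", {
  snn_at <- function(mix) {
    ds <- simulate_dataset(small_sim_config(seed = 16, n_samples = 40,
                                            geographic_mixing = mix,
                                            coinfection_fraction = 0,
                                            reassortment_rate = 0))
    sub <- dplyr::filter(ds$sequences, segment == "RNA1")
    tn <- distance_matrix(sub, mode = "tn93")
    labs <- setNames(ds$metadata$location, ds$metadata$seq_id)[sub$seq_id]
    snn_statistic(tn, labs)
  }
  vals <- vapply(c(0, 0.2, 0.5, 0.8, 1), snn_at, numeric(1))
  expect_true(all(diff(vals) < 0.05)) # non-increasing up to simulation noise
  expect_equal(vals[1], 1)
  expect_lt(vals[5], 0.6)
})

test_that("emitted files round-trip to the in-memory dataset", {
  ds <- simulate_dataset(small_sim_config(seed = 17, n_samples = 20))
  dir <- withr::local_tempdir()
  files <- emit_dataset(ds, dir)
  expect_true(all(file.exists(files)))
  md <- read_metadata(files[["metadata"]])
  back <- dplyr::bind_rows(lapply(segment_levels(), function(seg) {
    read_aligned_fasta(files[[paste0("fasta_", seg)]])
  }))
  merged <- join_sequence_metadata(back, md)
  orig <- dplyr::arrange(ds$sequences, seq_id)
  expect_equal(dplyr::arrange(merged, seq_id)$residues, orig$residues)
  expect_equal(sort(md$seq_id), sort(ds$sequences$seq_id))
  truth <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  expect_setequal(truth$seq_ids, ds$sequences$seq_id)
  qpcr <- readr::read_tsv(files[["qpcr"]], show_col_types = FALSE)
  expect_equal(nrow(qpcr), 20)
})

test_that("qPCR levels reproduce the configured bimodal mixture", {
  ds <- simulate_dataset(sim_config(seed = 18))
  lv <- delta_ct_level(ds$qpcr$ct_target, ds$qpcr$ct_reference)
  lg <- log10(lv)
  # two well-separated modes near the configured values
  hi <- lg[lg > -1]
  lo <- lg[lg <= -1]
  expect_equal(median(hi), log10(4.1), tolerance = 0.35)
  expect_equal(median(lo), log10(1 / 3907), tolerance = 0.35)
  expect_gt(length(hi) / length(lg), 0.55)
})

test_that("strand ratios are lowest for RNA1 as configured", {
  ds <- simulate_dataset(sim_config(seed = 19))
  rc <- tidyr::pivot_wider(ds$read_counts, names_from = "strand",
                           values_from = "strand_reads")
  ratios <- rc |>
    dplyr::group_by(segment) |>
    dplyr::summarise(ratio = median(plus / minus), .groups = "drop")
  r1 <- ratios$ratio[ratios$segment == "RNA1"]
  expect_true(all(r1 < ratios$ratio[ratios$segment != "RNA1"]))
})
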
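# Build an identity matrix from a named list of pairwise values,
# defaulting unspecified pairs to `fill`.
ident_matrix <- function(ids, pairs = list(), fill = 85) {
  m <- matrix(fill, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  for (p in pairs) {
    m[p[[1]], p[[2]]] <- m[p[[2]], p[[1]]] <- p[[3]]
  }
  structure(m, mode = "identity", class = c("pairwise_matrix", "matrix"))
}

test_that("identity-gap pairs mirroring the published worked examples are flagged", {
  samples <- c("fly1", "fly2", "fly3")
  map <- tibble::tibble(
    sample_id = samples,
    seq_id_x = paste0(samples, "_R1"),
    seq_id_y = paste0(samples, "_R3")
  )
  # fly1/fly2: near-clonal on segment X (99.5%) but divergent on Y (88.9%)
  ix <- ident_matrix(map$seq_id_x, list(list("fly1_R1", "fly2_R1", 99.5)))
  iy <- ident_matrix(map$seq_id_y, list(list("fly1_R3", "fly2_R3", 88.9)), fill = 97)
  dp <- segment_discordance_pairs(ix, iy, map, segment_x = "RNA1", segment_y = "RNA3")
  expect_equal(nrow(dp), 1)
  expect_equal(dp$identity_high, 99.5)
  expect_equal(dp$identity_low, 88.9)
  expect_equal(dp$segment_low, "RNA3")

  # second pattern: 98.7% on X vs 91.9% on Y
  ix2 <- ident_matrix(map$seq_id_x, list(list("fly1_R1", "fly3_R1", 98.7)))
  iy2 <- ident_matrix(map$seq_id_y, list(list("fly1_R3", "fly3_R3", 91.9)), fill = 97)
  dp2 <- segment_discordance_pairs(ix2, iy2, map, segment_x = "RNA1", segment_y = "chaq")
  expect_equal(nrow(dp2), 1)
  expect_equal(dp2$identity_low, 91.9)
})

test_that("the gap rule is direction-symmetric and respects both thresholds", {
  samples <- c("a", "b")
  map <- tibble::tibble(sample_id = samples,
                        seq_id_x = paste0(samples, "_x"),
                        seq_id_y = paste0(samples, "_y"))
  # divergent on X, clonal on Y: flagged with roles swapped
  ix <- ident_matrix(map$seq_id_x, list(list("a_x", "b_x", 90)))
  iy <- ident_matrix(map$seq_id_y, list(list("a_y", "b_y", 99.9)))
  dp <- segment_discordance_pairs(ix, iy, map, segment_x = "X", segment_y = "Y")
  expect_equal(dp$segment_low, "X")
  # 97/99.9: high but not low enough -> no flag
  ix2 <- ident_matrix(map$seq_id_x, list(list("a_x", "b_x", 97)))
  expect_equal(nrow(segment_discordance_pairs(ix2, iy, map)), 0)
  expect_error(segment_discordance_pairs(ix, iy, map, high = 95, low = 95), "exceed")
})

test_that("coinfected samples (duplicate map rows) are excluded with a warning", {
  map <- tibble::tibble(
    sample_id = c("a", "a", "b"),
    seq_id_x = c("a_x1", "a_x2", "b_x"),
    seq_id_y = c("a_y1", "a_y2", "b_y")
  )
  ix <- ident_matrix(unique(map$seq_id_x))
  iy <- ident_matrix(unique(map$seq_id_y))
  expect_warning(dp <- segment_discordance_pairs(ix, iy, map), "coinfection")
  expect_equal(nrow(dp), 0)
})

test_that("collapsed-tree confirmation vetoes pairs sharing a polytomy", {
  samples <- c("a", "b", "c")
  map <- tibble::tibble(sample_id = samples,
                        seq_id_x = paste0(samples, "_x"),
                        seq_id_y = paste0(samples, "_y"))
  ix <- ident_matrix(map$seq_id_x, list(list("a_x", "b_x", 99.5)))
  iy <- ident_matrix(map$seq_id_y, list(list("a_y", "b_y", 92)), fill = 97)
  # tree where the divergent-segment sequences a_y and b_y fall in the
  # same polytomy after collapse: the pair is vetoed
  tree_same <- collapse_short_branches(
    read_newick(text = "((a_y:0.01,b_y:0.0005):0.0004,c_y:0.05);"), 0.001
  )
  dp <- segment_discordance_pairs(ix, iy, map, tree_y = tree_same)
  expect_equal(nrow(dp), 0)
  # tree separating them: the pair survives
  tree_apart <- collapse_short_branches(
    read_newick(text = "((a_y:0.01,c_y:0.01):0.05,b_y:0.05);"), 0.001
  )
  dp2 <- segment_discordance_pairs(ix, iy, map, tree_y = tree_apart)
  expect_equal(nrow(dp2), 1)
})

test_that("flagged pairs sharing a sample merge into one event", {
  samples <- c("a", "b", "c", "d")
  map <- tibble::tibble(sample_id = samples,
                        seq_id_x = paste0(samples, "_x"),
                        seq_id_y = paste0(samples, "_y"))
  ix <- ident_matrix(map$seq_id_x, list(
    list("a_x", "b_x", 99.5), list("a_x", "c_x", 99.4), list("b_x", "c_x", 99.6)
  ))
  iy <- ident_matrix(map$seq_id_y, list(
    list("a_y", "b_y", 90), list("a_y", "c_y", 90)
  ), fill = 97)
  dp <- segment_discordance_pairs(ix, iy, map)
  expect_equal(nrow(dp), 2)
  ev <- attr(dp, "events")
  expect_equal(nrow(ev), 1)
  expect_match(ev$samples, "a,b,c")
})

test_that("clade context labels pairs within or between clades", {
  samples <- c("a", "b")
  map <- tibble::tibble(sample_id = samples,
                        seq_id_x = paste0(samples, "_x"),
                        seq_id_y = paste0(samples, "_y"))
  ix <- ident_matrix(map$seq_id_x, list(list("a_x", "b_x", 99.5)))
  iy <- ident_matrix(map$seq_id_y, list(list("a_y", "b_y", 90)), fill = 97)
  genos <- tibble::tibble(seq_id = c("a_y", "b_y"), clade = c("G1", "G1"))
  dp <- segment_discordance_pairs(ix, iy, map, genotypes = genos)
  expect_equal(dp$clade_context, "within-clade")
  genos2 <- tibble::tibble(seq_id = c("a_y", "b_y"), clade = c("G1", "G2"))
  dp2 <- segment_discordance_pairs(ix, iy, map, genotypes = genos2)
  expect_equal(dp2$clade_context, "between-clade")
})

test_that("clade concordance finds planted mixed-clade samples only", {
  clades <- tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3"), each = 3),
    segment = rep(c("RNA1", "RNA2", "RNA3"), 3),
    clade = c("melA", "melA", "melA",
              "melA", "melB", "melA", # planted between-clade reassortant
              "melB", "melB", "melB")
  )
  tab <- clade_concordance_table(clades)
  expect_equal(attr(tab, "discordant_samples"), "s2")
  expect_equal(glance(tab)$n_discordant, 1)
  all_same <- clade_concordance_table(dplyr::filter(clades, sample_id != "s2"))
  expect_equal(glance(all_same)$n_discordant, 0)
})

test_that("planted within-clade events are recovered end to end", {
  ds <- simulate_dataset(sim_config(seed = 202, n_samples = 36,
                                    coinfection_fraction = 0),
                         n_reassortment_events = 3)
  ev <- ds$truth$reassortment_events
  expect_true(all(ev$resolvable))
  st <- ds$truth$sample_table
  mats <- lapply(segment_levels(), function(s) {
    sub <- dplyr::filter(ds$sequences, segment == s, endsWith(seq_id, "_1"))
    sub$seq_id <- sub$sample_id
    distance_matrix(sub, mode = "identity")
  })
  names(mats) <- segment_levels()
  found <- character()
  for (pr in utils::combn(c("RNA1", "RNA2", "RNA3"), 2, simplify = FALSE)) {
    shared <- intersect(rownames(mats[[pr[1]]]), rownames(mats[[pr[2]]]))
    map <- tibble::tibble(sample_id = shared, seq_id_x = shared, seq_id_y = shared)
    dp <- segment_discordance_pairs(mats[[pr[1]]], mats[[pr[2]]], map,
                                    segment_x = pr[1], segment_y = pr[2])
    hit <- dp$segment_low %in% pr | dp$segment_high %in% pr
    found <- union(found, c(dp$sample_a, dp$sample_b))
  }
  galbut_ev <- ev[ev$segment %in% c("RNA1", "RNA2", "RNA3"), ]
  expect_true(all(galbut_ev$sample_id %in% found))
})
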
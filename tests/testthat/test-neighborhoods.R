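test_that("neighborhood extraction windows and truncation at replicon ends", {
  g <- toy_genome()
  nb <- extract_neighborhoods(g, "Effector", window = 2L)
  expect_length(nb, 1L)
  expect_equal(nb[[1]]$anchor, "g3")
  expect_equal(nb[[1]]$members$gene_id, c("g1", "g2", "g3", "g4", "g5"))

  nb_first <- extract_neighborhoods(g, c("TIR"), window = 2L)
  expect_equal(nb_first[[1]]$members$gene_id, c("g1", "g2", "g3"))  # no upstream

  expect_length(extract_neighborhoods(g, "NoSuchDomain", window = 2L), 0L)

  nb_pred <- extract_neighborhoods(g, function(row, prot) row$gene_id == "h1",
                                   window = 2L)
  expect_equal(nb_pred[[1]]$members$gene_id, "h1")   # singleton replicon
})

test_that("distance filter trims outward walk at the first oversized gap", {
  tx <- taxon_record("t", "P")
  # downstream gaps from anchor: 10, 60, 5
  genes <- data.frame(gene_id = c("a", "d1", "d2", "d3"),
                      replicon_id = "chr",
                      start = c(1L, 111L, 261L, 377L),
                      end = c(100L, 200L, 371L, 450L),
                      strand = "+", protein_id = NA_character_,
                      stringsAsFactors = FALSE)
  g <- genome(tx, genes)
  nb <- extract_neighborhoods(g, function(r, p) r$gene_id == "a", window = 3L)[[1]]
  out <- apply_validity_filters(nb, max_gap_nt = 50L)
  expect_equal(out$members$gene_id, c("a", "d1"))
  flags <- out$filter_flags
  expect_equal(flags$removed_by[flags$gene_id == "d2"], "distance")
  expect_equal(flags$removed_by[flags$gene_id == "d3"], "beyond_break")
})

test_that("gap exactly at the threshold is retained and overlaps always kept", {
  tx <- taxon_record("t", "P")
  genes <- data.frame(gene_id = c("a", "b", "c"), replicon_id = "chr",
                      start = c(1L, 151L, 240L), end = c(100L, 250L, 330L),
                      strand = "+", protein_id = NA_character_,
                      stringsAsFactors = FALSE)
  # gap a->b = 50 (boundary), b->c = -11 (overlap)
  g <- genome(tx, genes)
  nb <- extract_neighborhoods(g, function(r, p) r$gene_id == "a", window = 2L)[[1]]
  out <- apply_validity_filters(nb, max_gap_nt = 50L)
  expect_equal(out$members$gene_id, c("a", "b", "c"))
})

test_that("directionality filter breaks at the first strand flip", {
  g <- toy_genome()  # g5 is on '-' among '+' genes
  nb <- extract_neighborhoods(g, "Effector", window = 2L)[[1]]
  out <- apply_validity_filters(nb, max_gap_nt = 1e6L)
  expect_false("g5" %in% out$members$gene_id)
  expect_equal(out$filter_flags$removed_by[out$filter_flags$gene_id == "g5"],
               "directionality")
  keep_all <- apply_validity_filters(nb, max_gap_nt = 1e6L,
                                     require_codirectional = FALSE)
  expect_true("g5" %in% keep_all$members$gene_id)
})

test_that("trimming is monotone in max_gap_nt", {
  set.seed(23)
  sim <- generate_genomes(synthetic_config(
    n_taxa = 4L, seed = 23L,
    phyla = c(Cyanobacteria = 0.5, Proteobacteria = 0.5),
    cassettes = list(list(n_genes = 3L, n_carriers = 2L, n_phyla = 2L,
                          max_gap = 50L))))
  anchors <- sim$truth$cassettes[[1]]$anchor_domain
  nbs <- unlist(lapply(sim$genomes, extract_neighborhoods, anchor = anchors,
                       window = 3L), recursive = FALSE)
  for (nb in nbs) {
    kept_prev <- character()
    for (gap in c(0L, 25L, 50L, 200L, 5000L)) {
      kept <- apply_validity_filters(nb, max_gap_nt = gap)$members$gene_id
      expect_true(all(kept_prev %in% kept))
      kept_prev <- kept
    }
  }
})

test_that("planted cassette across 3 phyla yields exactly one 6-member group", {
  sim <- generate_genomes(synthetic_config(n_taxa = 12L, seed = 41L))
  anchors <- sim$truth$cassettes[[1]]$anchor_domain
  nbs <- unlist(lapply(sim$genomes, extract_neighborhoods, anchor = anchors,
                       window = 2L), recursive = FALSE)
  nbs <- lapply(nbs, apply_validity_filters)
  groups <- find_conserved_groups(nbs, sim$genomes)
  expect_length(groups, 1L)
  expect_length(groups[[1]]$member_neighborhoods, 6L)
  expect_length(groups[[1]]$phyla, 3L)
  ev <- evaluate_recovery(groups, sim$truth)
  expect_equal(ev$recall, 1.0)
  expect_equal(ev$precision, 1.0)
})

test_that("a cassette confined to one phylum is filtered out", {
  cfg <- synthetic_config(n_taxa = 8L, seed = 42L,
                          cassettes = list(list(n_genes = 3L, n_carriers = 2L,
                                                n_phyla = 1L, max_gap = 50L)))
  sim <- generate_genomes(cfg)
  anchors <- sim$truth$cassettes[[1]]$anchor_domain
  nbs <- unlist(lapply(sim$genomes, extract_neighborhoods, anchor = anchors,
                       window = 2L), recursive = FALSE)
  nbs <- lapply(nbs, apply_validity_filters)
  expect_length(find_conserved_groups(nbs, sim$genomes), 0L)
})

test_that("neighborhoods lacking sequences are rejected by name", {
  g <- toy_genome()
  g$proteins$p2$sequence <- NA_character_
  nb <- extract_neighborhoods(g, "Effector", window = 1L)
  expect_error(find_conserved_groups(nb, list(tx1 = g)), "anchored at g3")
})

test_that("group discovery is invariant to neighborhood input order", {
  sim <- generate_genomes(synthetic_config(n_taxa = 8L, seed = 43L))
  anchors <- sim$truth$cassettes[[1]]$anchor_domain
  nbs <- unlist(lapply(sim$genomes, extract_neighborhoods, anchor = anchors,
                       window = 2L), recursive = FALSE)
  nbs <- lapply(nbs, apply_validity_filters)
  g1 <- find_conserved_groups(nbs, sim$genomes)
  g2 <- find_conserved_groups(rev(nbs), sim$genomes)
  taxa1 <- lapply(g1, function(g) sort(unname(g$taxa)))
  taxa2 <- lapply(g2, function(g) sort(unname(g$taxa)))
  expect_setequal(taxa1, taxa2)
})
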
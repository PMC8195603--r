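test_that("generation is fully deterministic under the seed", {
  cfg <- synthetic_config(n_taxa = 6L, seed = 11L,
                          phyla = c(Cyanobacteria = 0.5, Proteobacteria = 0.5),
                          cassettes = list(list(n_genes = 3L, n_carriers = 4L,
                                                n_phyla = 2L, max_gap = 50L)))
  sim1 <- generate_genomes(cfg)
  sim2 <- generate_genomes(cfg)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  for (i in seq_along(sim1$genomes)) {
    write_annotation_table(sim1$genomes[[i]], p1)
    write_annotation_table(sim2$genomes[[i]], p2)
    expect_identical(readLines(p1), readLines(p2))
  }
  expect_identical(sim1$truth, sim2$truth)

  a1 <- generate_alignment(8L, rep(c("conserved", "diversified"), 5), seed = 4L)
  a2 <- generate_alignment(8L, rep(c("conserved", "diversified"), 5), seed = 4L)
  expect_identical(a1, a2)

  c1 <- generate_count_table(20L, 10L, seed = 9L)
  c2 <- generate_count_table(20L, 10L, seed = 9L)
  expect_identical(c1, c2)
})

test_that("planted cassettes are recorded with carriers, loci and phyla", {
  cfg <- synthetic_config(n_taxa = 12L, seed = 21L,
                          cassettes = list(list(n_genes = 4L, n_carriers = 6L,
                                                n_phyla = 3L, max_gap = 50L)))
  sim <- generate_genomes(cfg)
  cs <- sim$truth$cassettes[[1]]
  expect_length(cs$carriers, 6L)
  expect_length(cs$inserted_genes, 6L)
  expect_setequal(names(cs$inserted_genes), cs$carriers)
  expect_length(cs$phyla, 3L)
  # every planted gene id resolves in its carrier genome
  for (tid in cs$carriers) {
    gids <- unname(cs$inserted_genes[[tid]])
    expect_true(all(gids %in% sim$genomes[[tid]]$genes$gene_id))
  }
})

test_that("planted cassettes satisfy all three validity filters by construction", {
  for (seed in c(31L, 32L, 33L)) {
    sim <- generate_genomes(synthetic_config(n_taxa = 12L, seed = seed))
    cs <- sim$truth$cassettes[[1]]
    phyla <- vapply(cs$carriers, function(t) sim$genomes[[t]]$taxon$phylum,
                    character(1))
    expect_gte(length(unique(phyla)), 2L)
    for (tid in cs$carriers) {
      g <- sim$genomes[[tid]]$genes
      rows <- g[match(unname(cs$inserted_genes[[tid]]), g$gene_id), ]
      rows <- rows[order(rows$start), ]
      expect_equal(length(unique(rows$strand)), 1L)           # co-directional
      gaps <- intergenic_gap(rows$end[-nrow(rows)], rows$start[-1])
      expect_true(all(gaps <= 50L))                           # distance filter
    }
  }
})

test_that("zero divergence gives identical family copies; identity decreases with divergence", {
  sim0 <- generate_genomes(synthetic_config(n_taxa = 8L, seed = 5L,
                                            family_divergence = 0))
  cs <- sim0$truth$cassettes[[1]]
  fam1 <- vapply(cs$carriers, function(tid) {
    gid <- unname(cs$inserted_genes[[tid]][cs$families[1]])
    g <- sim0$genomes[[tid]]
    g$proteins[[g$genes$protein_id[g$genes$gene_id == gid]]]$sequence
  }, character(1))
  expect_equal(length(unique(fam1)), 1L)

  # mean pairwise identity is monotone decreasing in divergence
  set.seed(77)
  anc <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 300,
                      replace = TRUE), collapse = "")
  mean_ident <- vapply(c(0.05, 0.15, 0.3), function(d) {
    idents <- replicate(20, {
      a <- strsplit(mutate_sequence(anc, d), "")[[1]]
      b <- strsplit(mutate_sequence(anc, d), "")[[1]]
      mean(a == b)
    })
    mean(idents)
  }, numeric(1))
  expect_true(all(diff(mean_ident) < 0))
})

test_that("alignment generator hits its entropy targets", {
  a <- generate_alignment(10L, rep("conserved", 6), seed = 1L)
  expect_equal(entropy_profile(a)$H, rep(0, 6))
  # diversified k=2 columns: mean entropy -> 1 bit for many rows
  big <- generate_alignment(4000L, rep("diversified", 30), k = 2L, seed = 2L)
  expect_equal(mean(entropy_profile(big)$H), 1.0, tolerance = 0.01)
  expect_error(generate_alignment(1L, "conserved"), ">= 2")
})

test_that("count tables have Poisson background and recorded expansions", {
  ct <- generate_count_table(40L, 25L, seed = 8L,
                             expansion_spec = list(list(organism = 3L,
                                                        n_families = 5L,
                                                        copies = 300L)))
  expect_equal(ct$truth[[1]]$organism, "org003")
  expect_equal(ct$truth[[1]]$copies, 300L)
  expect_equal(sum(ct$counts["org003", ct$truth[[1]]$families]), 300L)
  # background block: no count above the Poisson(1) 99.99% quantile except
  # by chance (tail freq at most a few in 1000 draws)
  bg <- ct$counts[, seq_len(25L)]
  q <- stats::qpois(0.9999, 1)
  expect_lte(mean(bg > q), 5 / 1000)
})

test_that("architecture generator plants terminal bias only where asked", {
  archs <- generate_architectures(300L, "X", position_probs = c(1, 0, 0),
                                  k_range = c(2L, 5L), seed = 3L)
  firsts <- vapply(archs, `[`, character(1), 1L)
  expect_true(all(firsts == "X"))
  null_archs <- generate_architectures(300L, "X", position_probs = NULL,
                                       k_range = c(3L, 3L), seed = 3L)
  pos <- vapply(null_archs, function(a) which(a == "X"), integer(1))
  expect_gt(min(table(factor(pos, levels = 1:3))), 0)
})
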
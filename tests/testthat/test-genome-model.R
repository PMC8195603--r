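test_that("annotation-table rows map to genes, architectures and tri-state flags", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("taxon_id", "phylum", "multicellular", "replicon_id", "gene_id",
            "start", "end", "strand", "protein_id", "architecture"),
          collapse = "\t"),
    "t1\tCyanobacteria\ttrue\tchr\tg1\t100\t400\t+\tp1\tTIR+Caspase",
    "t1\tCyanobacteria\ttrue\tchr\tg2\t500\t900\t-\tp2\t"),
    path)
  g <- read_annotation_table(path)
  expect_equal(nrow(g$genes), 2L)
  expect_equal(g$proteins$p1$architecture, c("TIR", "Caspase"))
  expect_equal(g$proteins$p2$architecture, character())
  expect_true(g$taxon$multicellular)
  expect_equal(g$genes$strand, c("+", "-"))
})

test_that("multicellular 'NA' is kept tri-state, not coerced", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("taxon_id", "phylum", "multicellular", "replicon_id", "gene_id",
            "start", "end", "strand", "protein_id", "architecture"),
          collapse = "\t"),
    "t2\tProteobacteria\tNA\tchr\tg1\t1\t60\t+\tp1\tX"),
    path)
  g <- read_annotation_table(path)
  expect_true(is.na(g$taxon$multicellular))
  expect_true(is.logical(g$taxon$multicellular))
})

test_that("malformed annotation rows are rejected with a row number", {
  hdr <- paste(c("taxon_id", "phylum", "multicellular", "replicon_id",
                 "gene_id", "start", "end", "strand", "protein_id",
                 "architecture"), collapse = "\t")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr, "t1\tP\ttrue\tchr\tg1\t100\t50\t+\tp1\tX"), path)
  expect_error(read_annotation_table(path), "row 1.*coordinates")
  writeLines(c(hdr, "t1\tP\ttrue\tchr\tg1\t1\t50\t*\tp1\tX"), path)
  expect_error(read_annotation_table(path), "row 1.*strand")
  writeLines(c(hdr,
               "t1\tP\ttrue\tchr\tg1\t1\t50\t+\tp1\tX",
               "t1\tP\ttrue\tchr\tg1\t60\t90\t+\tp2\tY"), path)
  expect_error(read_annotation_table(path), "duplicate gene_id")
})

test_that("write/read round trip is lossless, including empty genomes", {
  g <- toy_genome()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(g, path)
  g2 <- read_annotation_table(path)
  expect_equal(g2$genes, g$genes)
  expect_equal(g2$proteins, g$proteins)
  expect_equal(g2$taxon, g$taxon)

  sim <- generate_genomes(synthetic_config(n_taxa = 4L, seed = 3L,
                                           cassettes = list()))
  for (gs in sim$genomes) {
    write_annotation_table(gs, path)
    back <- read_annotation_table(path)
    expect_equal(back$genes, gs$genes)
    expect_equal(back$proteins, gs$proteins)
  }

  empty <- genome(taxon_record("t0", "P"), toy_genome()$genes[0, ], list())
  write_annotation_table(empty, path)
  expect_equal(length(readLines(path)), 1L)  # header only
})

test_that("genes are sorted by (replicon_id, start) regardless of input order", {
  g <- toy_genome()
  shuffled <- g$genes[c(4, 6, 1, 5, 3, 2), ]
  g2 <- genome(g$taxon, shuffled, g$proteins)
  expect_equal(g2$genes, g$genes)
  expect_false(is.unsorted(g2$genes$start[g2$genes$replicon_id == "chr"]))
})

test_that("overlapping genes are permitted but flagged", {
  tx <- taxon_record("t", "P")
  genes <- data.frame(gene_id = c("a", "b"), replicon_id = "chr",
                      start = c(1L, 90L), end = c(100L, 200L), strand = "+",
                      protein_id = NA_character_, stringsAsFactors = FALSE)
  g <- genome(tx, genes)
  expect_equal(attr(g, "overlapping"), "b")
})

test_that("GenBank reader resolves strands, joins and pairs with the TSV dialect", {
  expect_silent(g <- read_genbank(extdata("example.gbk")))
  expect_equal(nrow(g$genes), 3L)
  cds2 <- g$genes[g$genes$gene_id == "AAA00002.1", ]
  expect_equal(cds2$strand, "-")       # complement(501..800)
  expect_equal(c(cds2$start, cds2$end), c(501L, 800L))
  cds3 <- g$genes[g$genes$gene_id == "AAA00003.1", ]
  expect_equal(c(cds3$start, cds3$end), c(50L, 280L))  # join flattened
  expect_match(g$proteins[["AAA00001.1"]]$sequence, "^M")

  paired <- read_annotation_table(extdata("example_annotation.tsv"))
  expect_equal(g$genes, paired$genes)
  expect_equal(g$proteins, paired$proteins)
  expect_equal(g$taxon, paired$taxon)
})

test_that("GenBank records without CDS or protein_id degrade with warnings", {
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       EMPTY01 100 bp DNA linear BCT 01-JAN-2020",
               "FEATURES             Location/Qualifiers",
               "     source          1..100", "//"), path)
  expect_warning(g <- read_genbank(path), "no CDS")
  expect_equal(nrow(g$genes), 0L)

  writeLines(c("LOCUS       NOID01 500 bp DNA linear BCT 01-JAN-2020",
               "FEATURES             Location/Qualifiers",
               "     CDS             10..69",
               "                     /locus_tag=\"LT_1\"",
               paste0("                     /translation=\"",
                      strrep("MA", 9), "M\""),
               "//"), path)
  expect_warning(g <- read_genbank(path), "assigned 'LT_1_1'")
  expect_equal(g$genes$gene_id, "LT_1_1")

  writeLines("not a genbank file", path)
  expect_error(read_genbank(path), "line 1")
})

test_that("alignment container enforces its invariants and round-trips FASTA", {
  expect_error(alignment("a", "ACD"), ">= 2 rows")
  expect_error(alignment(c("a", "b"), c("ACD", "AC")), "differ in length")
  aln <- alignment(c("a", "b"), c("AC-D", "ACED"))
  path <- withr::local_tempfile(fileext = ".fa")
  write_alignment(aln, path)
  expect_equal(read_alignment(path), aln)
})

test_that("hit tables validate header and p-value range", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query\thit\tp_value", "A\tB\t1e-6", "A\tB\t0.02"), path)
  ht <- read_hit_table(path)
  expect_equal(nrow(ht), 2L)
  writeLines(c("query\thit\tp_value", "A\tB\t0"), path)
  expect_error(read_hit_table(path), "p_value")
  writeLines(c("q\th\tp", "A\tB\t0.5"), path)
  expect_error(read_hit_table(path), "header")
})
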
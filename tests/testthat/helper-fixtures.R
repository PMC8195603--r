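# Shared in-code fixtures for the suite.

# A hand-laid genome: two replicons, operon-like run around g2..g4.
toy_genome <- function() {
  tx <- taxon_record("tx1", "Cyanobacteria", multicellular = TRUE)
  genes <- data.frame(
    gene_id    = c("g1", "g2", "g3", "g4", "g5", "h1"),
    replicon_id = c(rep("chr", 5), "pls"),
    start      = c(100L, 600L, 1000L, 1460L, 2000L, 10L),
    end        = c(400L, 950L, 1399L, 1900L, 2300L, 300L),
    strand     = c("+", "+", "+", "+", "-", "+"),
    protein_id = c("p1", "p2", "p3", "p4", "p5", "q1"),
    stringsAsFactors = FALSE)
  prots <- list(
    p1 = protein("p1", strrep("ACDEFGHIKL", 10), c("TIR", "Caspase")),
    p2 = protein("p2", strrep("MKTAYIAKQR", 10), "AnchorDom"),
    p3 = protein("p3", strrep("LIVMFWYACD", 10), "Effector"),
    p4 = protein("p4", strrep("GASTCPNQDE", 10), "Effector2"),
    p5 = protein("p5", strrep("HKRDENQSTA", 10), character()),
    q1 = protein("q1", strrep("WYFMLIVATC", 10), "Solo"))
  genome(tx, genes, prots)
}

# families of mutated copies with known membership, for clustering checks
make_families <- function(n_fam, n_members, divergence, len_range = c(150L, 250L)) {
  seqs <- character()
  truth <- character()
  for (f in seq_len(n_fam)) {
    len <- sample(len_range[1]:len_range[2], 1L)
    anc <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        len, replace = TRUE), collapse = "")
    for (m in seq_len(n_members)) {
      id <- sprintf("f%02d_m%02d", f, m)
      seqs[id] <- mutate_sequence(anc, divergence)
      truth[id] <- sprintf("f%02d", f)
    }
  }
  list(sequences = seqs, families = truth)
}

# brute-force single-linkage components from an explicit edge predicate
brute_force_components <- function(ids, linked) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    if (linked(ids[i], ids[j])) {
      ri <- find(ids[i]); rj <- find(ids[j])
      if (ri != rj) parent[[ri]] <- rj
    }
  }
  roots <- vapply(ids, find, character(1))
  comps <- split(ids, roots)
  comps <- lapply(comps, sort)
  comps <- comps[order(vapply(comps, `[`, character(1), 1L))]
  names(comps) <- NULL
  comps
}

extdata <- function(f) system.file("extdata", f, package = "contextscan")
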
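#' Configuration for the synthetic genome generator
#'
#' Defines the study conditions under which planted conserved cassettes are
#' benchmarked: taxa spread over several phyla, operon-like strand runs,
#' realistic intergenic gaps, and homologous families at a tunable per-site
#' divergence. All randomness flows from `seed`; a fixed seed reproduces the
#' output byte for byte.
#'
#' @param n_taxa Number of genomes.
#' @param phyla Named numeric vector: phylum labels with per-taxon assignment
#'   probabilities (must sum to 1).
#' @param multicellular_fraction Fraction of taxa flagged multicellular;
#'   a small fraction is left unknown (`NA`) to exercise tri-state handling.
#' @param unknown_fraction Fraction of taxa with unknown multicellularity.
#' @param genes_per_replicon Integer range `c(min, max)`.
#' @param n_replicons Replicons per genome (integer range `c(min, max)`).
#' @param intergenic_gap `list(mean, sd, min)`: normal gap model, truncated
#'   at `min` (negative values produce overlapping genes).
#' @param operon_run_length Mean geometric run length of same-strand genes.
#' @param family_divergence Per-site substitution probability within a
#'   planted family, in `[0, 0.5]`.
#' @param protein_length Background protein length range (aa).
#' @param cassettes List of cassette specs, each
#'   `list(n_genes, n_carriers, n_phyla, max_gap)`: a co-directional run of
#'   `n_genes` homologous families planted into `n_carriers` taxa spanning
#'   `n_phyla` phyla with intergenic gaps `<= max_gap`.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_taxa = 12L,
                             phyla = c(Cyanobacteria = 0.25,
                                       Actinobacteria = 0.25,
                                       Proteobacteria = 0.25,
                                       Chloroflexi = 0.25),
                             multicellular_fraction = 0.3,
                             unknown_fraction = 0.1,
                             genes_per_replicon = c(25L, 35L),
                             n_replicons = c(1L, 1L),
                             intergenic_gap = list(mean = 150, sd = 80, min = -30),
                             operon_run_length = 3,
                             family_divergence = 0.1,
                             protein_length = c(150L, 400L),
                             cassettes = list(list(n_genes = 4L, n_carriers = 6L,
                                                   n_phyla = 3L, max_gap = 50L)),
                             seed = 1L) {
  if (abs(sum(phyla) - 1) > 1e-9) stopf("phyla probabilities must sum to 1")
  if (is.null(names(phyla))) stopf("phyla must be a named vector")
  if (family_divergence < 0 || family_divergence > 0.5)
    stopf("family_divergence must lie in [0, 0.5]")
  if (multicellular_fraction < 0 || multicellular_fraction > 1)
    stopf("multicellular_fraction must lie in [0, 1]")
  structure(list(n_taxa = as.integer(n_taxa), phyla = phyla,
                 multicellular_fraction = multicellular_fraction,
                 unknown_fraction = unknown_fraction,
                 genes_per_replicon = as.integer(genes_per_replicon),
                 n_replicons = as.integer(n_replicons),
                 intergenic_gap = intergenic_gap,
                 operon_run_length = operon_run_length,
                 family_divergence = family_divergence,
                 protein_length = as.integer(protein_length),
                 cassettes = cassettes, seed = as.integer(seed)),
            class = "synthetic_config")
}

random_protein_seq <- function(len) paste(sample(AA20, len, replace = TRUE),
                                          collapse = "")

#' Mutate a protein sequence at a per-site substitution rate
#'
#' Substitutions are i.i.d. per site, uniform over the 19 alternative
#' residues; no indels.
#'
#' @param seq Amino-acid string.
#' @param divergence Per-site substitution probability.
#' @return Mutated sequence string.
#' @export
mutate_sequence <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < divergence
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit],
                         function(a) sample(setdiff(AA20, a), 1L), character(1))
  }
  paste(chars, collapse = "")
}

#' Generate synthetic genomes with planted conserved cassettes
#'
#' Background genes carry unique singleton families (random sequences,
#' length drawn from `protein_length`) so any false-positive conserved
#' neighborhood is attributable. Strand runs are drawn first (geometric
#' lengths) and genes assigned into the runs, emulating operons. Each
#' cassette is a co-directional run of homologous families with intergenic
#' gaps at or below its `max_gap`, inserted at a random locus of each
#' carrier; carriers span the configured number of phyla, so every planted
#' cassette passes the distance, directionality and phylum filters by
#' construction. Cassette proteins are mutated copies of a family ancestor
#' at `family_divergence`.
#'
#' @param config A [synthetic_config()].
#' @return `list(genomes = <list of genome>, truth = <planted_truth>)`. The
#'   truth object records, per cassette: family ids in order, carrier taxa,
#'   phyla spanned, and the inserted gene ids per carrier.
#' @export
generate_genomes <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_taxa
  phyla_lbl <- names(config$phyla)

  # round-robin base assignment keeps every phylum populated, then shuffle
  base <- rep(phyla_lbl, length.out = n)
  taxon_phyla <- sample(base)
  taxon_ids <- sprintf("t%02d", seq_len(n))
  mc_draw <- stats::runif(n)
  multicellular <- ifelse(mc_draw < config$multicellular_fraction, TRUE,
                          ifelse(mc_draw < config$multicellular_fraction +
                                   config$unknown_fraction, NA, FALSE))

  # plan cassettes: carriers spread over the requested number of phyla
  truth_cassettes <- list()
  carrier_plan <- vector("list", length(config$cassettes))
  for (ci in seq_along(config$cassettes)) {
    cs <- config$cassettes[[ci]]
    pool_phyla <- names(which(table(taxon_phyla) > 0))
    if (cs$n_phyla > length(pool_phyla))
      stopf("cassette %d: %d phyla requested but only %d present",
            ci, cs$n_phyla, length(pool_phyla))
    chosen_phyla <- sample(pool_phyla, cs$n_phyla)
    # allocate carriers as evenly as possible over the chosen phyla
    alloc <- rep(floor(cs$n_carriers / cs$n_phyla), cs$n_phyla)
    extra <- cs$n_carriers - sum(alloc)
    if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
    carriers <- character()
    for (pi in seq_along(chosen_phyla)) {
      cand <- taxon_ids[taxon_phyla == chosen_phyla[pi]]
      if (length(cand) < alloc[pi])
        stopf("cassette %d: phylum %s has %d taxa, %d carriers needed",
              ci, chosen_phyla[pi], length(cand), alloc[pi])
      carriers <- c(carriers, sample(cand, alloc[pi]))
    }
    fam_ids <- sprintf("CAS%d_f%d", ci, seq_len(cs$n_genes))
    anc_len <- sample(config$protein_length[1]:config$protein_length[2],
                      cs$n_genes, replace = TRUE)
    ancestors <- vapply(anc_len, random_protein_seq, character(1))
    carrier_plan[[ci]] <- list(spec = cs, carriers = carriers,
                               phyla = chosen_phyla, fam_ids = fam_ids,
                               ancestors = ancestors)
    truth_cassettes[[ci]] <- list(cassette_id = sprintf("CAS%d", ci),
                                  families = fam_ids, carriers = carriers,
                                  phyla = sort(chosen_phyla),
                                  anchor_domain = sprintf("CAS%d_D1", ci),
                                  inserted_genes = list())
  }

  genomes <- vector("list", n)
  for (ti in seq_len(n)) {
    tid <- taxon_ids[ti]
    tx <- taxon_record(tid, taxon_phyla[ti],
                       multicellular = multicellular[ti])
    n_rep <- sample_range(config$n_replicons[1], config$n_replicons[2])
    gene_rows <- list()
    proteins <- list()
    gcount <- 0L
    for (ri in seq_len(n_rep)) {
      rep_id <- sprintf("%s_r%d", tid, ri)
      ng <- sample_range(config$genes_per_replicon[1], config$genes_per_replicon[2])
      # items: list(len, strand, protein seq, family label)
      items <- list()
      # strand runs drawn first, genes assigned into runs
      strands <- character(0)
      while (length(strands) < ng) {
        run <- 1L + stats::rgeom(1L, 1 / config$operon_run_length)
        strands <- c(strands, rep(sample(c("+", "-"), 1L), run))
      }
      strands <- strands[seq_len(ng)]
      for (gi in seq_len(ng)) {
        gcount <- gcount + 1L
        len <- sample_range(config$protein_length[1], config$protein_length[2])
        items[[gi]] <- list(aa_len = len, strand = strands[gi],
                            seq = random_protein_seq(len),
                            domain = sprintf("BG_%s_%04d", tid, gcount),
                            family = NA_character_, gap = NA_integer_)
      }
      # splice cassettes carried by this taxon into the first replicon
      if (ri == 1L) {
        for (ci in seq_along(carrier_plan)) {
          cp <- carrier_plan[[ci]]
          if (!tid %in% cp$carriers) next
          cs <- cp$spec
          strand <- sample(c("+", "-"), 1L)
          cass_items <- lapply(seq_len(cs$n_genes), function(k) {
            list(aa_len = nchar(cp$ancestors[k]), strand = strand,
                 seq = mutate_sequence(cp$ancestors[k], config$family_divergence),
                 domain = sprintf("CAS%d_D%d", ci, k),
                 family = cp$fam_ids[k],
                 gap = sample(0:cs$max_gap, 1L))
          })
          cass_items[[1]]$gap <- NA_integer_  # first gene uses background gap
          at <- sample(0:length(items), 1L)
          items <- append(items, cass_items, after = at)
        }
      }
      # lay out coordinates
      pos <- 1L
      for (gi in seq_along(items)) {
        it <- items[[gi]]
        if (gi > 1L) {
          gap <- it$gap
          if (is.na(gap)) {
            gap <- round(stats::rnorm(1L, config$intergenic_gap$mean,
                                      config$intergenic_gap$sd))
            gap <- max(gap, config$intergenic_gap$min)
          }
          pos <- pos + gap
          if (pos < 1L) pos <- 1L
        }
        glen <- 3L * it$aa_len + 3L
        gene_id <- sprintf("%s_g%04d", tid, length(gene_rows) + 1L)
        pid <- sprintf("%s_p", gene_id)
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = gene_id, replicon_id = rep_id,
          start = pos, end = pos + glen - 1L, strand = it$strand,
          protein_id = pid, stringsAsFactors = FALSE)
        proteins[[pid]] <- protein(pid, it$seq, it$domain)
        if (!is.na(it$family)) {
          ci <- as.integer(sub("^CAS(\\d+)_.*$", "\\1", it$family))
          rec <- truth_cassettes[[ci]]$inserted_genes
          rec[[tid]] <- c(rec[[tid]], stats::setNames(gene_id, it$family))
          truth_cassettes[[ci]]$inserted_genes <- rec
        }
        pos <- pos + glen
      }
    }
    genomes[[ti]] <- genome(tx, do.call(rbind, gene_rows), proteins)
  }
  names(genomes) <- taxon_ids
  truth <- structure(list(cassettes = truth_cassettes,
                          biased_domains = list(), expansions = list(),
                          alignment_entropy_profile = NULL),
                     class = "planted_truth")
  list(genomes = genomes, truth = truth)
}

#' Generate an alignment with a planted per-column entropy profile
#'
#' Conserved columns repeat a single residue (entropy 0); diversified
#' columns draw uniformly from `k` residues, so column entropy approaches
#' `log2(k)` bits as rows grow.
#'
#' @param n_rows Number of sequences (>= 2).
#' @param profile Character vector over `{"conserved", "diversified"}`, one
#'   entry per column.
#' @param k Number of residues a diversified column draws from.
#' @param seed Optional integer seed (set for reproducibility).
#' @return An [alignment()].
#' @export
generate_alignment <- function(n_rows, profile, k = 8L, seed = NULL) {
  if (n_rows < 2L) stopf("n_rows must be >= 2")
  if (!all(profile %in% c("conserved", "diversified")))
    stopf("profile entries must be 'conserved' or 'diversified'")
  if (!is.null(seed)) set.seed(seed)
  cols <- vapply(profile, function(cl) {
    if (cl == "conserved") {
      paste(rep(sample(AA20, 1L), n_rows), collapse = "")
    } else {
      alphabet <- sample(AA20, k)
      paste(sample(alphabet, n_rows, replace = TRUE), collapse = "")
    }
  }, character(1))
  mat <- do.call(cbind, strsplit(cols, ""))
  rows <- apply(mat, 1L, paste, collapse = "")
  alignment(sprintf("seq%03d", seq_len(n_rows)), rows)
}

#' Generate an organism-by-family count table with planted expansions
#'
#' Background counts are Poisson(`lambda`); each planted expansion gives one
#' outlier organism `copies` extra proteins spread evenly over `n_families`
#' dedicated families, emulating a lineage-specific expansion of an
#' architecturally diverse repertoire.
#'
#' @param n_org,n_fam Background table dimensions.
#' @param expansion_spec List of `list(organism, n_families, copies)`;
#'   `organism` is an index into the background organisms.
#' @param seed Integer seed.
#' @param lambda Background Poisson mean.
#' @return `list(counts = <matrix>, truth = <list of planted expansions>)`;
#'   the matrix has organism rows and family columns.
#' @export
generate_count_table <- function(n_org, n_fam, expansion_spec = list(),
                                 seed = 1L, lambda = 1) {
  set.seed(seed)
  counts <- matrix(stats::rpois(n_org * n_fam, lambda), nrow = n_org,
                   dimnames = list(sprintf("org%03d", seq_len(n_org)),
                                   sprintf("fam%03d", seq_len(n_fam))))
  truth <- list()
  for (ex in expansion_spec) {
    per_fam <- ex$copies %/% ex$n_families
    new_cols <- matrix(0L, nrow = n_org, ncol = ex$n_families)
    colnames(new_cols) <- sprintf("exp_%s_f%d", rownames(counts)[ex$organism],
                                  seq_len(ex$n_families))
    new_cols[ex$organism, ] <- per_fam
    counts <- cbind(counts, new_cols)
    truth[[length(truth) + 1L]] <- list(
      organism = rownames(counts)[ex$organism],
      families = colnames(new_cols), copies = per_fam * ex$n_families)
  }
  list(counts = counts, truth = truth)
}

#' Generate domain architectures with a planted positional bias
#'
#' Each architecture has `k` domains with `k` drawn from `k_range`; the
#' target domain occupies the N-terminal, internal or C-terminal region
#' with probabilities `position_probs` (internal slots are chosen uniformly
#' among the `k - 2` middle positions). With `position_probs = NULL` the
#' domain is placed uniformly over all `k` slots — the slot-availability
#' null.
#'
#' @param n_arch Number of architectures.
#' @param target_domain Label of the biased domain.
#' @param position_probs `c(N, internal, C)` probabilities, or `NULL` for
#'   the slot-uniform null.
#' @param k_range Integer range of architecture lengths (>= 2).
#' @param seed Optional seed.
#' @return List of character vectors (architectures); filler domains are
#'   unique so all architectures are distinct.
#' @export
generate_architectures <- function(n_arch, target_domain = "X",
                                   position_probs = NULL,
                                   k_range = c(2L, 5L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_arch), function(i) {
    k <- sample_range(k_range[1], k_range[2])
    if (is.null(position_probs)) {
      slot <- sample(k, 1L)
    } else {
      region <- sample(3L, 1L, prob = position_probs)
      slot <- switch(region, 1L, if (k > 2L) sample(2:(k - 1L), 1L) else
                       sample(c(1L, k), 1L), k)
    }
    arch <- sprintf("FILL_%d_%d", i, seq_len(k))
    arch[slot] <- target_domain
    arch
  })
}

#' Generate homologous protein families at a fixed divergence
#'
#' Each family is a set of mutated copies of a random ancestor (see
#' [mutate_sequence()]); membership is returned for clustering benchmarks.
#'
#' @param n_fam Number of families.
#' @param n_members Members per family.
#' @param divergence Per-site substitution probability from the ancestor.
#' @param len_range Ancestor length range (aa).
#' @param seed Optional integer seed.
#' @return `list(sequences = <named character>, families = <named character:
#'   member id -> family id>)`.
#' @export
generate_protein_families <- function(n_fam, n_members, divergence,
                                      len_range = c(150L, 250L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- character()
  fams <- character()
  for (f in seq_len(n_fam)) {
    anc <- random_protein_seq(sample_range(len_range[1], len_range[2]))
    for (m in seq_len(n_members)) {
      id <- sprintf("f%02d_m%02d", f, m)
      seqs[id] <- mutate_sequence(anc, divergence)
      fams[id] <- sprintf("f%02d", f)
    }
  }
  list(sequences = seqs, families = fams)
}
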
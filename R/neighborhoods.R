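#' Extract gene neighborhoods around anchor genes
#'
#' One neighborhood per gene matched by the anchor predicate: the window of
#' up to `window` genes on each side of the anchor on its replicon,
#' truncated at replicon ends (no wraparound).
#'
#' @param gnm A [genome()].
#' @param anchor Either a character vector of domain labels (a gene anchors
#'   when its protein's architecture contains any of them) or a predicate
#'   `function(gene_row, protein)` returning `TRUE`/`FALSE`.
#' @param window Genes on each side (>= 1).
#' @return List of `neighborhood` objects, each with the anchor gene id,
#'   taxon id, phylum, and a `members` gene data frame (contiguous on one
#'   replicon, sorted by start, anchor included).
#' @export
extract_neighborhoods <- function(gnm, anchor, window = 2L) {
  stopifnot(inherits(gnm, "genome"))
  if (window < 1L) stopf("window must be >= 1")
  pred <- if (is.character(anchor)) {
    function(gene_row, prot)
      !is.null(prot) && length(intersect(prot$architecture, anchor)) > 0L
  } else anchor
  out <- list()
  genes <- gnm$genes
  for (rep in unique(genes$replicon_id)) {
    gr <- genes[genes$replicon_id == rep, , drop = FALSE]
    for (i in seq_len(nrow(gr))) {
      prot <- if (is.na(gr$protein_id[i])) NULL else gnm$proteins[[gr$protein_id[i]]]
      if (!isTRUE(pred(gr[i, ], prot))) next
      lo <- max(1L, i - window)
      hi <- min(nrow(gr), i + window)
      out[[length(out) + 1L]] <- structure(
        list(anchor = gr$gene_id[i], taxon_id = gnm$taxon$taxon_id,
             phylum = gnm$taxon$phylum, window = as.integer(window),
             members = gr[lo:hi, , drop = FALSE]),
        class = "neighborhood")
    }
  }
  out
}

#' Apply the distance and directionality validity filters
#'
#' Members are trimmed outward from the anchor: walking away from it in
#' each direction, retention stops at the first gene whose intergenic gap
#' to the previously retained gene exceeds `max_gap_nt` (inclusive `<=`
#' comparison; overlapping genes, with negative gaps, are always kept) or,
#' when `require_codirectional`, whose strand differs from the anchor's.
#'
#' @param neigh A neighborhood from [extract_neighborhoods()].
#' @param max_gap_nt Maximum tolerated intergenic gap (default 50 nt).
#' @param require_codirectional Apply the strand filter (default `TRUE`).
#' @return The trimmed neighborhood, with a `filter_flags` field recording,
#'   per original member, whether it was kept and which filter removed it.
#' @export
apply_validity_filters <- function(neigh, max_gap_nt = 50L,
                                   require_codirectional = TRUE) {
  stopifnot(inherits(neigh, "neighborhood"))
  if (max_gap_nt < 0L) stopf("max_gap_nt must be >= 0")
  m <- neigh$members
  ai <- which(m$gene_id == neigh$anchor)
  keep <- logical(nrow(m))
  why <- rep(NA_character_, nrow(m))
  keep[ai] <- TRUE
  astrand <- m$strand[ai]
  for (dir in c(-1L, 1L)) {
    prev <- ai
    i <- ai + dir
    while (i >= 1L && i <= nrow(m)) {
      gap <- if (dir > 0L) intergenic_gap(m$end[prev], m$start[i]) else
        intergenic_gap(m$end[i], m$start[prev])
      if (gap > max_gap_nt) { why[i] <- "distance"; break }
      if (require_codirectional && m$strand[i] != astrand) {
        why[i] <- "directionality"; break
      }
      keep[i] <- TRUE
      prev <- i
      i <- i + dir
    }
    while (i >= 1L && i <= nrow(m)) {  # genes beyond the break point
      if (is.na(why[i])) why[i] <- "beyond_break"
      i <- i + dir
    }
  }
  flags <- data.frame(gene_id = m$gene_id, kept = keep, removed_by = why,
                      stringsAsFactors = FALSE)
  neigh$members <- m[keep, , drop = FALSE]
  neigh$filter_flags <- flags
  neigh
}

#' Identify conserved neighborhood groups across taxa
#'
#' Pools the proteins of all neighborhood members, clusters them into
#' families with [cluster_sequences()], and groups neighborhoods: two
#' neighborhoods are linked when their anchors' proteins share a cluster
#' and they share at least `min_shared_flanks` additional flanking family;
#' groups are the connected components of that relation. Groups whose
#' member taxa span fewer than `min_phyla` distinct phyla are discarded
#' (the phylum-spread filter); filter provenance is recorded per group.
#'
#' @param neighborhoods List of (typically filter-trimmed) neighborhoods
#'   across several genomes.
#' @param genomes Named list of the source [genome()] objects (for protein
#'   sequences and phyla).
#' @param L,S Clustering thresholds; the family-detection preset is the
#'   default.
#' @param min_phyla Minimum distinct phyla per reported group (default 2).
#' @param min_shared_flanks Minimum shared non-anchor families linking two
#'   neighborhoods (default 1).
#' @return List of `conserved_group` objects: member neighborhoods,
#'   `family_assignment` (gene id -> cluster id), `phyla`, `taxa`, and
#'   `filter_flags`.
#' @export
find_conserved_groups <- function(neighborhoods, genomes, L = 0.6, S = 0.8,
                                  min_phyla = 2L, min_shared_flanks = 1L) {
  if (!length(neighborhoods)) return(list())
  prot_of_gene <- character()
  seqs <- character()
  for (nb in neighborhoods) {
    gnm <- genomes[[nb$taxon_id]]
    if (is.null(gnm)) stopf("no genome provided for taxon %s", nb$taxon_id)
    for (i in seq_len(nrow(nb$members))) {
      gid <- nb$members$gene_id[i]
      pid <- nb$members$protein_id[i]
      if (is.na(pid)) next
      p <- gnm$proteins[[pid]]
      if (is.null(p) || is.na(p$sequence))
        stopf("neighborhood anchored at %s: member %s lacks a protein sequence",
              nb$anchor, gid)
      prot_of_gene[gid] <- pid
      seqs[pid] <- p$sequence
    }
  }
  clustering <- cluster_sequences(seqs, L = L, S = S)
  fam_of_gene <- clustering$assignment[prot_of_gene]
  names(fam_of_gene) <- names(prot_of_gene)

  n <- length(neighborhoods)
  anchor_fam <- vapply(neighborhoods, function(nb)
    fam_of_gene[[nb$anchor]], integer(1))
  flank_fams <- lapply(neighborhoods, function(nb) {
    g <- setdiff(nb$members$gene_id, nb$anchor)
    unique(unname(fam_of_gene[g]))
  })
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (n > 1L) {
    edges <- integer(0)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (anchor_fam[i] != anchor_fam[j]) next
      shared <- length(intersect(flank_fams[[i]], flank_fams[[j]]))
      if (shared >= min_shared_flanks) edges <- c(edges, i, j)
    }
    if (length(edges)) g <- igraph::add_edges(g, edges)
  }
  comp <- igraph::components(g)$membership
  groups <- list()
  for (k in sort(unique(comp))) {
    idx <- which(comp == k)
    if (length(idx) < 2L) next  # a lone neighborhood is not conservation
    members <- neighborhoods[idx]
    phyla <- sort(unique(vapply(members, `[[`, character(1), "phylum")))
    taxa <- vapply(members, `[[`, character(1), "taxon_id")
    flags <- list(distance_directionality = "applied upstream",
                  phyla_count = length(phyla),
                  passes_phylum_filter = length(phyla) >= min_phyla)
    if (length(phyla) < min_phyla) next
    gene_ids <- unlist(lapply(members, function(nb) nb$members$gene_id))
    groups[[length(groups) + 1L]] <- structure(
      list(member_neighborhoods = members,
           anchor_family = anchor_fam[idx[1L]],
           family_assignment = fam_of_gene[gene_ids],
           phyla = phyla, taxa = taxa, filter_flags = flags),
      class = "conserved_group")
  }
  groups
}

#' Score recovery of planted cassettes by conserved-group detection
#'
#' A planted cassette counts as recovered when some reported group's
#' anchors include the cassette's planted anchor genes in every carrier;
#' a reported group is a true positive when all of its anchors are planted
#' genes of one cassette.
#'
#' @param groups Output of [find_conserved_groups()].
#' @param truth The `planted_truth` from [generate_genomes()].
#' @return `list(recall, precision, n_groups)`; precision is `NA` when no
#'   group was reported.
#' @export
evaluate_recovery <- function(groups, truth) {
  planted_gene_sets <- lapply(truth$cassettes, function(cs)
    unlist(lapply(cs$inserted_genes, unname)))
  anchor_sets <- lapply(groups, function(gr)
    vapply(gr$member_neighborhoods, `[[`, character(1), "anchor"))
  anchor_gene_sets <- lapply(truth$cassettes, function(cs)
    vapply(cs$inserted_genes, function(v) unname(v[cs$families[1L]]),
           character(1)))
  recovered <- vapply(anchor_gene_sets, function(anchors)
    any(vapply(anchor_sets, function(a) all(anchors %in% a), logical(1))),
    logical(1))
  tp <- vapply(anchor_sets, function(a)
    any(vapply(planted_gene_sets, function(p) all(a %in% p), logical(1))),
    logical(1))
  list(recall = if (length(recovered)) mean(recovered) else NA_real_,
       precision = if (length(tp)) mean(tp) else NA_real_,
       n_groups = length(groups))
}
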
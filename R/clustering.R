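#' Pairwise alignment score summary for the clustering contract
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62 and affine gap costs
#' (open 11, extend 1). Because BLOSUM62 entries are log-odds in half-bit
#' units, `score / 2` converts to bits; the reported `score_density` is
#' bits per gapless aligned column. `coverage` is the number of gapless
#' aligned columns divided by the longer sequence length, so it lies in
#' `[0, 1]` and equals 1 for equal-length, gap-free alignments.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @return `list(identity_fraction, score_density, coverage, aligned_columns)`;
#'   symmetric in argument order.
#' @export
pair_score <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stopf("empty sequence")
  ps <- pair_scores_one_subject(seq_a, seq_b)
  lapply(ps, `[`, 1L)
}

# vectorized workhorse: many patterns against one subject
pair_scores_one_subject <- function(patterns, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  cols <- nm + nmm  # gapless aligned columns
  longer <- pmax(nchar(patterns), nchar(subject))
  list(identity_fraction = ifelse(cols > 0, nm / cols, 0),
       score_density = ifelse(cols > 0, Biostrings::score(aln) / (2 * cols), -Inf),
       coverage = cols / longer,
       aligned_columns = cols)
}

#' Single-linkage protein clustering by coverage and score density
#'
#' Reimplements the BLASTCLUST contract: two sequences are linked when their
#' pairwise `coverage >= L` and `score_density >= S` (see [pair_score()]);
#' clusters are the connected components of the link graph (single
#' linkage). Two presets are provided: near-identical clustering
#' `(L = 0.9, S = 1.89)` and family detection `(L = 0.6, S = 0.8)`. The
#' numeric S scale is this package's defined bits-per-column density, a
#' documented stand-in for BLASTCLUST's internal normalization.
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param L Length-coverage threshold in `[0, 1]`.
#' @param S Score-density threshold (bits per aligned column), >= 0.
#' @return An object of class `protein_clustering`:
#'   `list(clusters = <list of member-id vectors>, assignment = <named
#'   integer vector>, parameters = c(L, S))`. Clusters are ordered by their
#'   smallest member id and members sorted within each cluster, so the
#'   output is invariant to input order.
#' @export
cluster_sequences <- function(sequences, L = 0.9, S = 1.89) {
  if (L < 0 || L > 1) stopf("L must lie in [0, 1]")
  if (S < 0) stopf("S must be >= 0")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stopf("sequences must be uniquely named")
  ids <- sort(names(sequences))
  sequences <- sequences[ids]
  n <- length(ids)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (n > 1L) {
    edges <- character(0)
    for (j in 2:n) {
      ps <- pair_scores_one_subject(unname(sequences[1:(j - 1L)]), sequences[[j]])
      hit <- which(ps$coverage >= L & ps$score_density >= S)
      if (length(hit)) edges <- c(edges, rbind(ids[hit], ids[j]))
    }
    if (length(edges)) g <- igraph::add_edges(g, edges)
  }
  comp <- igraph::components(g)
  members <- split(ids, comp$membership[ids])
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[`, character(1), 1L))]
  names(members) <- NULL
  assignment <- integer(n)
  names(assignment) <- ids
  for (k in seq_along(members)) assignment[members[[k]]] <- k
  structure(list(clusters = members, assignment = assignment,
                 parameters = c(L = L, S = S)),
            class = "protein_clustering")
}

#' @export
print.protein_clustering <- function(x, ...) {
  cat(sprintf("<protein_clustering> %d sequence(s) in %d cluster(s) (L=%g, S=%g)\n",
              length(x$assignment), length(x$clusters),
              x$parameters["L"], x$parameters["S"]))
  invisible(x)
}

#' Write a clustering as a BLASTCLUST-style file
#'
#' One cluster per line, member ids whitespace-separated.
#' @param clustering A [cluster_sequences()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clustering, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(clustering$clusters, paste, character(1), collapse = " "),
             con, sep = "\n")
  invisible(path)
}

#' Purity and completeness of a clustering against known families
#'
#' @param clustering A [cluster_sequences()] result.
#' @param families Named character vector: sequence id -> true family label.
#' @return `list(purity, completeness)`. Purity is the fraction of clusters
#'   whose members all share one family; completeness the mean, over
#'   families, of the largest fraction of the family kept in one cluster.
#' @export
clustering_quality <- function(clustering, families) {
  fam_of <- families[names(clustering$assignment)]
  purity <- mean(vapply(clustering$clusters, function(m)
    length(unique(fam_of[m])) == 1L, logical(1)))
  completeness <- mean(vapply(split(names(fam_of), fam_of), function(m) {
    max(table(clustering$assignment[m])) / length(m)
  }, numeric(1)))
  list(purity = purity, completeness = completeness)
}
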
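#' Taxon metadata record
#'
#' A taxon with its phylum label and a tri-state multicellularity flag. The
#' flag is stored as a logical (`TRUE`/`FALSE`/`NA`) and is never silently
#' collapsed to a boolean: statistics that need a binary trait must drop
#' unknowns explicitly (see [trait_counts()]).
#'
#' @param taxon_id Unique identifier (opaque string).
#' @param phylum Non-empty phylum label.
#' @param name Display name; defaults to `taxon_id`.
#' @param multicellular `TRUE`, `FALSE` or `NA` (unknown).
#' @return An object of class `taxon_record`.
#' @export
taxon_record <- function(taxon_id, phylum, name = taxon_id, multicellular = NA) {
  if (!is.character(taxon_id) || length(taxon_id) != 1L || !nzchar(taxon_id))
    stopf("taxon_id must be a non-empty string")
  if (!is.character(phylum) || length(phylum) != 1L || !nzchar(phylum))
    stopf("phylum must be a non-empty string")
  if (!is.logical(multicellular) || length(multicellular) != 1L)
    stopf("multicellular must be TRUE, FALSE or NA (logical)")
  structure(list(taxon_id = taxon_id, name = name, phylum = phylum,
                 multicellular = multicellular),
            class = "taxon_record")
}

#' Protein with an ordered domain architecture
#'
#' @param protein_id Identifier string.
#' @param sequence Amino-acid string over the 20-letter alphabet plus `X`,
#'   or `NA` when unknown.
#' @param architecture Character vector of domain labels, N- to C-terminal;
#'   may be empty. Labels are free strings; no ontology is enforced.
#' @return An object of class `protein`.
#' @export
protein <- function(protein_id, sequence = NA_character_,
                    architecture = character()) {
  if (!is.character(protein_id) || length(protein_id) != 1L || !nzchar(protein_id))
    stopf("protein_id must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L)
    stopf("sequence must be a single string or NA")
  if (!is.na(sequence)) {
    bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c(AA20, "X"))
    if (length(bad))
      stopf("protein %s: illegal residue(s) %s", protein_id,
            paste(bad, collapse = ","))
  }
  if (!is.character(architecture)) stopf("architecture must be character")
  structure(list(protein_id = protein_id, sequence = sequence,
                 architecture = architecture),
            class = "protein")
}

#' Genome: taxon, gene table and protein map
#'
#' Genes are held as a data frame (`gene_id`, `replicon_id`, `start`, `end`,
#' `strand`, `protein_id`) and are always stored sorted by
#' `(replicon_id, start)` regardless of input order. Coordinates are 1-based
#' inclusive (GenBank convention). Overlapping genes are permitted but
#' flagged in the `"overlapping"` attribute.
#'
#' @param taxon A [taxon_record()].
#' @param genes Data frame with the columns above. `protein_id` may be `NA`
#'   for non-coding genes.
#' @param proteins Named list of [protein()] objects; every non-`NA`
#'   `protein_id` in `genes` must resolve.
#' @return An object of class `genome`.
#' @export
genome <- function(taxon, genes, proteins = list()) {
  if (!inherits(taxon, "taxon_record")) stopf("taxon must be a taxon_record")
  need <- c("gene_id", "replicon_id", "start", "end", "strand", "protein_id")
  if (!is.data.frame(genes) || !all(need %in% names(genes)))
    stopf("genes must be a data.frame with columns %s", paste(need, collapse = ", "))
  genes <- genes[, need]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id))
      stopf("duplicate gene_id: %s",
            paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ","))
    if (any(genes$start < 1L) || any(genes$end < genes$start))
      stopf("gene coordinates must satisfy 1 <= start <= end")
    if (!all(genes$strand %in% c("+", "-")))
      stopf("strand must be '+' or '-'")
    coding <- !is.na(genes$protein_id)
    missing <- setdiff(genes$protein_id[coding], names(proteins))
    if (length(missing))
      stopf("protein_id(s) not in protein map: %s", paste(missing, collapse = ","))
    genes <- genes[order(genes$replicon_id, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
  }
  g <- structure(list(taxon = taxon, genes = genes, proteins = proteins),
                 class = "genome")
  attr(g, "overlapping") <- overlapping_gene_ids(genes)
  g
}

# gene_ids overlapping their predecessor on the same replicon (sorted order)
overlapping_gene_ids <- function(genes) {
  out <- character()
  for (rep in unique(genes$replicon_id)) {
    gr <- genes[genes$replicon_id == rep, , drop = FALSE]
    if (nrow(gr) < 2L) next
    ov <- which(gr$start[-1L] <= gr$end[-nrow(gr)])
    if (length(ov)) out <- c(out, gr$gene_id[ov + 1L])
  }
  out
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s (%s), %d gene(s) on %d replicon(s), %d protein(s)\n",
              x$taxon$taxon_id, x$taxon$phylum, nrow(x$genes),
              length(unique(x$genes$replicon_id)), length(x$proteins)))
  invisible(x)
}

#' Intergenic gap between consecutive genes
#'
#' `next.start - prev.end - 1` under 1-based inclusive coordinates; negative
#' for overlapping genes.
#' @param prev_end,next_start Integer coordinates.
#' @return Integer gap in nucleotides.
#' @export
intergenic_gap <- function(prev_end, next_start) {
  as.integer(next_start) - as.integer(prev_end) - 1L
}

parse_multicellular <- function(x, row = NA_integer_) {
  x <- tolower(trimws(x))
  if (x %in% c("true", "t")) return(TRUE)
  if (x %in% c("false", "f")) return(FALSE)
  if (x %in% c("na", "")) return(NA)
  stopf("row %s: multicellular must be one of true/false/NA, got '%s'", row, x)
}

ANNOT_COLS <- c("taxon_id", "phylum", "multicellular", "replicon_id",
                "gene_id", "start", "end", "strand", "protein_id",
                "architecture")

#' Read a genome from the annotation-table dialect
#'
#' Tab-separated, UTF-8, one gene per row, header columns exactly
#' `taxon_id, phylum, multicellular, replicon_id, gene_id, start, end,
#' strand, protein_id, architecture` plus an optional `sequence` column.
#' `architecture` is a `'+'`-joined list of domain labels (empty allowed);
#' `multicellular` is `true`/`false`/`NA`.
#'
#' @param path File path.
#' @return A [genome()].
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           check.names = FALSE, na.strings = character())
  has_seq <- "sequence" %in% names(tab)
  want <- if (has_seq) c(ANNOT_COLS, "sequence") else ANNOT_COLS
  if (!identical(names(tab), want))
    stopf("annotation table %s: header must be exactly: %s", path,
          paste(want, collapse = ", "))
  if (nrow(tab) == 0L)
    stopf("annotation table %s: no rows (taxon metadata unavailable)", path)
  if (length(unique(tab$taxon_id)) != 1L)
    stopf("annotation table %s: multiple taxon_id values; one genome per file", path)

  for (i in seq_len(nrow(tab))) {
    st <- suppressWarnings(as.integer(tab$start[i]))
    en <- suppressWarnings(as.integer(tab$end[i]))
    if (is.na(st) || is.na(en) || en < st || st < 1L)
      stopf("row %d: bad coordinates start=%s end=%s", i, tab$start[i], tab$end[i])
    if (!tab$strand[i] %in% c("+", "-"))
      stopf("row %d: unknown strand symbol '%s'", i, tab$strand[i])
  }
  if (anyDuplicated(tab$gene_id))
    stopf("row %d: duplicate gene_id '%s'",
          which(duplicated(tab$gene_id))[1L],
          tab$gene_id[duplicated(tab$gene_id)][1L])

  taxon <- taxon_record(tab$taxon_id[1L], tab$phylum[1L],
                        multicellular = parse_multicellular(tab$multicellular[1L], 1L))
  proteins <- list()
  for (i in seq_len(nrow(tab))) {
    pid <- tab$protein_id[i]
    if (!nzchar(pid)) next
    arch <- if (nzchar(tab$architecture[i]))
      strsplit(tab$architecture[i], "+", fixed = TRUE)[[1]] else character()
    seq <- if (has_seq && nzchar(tab$sequence[i])) tab$sequence[i] else NA_character_
    proteins[[pid]] <- protein(pid, seq, arch)
  }
  genes <- data.frame(gene_id = tab$gene_id, replicon_id = tab$replicon_id,
                      start = as.integer(tab$start), end = as.integer(tab$end),
                      strand = tab$strand,
                      protein_id = ifelse(nzchar(tab$protein_id),
                                          tab$protein_id, NA_character_),
                      stringsAsFactors = FALSE)
  genome(taxon, genes, proteins)
}

#' Write a genome in the annotation-table dialect
#'
#' Round-trip safe: `read_annotation_table(write_annotation_table(g))`
#' reproduces `g` field for field. A `sequence` column is emitted when any
#' protein carries a sequence. An empty genome yields a header-only file.
#'
#' @param gnm A [genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(gnm, path) {
  stopifnot(inherits(gnm, "genome"))
  tx <- gnm$taxon
  mc <- if (is.na(tx$multicellular)) "NA" else tolower(as.character(tx$multicellular))
  genes <- gnm$genes
  has_seq <- any(vapply(gnm$proteins, function(p) !is.na(p$sequence), logical(1)))
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    pid <- genes$protein_id[i]
    arch <- seq <- ""
    if (!is.na(pid)) {
      p <- gnm$proteins[[pid]]
      arch <- paste(p$architecture, collapse = "+")
      if (has_seq) seq <- if (is.na(p$sequence)) "" else p$sequence
    }
    c(tx$taxon_id, tx$phylum, mc, genes$replicon_id[i], genes$gene_id[i],
      as.character(genes$start[i]), as.character(genes$end[i]),
      genes$strand[i], if (is.na(pid)) "" else pid, arch,
      if (has_seq) seq)
  })
  header <- if (has_seq) c(ANNOT_COLS, "sequence") else ANNOT_COLS
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Multiple sequence alignment container
#'
#' @param names Character vector of row names (unique).
#' @param rows Character vector of equal-length aligned strings over the
#'   amino-acid alphabet plus `-` (gap). At least 2 rows and 1 column.
#' @return An object of class `msa`.
#' @export
alignment <- function(names, rows) {
  if (length(names) != length(rows)) stopf("names and rows differ in length")
  if (length(rows) < 2L) stopf("alignment needs >= 2 rows")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stopf("alignment rows differ in length")
  if (w < 1L) stopf("alignment needs >= 1 column")
  structure(list(names = unname(as.character(names)),
                 rows = unname(as.character(rows))), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$rows), nchar(x$rows[1L])))
  invisible(x)
}

#' Read an aligned FASTA file
#' @param path FASTA path (aligned; equal-length rows).
#' @return An [alignment()].
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  alignment(names(ss), as.character(ss))
}

#' Write an alignment as FASTA
#' @param aln An [alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "msa"))
  ss <- Biostrings::AAStringSet(aln$rows)
  names(ss) <- aln$names
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a profile-search hit table
#'
#' TSV with header `query, hit, p_value`. Duplicate (query, hit) rows are
#' allowed (multiple searches) and resolved at network build time.
#'
#' @param path File path.
#' @return Data frame with columns `query`, `hit`, `p_value`.
#' @export
read_hit_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE,
                           colClasses = c("character", "character", "numeric"))
  if (!identical(names(tab), c("query", "hit", "p_value")))
    stopf("hit table %s: header must be query, hit, p_value", path)
  if (any(tab$p_value <= 0 | tab$p_value > 1))
    stopf("hit table %s: p_value must lie in (0, 1]", path)
  tab
}
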
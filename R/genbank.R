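#' Read a GenBank flat file into a genome
#'
#' Minimal flat-file reader for annotation records with CDS features. Each
#' record (LOCUS..//) becomes one replicon of a single [genome()]; the CDS
#' `protein_id` and `translation` qualifiers populate the protein map.
#' `join(...)`/`complement(...)` locations are flattened to
#' (min start, max end) and the strand taken from the outer `complement`
#' flag; partial-end markers (`<`, `>`) are ignored.
#'
#' Phylum and multicellularity are not encoded in GenBank flat files, so the
#' taxon defaults to the ORGANISM name with phylum `"Unknown"` and an
#' unknown multicellularity flag; pass `taxon` to override.
#'
#' @param path GenBank flat-file path.
#' @param taxon Optional [taxon_record()] overriding the derived metadata.
#' @return A [genome()]; records with zero CDS features yield an empty gene
#'   table with a warning.
#' @export
read_genbank <- function(path, taxon = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1L]))
    stopf("%s line 1: not a GenBank flat file (missing LOCUS)", path)

  organism <- NA_character_
  genes <- list()
  proteins <- list()
  replicon <- NA_character_
  in_features <- FALSE
  i <- 1L
  n <- length(lines)
  ordinal <- 0L

  read_feature_block <- function(start) {
    # collect continuation lines (indent > 5) of one feature
    j <- start + 1L
    while (j <= n && grepl("^ {6,}", lines[j]) &&
           !grepl("^ {5}\\S", lines[j]) && !grepl("^\\S", lines[j])) j <- j + 1L
    list(text = lines[start:(j - 1L)], next_i = j)
  }

  while (i <= n) {
    ln <- lines[i]
    if (grepl("^LOCUS", ln)) {
      fields <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(fields) < 2L) stopf("%s line %d: malformed LOCUS line", path, i)
      replicon <- fields[2L]
      in_features <- FALSE
    } else if (grepl("^\\s+ORGANISM", ln)) {
      organism <- trimws(sub("^\\s+ORGANISM\\s+", "", ln))
    } else if (grepl("^FEATURES", ln)) {
      in_features <- TRUE
    } else if (grepl("^(ORIGIN|CONTIG|//)", ln)) {
      in_features <- FALSE
    } else if (in_features && grepl("^ {5}CDS\\s", ln)) {
      blk <- read_feature_block(i)
      feat <- parse_cds_feature(blk$text, path, i)
      ordinal <- ordinal + 1L
      pid <- feat$protein_id
      if (is.na(pid)) {
        pid <- sprintf("%s_%d", feat$locus_tag %||% replicon, ordinal)
        warnf("%s line %d: CDS without protein_id; assigned '%s'", path, i, pid)
      }
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = pid, replicon_id = replicon,
        start = feat$start, end = feat$end, strand = feat$strand,
        protein_id = pid, stringsAsFactors = FALSE)
      proteins[[pid]] <- protein(pid, feat$translation %||% NA_character_)
      i <- blk$next_i
      next
    }
    i <- i + 1L
  }

  if (!length(genes))
    warnf("%s: no CDS features found; genome is empty", path)
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), replicon_id = character(),
               start = integer(), end = integer(), strand = character(),
               protein_id = character(), stringsAsFactors = FALSE)
  if (is.null(taxon)) {
    nm <- if (is.na(organism)) "unknown organism" else organism
    taxon <- taxon_record(nm, "Unknown", multicellular = NA)
  }
  genome(taxon, genes, proteins)
}

# one CDS feature block -> list(start, end, strand, protein_id, translation, locus_tag)
parse_cds_feature <- function(block, path, lineno) {
  loc <- sub("^ {5}CDS\\s+", "", block[1L])
  k <- 2L
  while (k <= length(block) && !grepl("^\\s+/", block[k])) {
    loc <- paste0(loc, trimws(block[k]))
    k <- k + 1L
  }
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
  if (!length(nums))
    stopf("%s line %d: cannot parse CDS location '%s'", path, lineno, loc)
  nums <- as.integer(nums)
  quals <- parse_qualifiers(block[k:length(block)])
  list(start = min(nums), end = max(nums), strand = strand,
       protein_id = quals[["protein_id"]] %||% NA_character_,
       translation = quals[["translation"]],
       locus_tag = quals[["locus_tag"]])
}

parse_qualifiers <- function(lines) {
  out <- list()
  cur_key <- NULL
  for (ln in lines) {
    t <- trimws(ln)
    if (startsWith(t, "/")) {
      m <- regmatches(t, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', t))[[1]]
      if (length(m) == 3L) {
        cur_key <- m[2L]
        out[[cur_key]] <- m[3L]
      } else cur_key <- NULL
    } else if (!is.null(cur_key)) {
      out[[cur_key]] <- paste0(out[[cur_key]], sub('"$', "", t))
    }
  }
  out
}
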
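#' Build a domain-architecture adjacency network
#'
#' Directed graph over domain labels; an edge `d1 -> d2` means `d2`
#' immediately follows `d1` (N- to C-terminal) in some architecture, with
#' weight the number of distinct architectures containing that adjacency.
#' Identical architectures are collapsed before counting when
#' `dedupe = TRUE` (exact label-sequence equality). Single-domain
#' architectures contribute isolated nodes only; tandem repeats produce
#' self-loops.
#'
#' @param architectures Either a list of character vectors (architectures)
#'   or a list of [protein()] objects.
#' @param dedupe Collapse duplicate architectures first (default `TRUE`).
#' @return An [igraph::graph] with edge attribute `weight`.
#' @export
build_architecture_network <- function(architectures, dedupe = TRUE) {
  archs <- lapply(architectures, function(a)
    if (inherits(a, "protein")) a$architecture else a)
  archs <- archs[vapply(archs, length, integer(1)) > 0L]
  if (dedupe) archs <- unique(archs)
  nodes <- sort(unique(unlist(archs)))
  edge_counts <- new.env(parent = emptyenv())
  for (a in archs) {
    if (length(a) < 2L) next
    pairs <- unique(paste(a[-length(a)], a[-1L], sep = "\r"))
    for (p in pairs)
      assign(p, (get0(p, envir = edge_counts) %||% 0L) + 1L, envir = edge_counts)
  }
  keys <- ls(edge_counts)
  g <- igraph::make_empty_graph(n = length(nodes), directed = TRUE)
  igraph::V(g)$name <- nodes
  if (length(keys)) {
    ends <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(ends)),
                           weight = unname(vapply(keys, get, numeric(1),
                                                  envir = edge_counts)))
  }
  g
}

#' Build a profile-search retrieval network
#'
#' Directed graph over profile labels: an edge `query -> hit` is drawn when
#' the hit's p-value is strictly below `p_threshold`; duplicate
#' (query, hit) rows keep the minimum p; edge weight is `-log10(p)`.
#'
#' @param hit_table Data frame with columns `query`, `hit`, `p_value`
#'   (see [read_hit_table()]).
#' @param p_threshold Strict upper bound on p (default `1e-4`).
#' @return An [igraph::graph] with edge attribute `weight`.
#' @export
build_retrieval_network <- function(hit_table, p_threshold = 1e-4) {
  if (any(hit_table$p_value <= 0)) stopf("p_value must be > 0")
  if (any(hit_table$p_value > 1)) stopf("p_value must be <= 1")
  key <- paste(hit_table$query, hit_table$hit, sep = "\r")
  best <- tapply(hit_table$p_value, key, min)
  keep <- best < p_threshold
  nodes <- sort(unique(c(hit_table$query, hit_table$hit)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = TRUE)
  igraph::V(g)$name <- nodes
  if (any(keep)) {
    ends <- do.call(rbind, strsplit(names(best)[keep], "\r", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(ends)),
                           weight = -log10(unname(best[keep])))
  }
  g
}

#' Export a network as GraphML or DOT
#' @param g An igraph graph.
#' @param path Output path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Positional counts of a domain over unique architectures
#'
#' Considers only unique architectures with at least two domains that
#' contain the domain; each occurrence is classified N-terminal (first
#' slot), C-terminal (last slot) or internal. The slot-availability
#' expectation sums, over occurrences, the per-architecture probabilities
#' `(1/k, (k-2)/k, 1/k)` of landing in each region of an architecture of
#' length `k`, normalized by the number of occurrences.
#'
#' @param domain Domain label.
#' @param architectures List of character vectors or [protein()] objects.
#' @return An object of class `positional_counts`:
#'   `list(domain, n_Nterm, n_internal, n_Cterm, slot_expectation)`.
#' @export
positional_counts <- function(domain, architectures) {
  archs <- lapply(architectures, function(a)
    if (inherits(a, "protein")) a$architecture else a)
  archs <- unique(archs)
  archs <- archs[vapply(archs, function(a)
    length(a) >= 2L && domain %in% a, logical(1))]
  if (!length(archs))
    stopf("domain '%s' absent from all multi-domain architectures", domain)
  n <- c(Nterm = 0L, internal = 0L, Cterm = 0L)
  expect <- c(0, 0, 0)
  for (a in archs) {
    k <- length(a)
    occ <- which(a == domain)
    for (slot in occ) {
      pos <- if (slot == 1L) 1L else if (slot == k) 3L else 2L
      n[pos] <- n[pos] + 1L
      expect <- expect + c(1 / k, (k - 2) / k, 1 / k)
    }
  }
  structure(list(domain = domain, n_Nterm = n[["Nterm"]],
                 n_internal = n[["internal"]], n_Cterm = n[["Cterm"]],
                 slot_expectation = expect / sum(n)),
            class = "positional_counts")
}

#' Chi-squared test for positional bias of a domain
#'
#' Pearson chi-squared of the observed (N-terminal, internal, C-terminal)
#' occurrence counts against the slot-availability null (each occurrence
#' uniform over its architecture's slots), df = 2. A naive uniform-thirds
#' null is available via `null = "uniform_thirds"`.
#'
#' @param counts A [positional_counts()] result.
#' @param null `"slot_availability"` (default) or `"uniform_thirds"`.
#' @return `list(chi2, df = 2, p, observed, expected)`.
#' @export
positional_bias_test <- function(counts,
                                 null = c("slot_availability", "uniform_thirds")) {
  null <- match.arg(null)
  obs <- c(counts$n_Nterm, counts$n_internal, counts$n_Cterm)
  total <- sum(obs)
  if (total < 1L) stopf("no occurrences to test")
  prop <- if (null == "slot_availability") counts$slot_expectation else rep(1 / 3, 3)
  expected <- total * prop
  if (any(expected == 0 & obs > 0))
    stopf("expected count 0 with nonzero observed; merge categories")
  use <- expected > 0
  chi2 <- sum((obs[use] - expected[use])^2 / expected[use])
  list(chi2 = chi2, df = 2L,
       p = stats::pchisq(chi2, df = 2L, lower.tail = FALSE),
       observed = obs, expected = expected)
}
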
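#' Count inputs for the trait-enrichment test
#'
#' Builds the (q, m, n, k) inputs of the hypergeometric test from a carrier
#' list and a taxon table with a tri-state trait: `q` trait-positive
#' carriers, `m` trait-positive organisms overall, `n` trait-negative
#' organisms overall, `k` carriers overall. Organisms with unknown trait are
#' dropped from all four counts consistently and reported in the audit.
#'
#' @param carriers Character vector of carrier taxon ids (or a list of
#'   [genome()] objects).
#' @param taxa Either a list of [taxon_record()] objects or a data frame
#'   with columns `taxon_id` and `multicellular` (logical, `NA` = unknown).
#' @return An object of class `enrichment_input`: `list(q, m, n, k,
#'   excluded_unknown, excluded_unknown_carriers)`.
#' @export
trait_counts <- function(carriers, taxa) {
  if (is.list(carriers) && length(carriers) && inherits(carriers[[1]], "genome"))
    carriers <- vapply(carriers, function(g) g$taxon$taxon_id, character(1))
  if (is.list(taxa) && !is.data.frame(taxa))
    taxa <- data.frame(
      taxon_id = vapply(taxa, `[[`, character(1), "taxon_id"),
      multicellular = vapply(taxa, `[[`, logical(1), "multicellular"),
      stringsAsFactors = FALSE)
  if (anyDuplicated(taxa$taxon_id)) stopf("duplicate taxon_id in taxon table")
  missing <- setdiff(carriers, taxa$taxon_id)
  if (length(missing))
    stopf("carrier taxa absent from table: %s", paste(missing, collapse = ","))
  if (!length(carriers)) stopf("zero carriers: nothing to test")
  trait <- taxa$multicellular
  names(trait) <- taxa$taxon_id
  known <- !is.na(trait)
  carriers <- unique(carriers)
  carriers_known <- carriers[known[carriers]]
  inp <- structure(list(q = sum(trait[carriers_known]),
                        m = sum(trait[known]),
                        n = sum(!trait[known]),
                        k = length(carriers_known),
                        excluded_unknown = sum(!known),
                        excluded_unknown_carriers =
                          length(carriers) - length(carriers_known)),
                   class = "enrichment_input")
  validate_enrichment_input(inp)
  inp
}

validate_enrichment_input <- function(x) {
  with(x, {
    if (q < 0 || m < 0 || n < 0 || k < 0) stopf("counts must be non-negative")
    if (q > min(m, k)) stopf("q must be <= min(m, k)")
    if (k > m + n) stopf("k must be <= m + n")
  })
  invisible(x)
}

#' Enrichment-input constructor from raw counts
#' @param q Trait-positive carriers.
#' @param m Trait-positive organisms in the background.
#' @param n Trait-negative organisms in the background.
#' @param k Total carriers.
#' @return An `enrichment_input`.
#' @export
enrichment_input <- function(q, m, n, k) {
  validate_enrichment_input(structure(
    list(q = as.integer(q), m = as.integer(m), n = as.integer(n),
         k = as.integer(k), excluded_unknown = 0L,
         excluded_unknown_carriers = 0L),
    class = "enrichment_input"))
}

# upper-tail probabilities P(X >= q) for every q in 0..min(m,k),
# as exact log-space summation of hypergeometric pmf terms
hypergeom_upper_tail_all <- function(m, n, k) {
  hi <- min(m, k)
  lo <- max(0L, k - n)
  logp <- rep(-Inf, hi + 1L)
  logp[(lo:hi) + 1L] <- stats::dhyper(lo:hi, m, n, k, log = TRUE)
  # reverse cumulative logsumexp
  out <- numeric(hi + 1L)
  acc <- -Inf
  for (q in hi:0) {
    acc <- logsumexp(c(acc, logp[q + 1L]))
    out[q + 1L] <- acc
  }
  pmin(exp(out), 1)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= q)` for `X ~ Hypergeometric(m, n, k)`: the probability of
#' observing at least `q` trait-positive organisms among `k` carriers drawn
#' without replacement from `m` positive and `n` negative organisms. The
#' observed value is included in the tail (the
#' `phyper(q - 1, lower.tail = FALSE)` convention). Computed by exact
#' summation of pmf terms in log space, stable up to `m + n` in the tens of
#' thousands.
#'
#' @param input An `enrichment_input` (see [trait_counts()],
#'   [enrichment_input()]).
#' @return p-value in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(input) {
  validate_enrichment_input(input)
  hypergeom_upper_tail_all(input$m, input$n, input$k)[input$q + 1L]
}
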
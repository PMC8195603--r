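#' Polydomain score per organism
#'
#' For a count table `c(o, p)` of proteins of family `p` in organism `o`,
#' each family's global log-frequency is
#' `f(p) = log2( colsum(p) / grand total )` and the polydomain score of an
#' organism is `PD(o) = sum_p c(o, p) * (f(p) - fbar)` with `fbar` the
#' unweighted mean of `f(p)` over families. Organisms with lineage-specific
#' expansions of globally prevalent, architecturally diverse families score
#' as high-|PD| outliers. Families with an all-zero column are dropped
#' before scoring (their log-frequency is undefined); dropping them leaves
#' all scores unchanged.
#'
#' @param counts Non-negative integer matrix, organisms in rows, families
#'   in columns (dimnames used for ids).
#' @param f Optional precomputed named `f(p)` vector (and its mean is then
#'   recomputed from it); used for scale-property analyses where `f` is
#'   held fixed while rows change.
#' @return An object of class `pds_result`: `list(pd = <named numeric>,
#'   f = <named numeric>, f_bar = <numeric>)`, with `pd` in input row
#'   order.
#' @export
compute_pds <- function(counts, f = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("negative counts")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("org%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("fam%03d", seq_len(ncol(counts)))
  if (is.null(f)) {
    keep <- colSums(counts) > 0
    if (!any(keep)) stopf("zero grand total: no non-empty family columns")
    counts <- counts[, keep, drop = FALSE]
    f <- log2(colSums(counts) / sum(counts))
  } else {
    if (!all(colnames(counts) %in% names(f)))
      stopf("precomputed f missing families: %s",
            paste(setdiff(colnames(counts), names(f)), collapse = ","))
    f <- f[colnames(counts)]
  }
  f_bar <- mean(f)
  pd <- drop(counts %*% (f - f_bar))
  structure(list(pd = pd, f = f, f_bar = f_bar), class = "pds_result")
}

#' @export
print.pds_result <- function(x, ...) {
  cat(sprintf("<pds_result> %d organism(s), %d family(ies), f_bar = %.4f\n",
              length(x$pd), length(x$f), x$f_bar))
  invisible(x)
}

#' Write polydomain scores and family frequencies as TSV
#' @param result A [compute_pds()] result.
#' @param path Output path for the per-organism scores (sorted descending);
#'   a companion `<path>.families.tsv` holds the `f(p)` table.
#' @return `path`, invisibly.
#' @export
write_pds <- function(result, path) {
  ord <- order(result$pd, decreasing = TRUE)
  df <- data.frame(organism = names(result$pd)[ord],
                   pds = unname(result$pd)[ord])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  fam <- data.frame(family = names(result$f), f = unname(result$f))
  utils::write.table(fam, paste0(path, ".families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
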
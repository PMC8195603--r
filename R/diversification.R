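#' Shannon entropy of one alignment column
#'
#' `H = -sum_i P_i log2 P_i` over the residue types observed in the column,
#' with `P_i` the fraction of non-gap symbols of type `i` (gaps are excluded
#' from the denominator) and `0 * log 0 = 0`.
#'
#' @param column Character vector of single-character symbols (residues and
#'   `-` gaps).
#' @return Entropy in bits, in `[0, log2(20)]`.
#' @export
column_entropy <- function(column) {
  res <- column[column != "-"]
  if (!length(res)) stopf("column is entirely gaps; exclude it upstream")
  p <- tabulate(factor(res)) / length(res)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-column entropy profile of an alignment
#'
#' Columns whose gap fraction exceeds `max_gap_fraction` are excluded;
#' entropy is computed on the retained columns.
#'
#' @param aln An [alignment()].
#' @param max_gap_fraction Maximum tolerated gap fraction per column
#'   (default 0.5).
#' @param alignment_id Optional identifier carried into the profile for
#'   reporting.
#' @return An object of class `entropy_profile`: `list(H = <numeric>,
#'   columns_used = <integer indices>, alignment_id)`.
#' @export
entropy_profile <- function(aln, max_gap_fraction = 0.5,
                            alignment_id = NA_character_) {
  stopifnot(inherits(aln, "msa"))
  mat <- do.call(rbind, strsplit(aln$rows, ""))
  gap_frac <- colMeans(mat == "-")
  keep <- which(gap_frac <= max_gap_fraction)
  if (!length(keep)) stopf("no columns retained at gap fraction <= %g",
                           max_gap_fraction)
  H <- apply(mat[, keep, drop = FALSE], 2L, column_entropy)
  structure(list(H = unname(H), columns_used = keep,
                 alignment_id = alignment_id),
            class = "entropy_profile")
}

#' Welch test for a difference in mean column entropy
#'
#' Two-sided Welch (unequal-variance) t-test treating alignment columns as
#' independent observations; used to call diversifying families whose mean
#' column entropy exceeds that of a conserved reference.
#'
#' @param profile_a,profile_b [entropy_profile()] objects with >= 2 columns
#'   each.
#' @return `list(t, p, mean_a, mean_b)`. Swapping the arguments flips the
#'   sign of `t` and leaves `p` unchanged.
#' @export
mean_entropy_test <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "entropy_profile"),
            inherits(profile_b, "entropy_profile"))
  if (length(profile_a$H) < 2L || length(profile_b$H) < 2L)
    stopf("each profile needs >= 2 columns")
  if (stats::var(profile_a$H) == 0 && stats::var(profile_b$H) == 0) {
    # degenerate: constant entropies; equal means => no evidence
    eq <- isTRUE(all.equal(mean(profile_a$H), mean(profile_b$H)))
    return(list(t = if (eq) 0 else Inf * sign(mean(profile_a$H) - mean(profile_b$H)),
                p = if (eq) 1 else 0,
                mean_a = mean(profile_a$H), mean_b = mean(profile_b$H)))
  }
  tt <- stats::t.test(profile_a$H, profile_b$H, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_a = mean(profile_a$H), mean_b = mean(profile_b$H))
}
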
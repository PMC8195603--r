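#' Convert a structure-similarity Z-score matrix to distances
#'
#' `d(i, j) = Z_max - z(i, j)` for `i != j`, where `Z_max` is the largest
#' off-diagonal Z in the matrix, and `d(i, i) = 0`; a linear, monotone,
#' bounded transform (the pair with the highest similarity sits at distance
#' 0). Set `transform = "reciprocal"` for `d = 1/z` instead. With
#' `normalize = TRUE`, Z-scores are first scaled by the geometric mean of
#' the two self-Z diagonal entries.
#'
#' @param z Symmetric numeric matrix of pairwise similarity Z-scores with
#'   self-Z on the diagonal; rownames are the labels.
#' @param transform `"zmax_minus_z"` (default) or `"reciprocal"`.
#' @param normalize Divide `z(i, j)` by `sqrt(z(i, i) * z(j, j))` first.
#' @return Symmetric non-negative distance matrix with zero diagonal.
#' @export
zscores_to_distance <- function(z, transform = c("zmax_minus_z", "reciprocal"),
                                normalize = FALSE) {
  transform <- match.arg(transform)
  if (!is.matrix(z) || nrow(z) != ncol(z)) stopf("z must be a square matrix")
  if (nrow(z) < 2L) stopf("need at least 2 labels")
  if (max(abs(z - t(z))) > 1e-9) stopf("z must be symmetric (tol 1e-9)")
  if (normalize) {
    s <- sqrt(diag(z))
    z <- z / outer(s, s)
  }
  off <- z
  diag(off) <- NA
  d <- if (transform == "zmax_minus_z") {
    max(off, na.rm = TRUE) - z
  } else {
    if (any(off <= 0, na.rm = TRUE)) stopf("reciprocal transform needs z > 0")
    1 / z
  }
  diag(d) <- 0
  d[d < 0] <- 0
  d <- (d + t(d)) / 2
  d
}

#' UPGMA (average-linkage) tree from a distance matrix
#'
#' Standard UPGMA: repeatedly merge the closest pair of clusters at height
#' `d/2`, replacing their distances to the rest by the size-weighted
#' arithmetic mean. Ties are broken by the lexicographically smallest pair
#' of cluster representatives (the smallest leaf label in each cluster),
#' so the result is deterministic and invariant to input order. The tree
#' is rooted and ultrametric by construction.
#'
#' @param d Symmetric non-negative matrix with zero diagonal (labels as
#'   rownames), or a `dist` object.
#' @return An [ape::phylo] tree with branch lengths.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stopf("d must be square")
  if (any(is.na(d)) || any(is.nan(d))) stopf("d contains NA/NaN")
  if (any(d < 0)) stopf("d contains negative entries")
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  if (n < 2L) stopf("need at least 2 leaves")

  # active clusters: node id in the growing tree, size, representative label
  node_id <- seq_len(n)          # leaves are 1..n; internal nodes n+1..2n-1
  size <- rep(1L, n)
  rep_lbl <- labels
  height <- rep(0, 2L * n - 1L)
  edge <- matrix(0L, nrow = 2L * n - 2L, ncol = 2L)
  edge_len <- numeric(2L * n - 2L)
  e <- 0L
  next_node <- 2L * n - 1L       # ape wants the root at n+1; we fill and relabel
  dd <- d
  active <- seq_len(n)
  parent_height <- numeric(0)
  merges <- list()

  internal <- n
  while (length(active) > 1L) {
    m <- length(active)
    best <- NULL
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      a <- active[i]; b <- active[j]
      key <- sort(c(rep_lbl[a], rep_lbl[b]))
      cand <- list(dist = dd[a, b], i = a, j = b, key = key)
      if (is.null(best) || cand$dist < best$dist - 1e-15 ||
          (abs(cand$dist - best$dist) <= 1e-15 &&
           (cand$key[1] < best$key[1] ||
            (cand$key[1] == best$key[1] && cand$key[2] < best$key[2]))))
        best <- cand
    }
    a <- best$i; b <- best$j
    internal <- internal + 1L
    h <- best$dist / 2
    height[internal] <- h
    for (child in c(a, b)) {
      e <- e + 1L
      edge[e, ] <- c(internal, node_id[child])
      edge_len[e] <- h - height[node_id[child]]
    }
    # size-weighted average distances to remaining clusters
    others <- setdiff(active, c(a, b))
    for (o in others)
      dd[a, o] <- dd[o, a] <-
        (size[a] * dd[a, o] + size[b] * dd[b, o]) / (size[a] + size[b])
    size[a] <- size[a] + size[b]
    rep_lbl[a] <- min(rep_lbl[a], rep_lbl[b])
    node_id[a] <- internal
    active <- setdiff(active, b)
  }

  # relabel internal nodes so the root is n+1 (ape convention: root has the
  # greatest height; we created it last as 2n-1)
  n_int <- internal - n
  remap <- integer(2L * n - 1L)
  remap[seq_len(n)] <- seq_len(n)
  # created order n+1..2n-1; root created last -> map creation order reversed
  remap[(n + 1L):(2L * n - 1L)] <- (2L * n - 1L):(n + 1L)
  edge2 <- matrix(remap[edge], ncol = 2L)
  tr <- list(edge = edge2, edge.length = edge_len, tip.label = labels,
             Nnode = n_int)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Read a square Z-score matrix from TSV
#'
#' First column holds the row labels; header holds the column labels.
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_zmatrix <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (!identical(rownames(m), colnames(m)))
    stopf("Z matrix %s: row and column labels differ", path)
  m
}

#' Maximum deviation from ultrametricity
#'
#' Largest difference among root-to-leaf path lengths; 0 for an exactly
#' ultrametric tree.
#' @param tree An [ape::phylo] tree.
#' @return Non-negative number.
#' @export
ultrametric_deviation <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  max(depths) - min(depths)
}
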
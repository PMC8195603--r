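#!/usr/bin/env Rscript
# Structure-similarity tree: simulate an all-vs-all Z-score matrix with two
# planted structural clades, convert to distances (d = Zmax - Z) and build
# the average-linkage (UPGMA) tree.

suppressMessages(library(contextscan))
dir.create("results", showWarnings = FALSE)

set.seed(601L)
labels <- c("bDLD1", "bDLD2", "bDLD3", "Death", "DED", "TRADD-N")
clade <- c(1, 1, 2, 2, 2, 1)
n <- length(labels)
z <- matrix(0, n, n, dimnames = list(labels, labels))
for (i in 1:(n - 1)) for (j in (i + 1):n) {
  base <- if (clade[i] == clade[j]) 14 else 5
  z[i, j] <- z[j, i] <- base + stats::runif(1, -1.5, 1.5)
}
diag(z) <- 30
utils::write.table(z, "results/zscores.tsv", sep = "\t", quote = FALSE,
                   col.names = NA)

d <- zscores_to_distance(read_zmatrix("results/zscores.tsv"))
tree <- upgma(d)
ape::write.tree(tree, "results/structure_tree.nwk")
message("UPGMA tree: ", ape::write.tree(tree))
message(sprintf("ultrametric deviation: %.2e", ultrametric_deviation(tree)))
same_clade <- split(labels, clade)
message("planted clades: ", paste(vapply(same_clade, paste, character(1),
                                         collapse = "+"), collapse = " | "))
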
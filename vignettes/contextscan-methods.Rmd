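---
title: "Methods: contextual genomics of conflict systems with contextscan"
author: "contextscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contextual genomics of conflict systems with contextscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextscan)
```

# The analytical problem

Bacterial conflict (anti-invader) systems and their metazoan apoptotic
relatives are usually discovered not from sequence alone but from *context*:
genes that stay next to each other across distant taxa, domains that keep
re-appearing next to other domains in the same polypeptide, and protein
families that blow up into lineage-specific expansions (LSEs) in particular
organisms. `contextscan` packages that contextual-analysis toolbox — gene
neighborhoods, domain-architecture networks, and a set of dedicated
statistics — together with a synthetic-genome generator that plants known
signal, so each stage can be validated against ground truth before it is
pointed at real annotations.

# Conserved gene neighborhoods

A *neighborhood* is the window of up to `window` genes on each side of an
anchor gene (an anchor is any gene whose product carries a queried domain).
Three validity filters decide what counts as a conserved neighborhood:

1. **Distance.** Walking outward from the anchor, retention stops at the
   first intergenic gap exceeding `max_gap_nt` (default 50 nt). The
   comparison is inclusive (`<= 50` is kept) and gaps are computed as
   `next.start - prev.end - 1` under 1-based inclusive coordinates, so
   overlapping genes have negative gaps and are always retained. We chose
   the permissive inclusive bound because 50 nt is a convention for
   operonic spacing, not a sharp biological constant.
2. **Directionality.** Each gene's strand is compared to the *anchor's*
   strand (operon semantics), not to a window majority — the majority rule
   would make retention depend on the window size. The filter trims rather
   than rejects the whole neighborhood; `require_codirectional = FALSE`
   disables it.
3. **Phylum spread.** Groups of matched neighborhoods whose member taxa
   span fewer than `min_phyla` (default 2) distinct phyla are discarded.
   The filter applies to the group, not to individual families: it is the
   neighborhood's recurrence across phyla that signals selection.

Neighborhoods are matched across taxa by clustering all member proteins
into families (next section) and linking two neighborhoods when their
anchors share a family *and* at least one non-anchor flanking family is
shared. Flank order is deliberately not required — real cassettes tolerate
local rearrangement — and groups are the connected components of this
relation, so conservation can be chained through intermediate taxa.

# Protein clustering: the coverage / score-density contract

Families are built by single-linkage clustering with two thresholds, a
length-coverage `L` and a score-density `S`, mirroring the classic
BLASTCLUST interface. For a pair of sequences we compute one global
(Needleman–Wunsch) alignment with BLOSUM62 and affine gap costs
(open 11, extend 1) and define:

* `coverage` — gapless aligned columns divided by the longer sequence
  length. (Defining coverage on the full alignment length would exceed 1
  for any gapped global alignment; gapless columns keep it in `[0, 1]`.)
* `score_density` — alignment score divided by `2 x` gapless columns.
  BLOSUM62 entries are log-odds in half-bit units, so this is bits per
  aligned column; identical sequences score the mean self-substitution
  value (about 2.9 bits/column for uniformly random composition).

Two presets are exposed: *near-identical* `(L = 0.9, S = 1.89)` for
redundancy removal, and *family detection* `(L = 0.6, S = 0.8)`, our
calibration for homolog grouping at the divergences the generator
produces. The numeric `S` scale is this package's defined density, not
BLASTCLUST's undocumented internal normalization; the contract (two
thresholds gating single-linkage edges) is what is reproduced. One
consequence of using an *optimal* alignment worth knowing: unrelated
random protein pairs align at roughly 20% identity (the twilight-zone
effect), not the 5% naive background — but their score density sits at or
below 0 bits/column, far under every preset, which is why `S`, not
identity, gates the graph.

Clusters are reported ordered by smallest member id, making the output
invariant to input order; correctness is checked in the tests against
brute-force connected components over exhaustive pairwise evaluation.

# Architecture networks and positional bias

Domain architectures (N→C ordered label lists) are analysed three ways:

* **Adjacency network** — a directed graph with an edge `d1 → d2` weighted
  by the number of *unique* architectures in which `d2` immediately
  follows `d1`. Deduplication is exact label-sequence equality; tandem
  repeats give self-loops.
* **Retrieval network** — from profile-search hit tables, an edge
  `query → hit` is kept only when `p < 1e-4` (strict inequality), the best
  p is kept for duplicated pairs, and the weight is `-log10(p)`.
* **Positional bias** — for a domain of interest, occurrences in unique
  multi-domain architectures are classified N-terminal / internal /
  C-terminal and tested with a Pearson chi-squared (df = 2) against the
  *slot-availability null*: an occurrence in an architecture of length `k`
  lands in the three regions with probabilities `(1/k, (k-2)/k, 1/k)`.
  Summing these over occurrences respects the length composition of the
  architecture set; a naive uniform-thirds null is available via the
  `null` argument. Single-domain architectures are excluded (a lone
  domain is trivially both terminal).

One calibration subtlety is documented rather than hidden: when
architecture lengths are mixed, the per-occurrence category probabilities
are heterogeneous and the Pearson statistic is mildly *conservative*
(its null distribution is a weighted chi-squared with weights below 1; we
measure type-I error near 0.03 at `k` in 2–5). At homogeneous length —
where the null is exactly multinomial — the test is calibrated (measured
type-I error 0.050–0.056 at `k = 3`, 100 occurrences), and that is the
setting used for the calibration simulations. Power against a planted 90%
N-terminal bias at 100 architectures is effectively 1.

# Entropy-based diversification

Column-wise Shannon entropy `H = -sum_i P_i log2 P_i` is computed with
`P_i` the fraction of *non-gap* residues of type `i`; columns with more
than `max_gap_fraction` (default 0.5) gaps are dropped. The paperless
decision here is gap handling — excluding gaps from the denominator and
masking gappy columns is standard practice, and both knobs are exposed.
Two families are compared with a two-sided Welch *t*-test on their column
entropies; Welch because nothing justifies assuming equal variances
between a diversifying and a conserved family. Columns are treated as
independent observations, a known simplification shared with the test it
implements: phylogenetic non-independence of sequences is not corrected.

The generator plants column classes — conserved (one residue) or
diversified (uniform over `k` residues, entropy → `log2 k`). For null
calibration the class of each column is drawn i.i.d.; with a fixed class
composition the class-count variance the *t*-test prices in would be
absent and the test becomes arbitrarily conservative. Measured type-I
error at `alpha = 0.05` is 0.045–0.06 over 2000 simulations; power on the
planted 50%-diversified (`k = 8`) vs 10%-diversified (`k = 2`) contrast at
100 columns and 20 rows is 1.0.

# Trait enrichment

Association of a system with a binary taxon trait (the motivating case is
prokaryotic multicellularity) uses the upper-tail hypergeometric
probability `P(X >= q)` with `q` trait-positive carriers among `k`
carriers, against a background of `m` positive and `n` negative organisms.
The tri-state trait (`TRUE`/`FALSE`/`NA`) is first-class throughout the
data model; organisms with unknown trait are dropped from all four counts
*consistently* and the exclusions are reported. The observed value is
included in the tail (`phyper(q - 1, lower.tail = FALSE)` convention) —
the conservative standard for enrichment. The tail is computed by exact
log-space summation of pmf terms, which the tests hold to relative error
below 1e-12 against independent summation on the full grid `m + n <= 60`
and which remains stable at `m + n = 10000`.

# Polydomain scores

For an organism-by-family count table `c(o, p)`, each family's global
log-frequency is `f(p) = log2(colsum_p / grand total)` and the polydomain
score is `PD(o) = sum_p c(o, p) (f(p) - fbar)`, with `fbar` the
*unweighted* mean of `f(p)` across families. Families with all-zero
columns are removed before scoring (their log-frequency is undefined;
removal provably leaves all scores unchanged). High-|PD| organisms are
those with many copies of globally prevalent families — exactly the
signature of lineage-specific expansions of architecturally diverse
repertoires. In the generator, an expansion plants several hundred copies
spread over dedicated families on a Poisson(1) background; planted
organisms exceed the 99th percentile of background |PD| in every seeded
run of the acceptance simulations.

# Structure trees

Pairwise structure-similarity Z-scores are converted to distances with
`d = Zmax - Z` (`Zmax` the largest off-diagonal entry), a linear monotone
transform that puts the most similar pair at distance zero; `d = 1/Z` is
available because tree topology can differ between transforms, and
self-Z normalization is optional since conventions differ between
structure-comparison tools. Trees are built by UPGMA with size-weighted
average linkage, merge heights `d/2`, and deterministic lexicographic
tie-breaking, then serialized to Newick. The implementation is held to
the average-linkage cophenetic distances of `stats::hclust` on thousands
of random matrices and is ultrametric by construction.

# The synthetic cohort: what it does and does not emulate

`generate_genomes()` produces multi-replicon annotations with operon-like
same-strand runs (geometric run lengths, drawn before gene assignment so
the directionality filter is exercised non-trivially), normal intergenic
gaps truncated at −30 nt (allowing overlaps), background proteins that
are unique random sequences (so every false-positive group is
attributable), and planted cassettes: co-directional runs of homologous
families with gaps at or below the conservation threshold, inserted into
carriers spanning a configured number of phyla, with member sequences
mutated i.i.d. per site from a family ancestor. Defaults — 12 taxa over 4
phyla, 25–35 genes per replicon, one 4-gene cassette in 6 carriers over 3
phyla, divergence 0.1 — are small enough for test-suite turnaround while
leaving every filter a real chance to fail.

What it does *not* emulate, and what passing therefore does not show:
no indels within families (the clustering oracle stays analytic), no
nucleotide-level realism (GC content, codon usage), no horizontal
transfer, no paralogy within background genomes, and no annotation error.
Recovery of planted cassettes at recall/precision 1.0 demonstrates the
machinery, not performance on noisy real assemblies.

# Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive throughout (GenBank convention).
* `0 log 0 = 0` in entropy; all-gap columns are an error upstream.
* Tail probabilities are summed in log space via logsumexp.
* UPGMA ties break on the lexicographically smallest pair of cluster
  representatives; equal Z-scores collapse to a star at height 0.
* Empty genomes round-trip as header-only tables; GenBank CDS without
  `protein_id` get `<locus_tag>_<ordinal>` ids with a warning.
* Every stochastic entry point takes a seed, and `run_pipeline()` fans a
  single master seed out to its stages; reruns are byte-identical.

# Problem sizes used in validation

The test and acceptance simulations use: the full hypergeometric grid
`m + n <= 60` (77,530 parameter triples); 2000-replicate null simulations
for both calibration checks (100 columns x 20 rows alignments; 100
architectures); 100-replicate power checks; 20 seeded cohorts of 12
genomes at divergence 0.15 for neighborhood recovery; 50 seeded count
tables for PDS separation; and 1000 random matrices (3–6 leaves) for the
UPGMA oracle. These sizes give binomial standard errors comfortably inside
the asserted bands while keeping a full validation run within a few
minutes on one CPU.
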
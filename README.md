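# contextscan

Contextual comparative genomics for bacterial/metazoan conflict systems:
conserved gene-neighborhood detection, domain-architecture network
analysis, and the statistics used to characterize them — all validated
against synthetic genomes with planted ground truth.

## Who this is for

Groups studying anti-invader ("conflict") systems, apoptotic-adaptor
domain superfamilies, and similar gene ensembles discover candidates from
*context*: genes that remain adjacent across distant taxa, domains that
recur next to other domains within polypeptides, and protein families
that expand dramatically in particular lineages. `contextscan` implements
that workflow for desk-scale datasets: it consumes genome annotations
(GenBank flat files or a simple TSV dialect), per-protein domain
architectures, aligned FASTA, profile-search hit tables and taxon
metadata, and it ships a seeded simulator so every stage can be
benchmarked with known planted signal.

## What it computes

* **Conserved neighborhoods** — windows around anchor genes, subjected to
  three validity filters: intergenic distance (≤ 50 nt by default),
  conservation of gene directionality, and presence in more than one
  phylum. Neighborhoods are matched across taxa by protein clustering
  (anchor family shared + ≥ 1 shared flanking family).
* **Protein clustering** — single-linkage under the BLASTCLUST-style
  contract: link two sequences iff coverage ≥ `L` and score density ≥ `S`
  (global BLOSUM62 alignment, affine 11/1; density in bits per aligned
  column). Presets: near-identical `(0.9, 1.89)`, family detection
  `(0.6, 0.8)`.
* **Architecture networks** — directed adjacency graphs over domains
  (edge `d1 → d2` weighted by unique architectures where `d2` follows
  `d1`), and retrieval networks from hit tables (edges at `p < 1e-4`,
  weight `-log10 p`).
* **Positional bias** — Pearson χ² (df = 2) of a domain's N-terminal /
  internal / C-terminal occurrence counts against a slot-availability
  null `(1/k, (k-2)/k, 1/k)` per architecture of length `k`.
* **Diversification** — column-wise Shannon entropy
  `H = -Σ P_i log2 P_i` over non-gap residues, and a Welch t-test on mean
  column entropy between families.
* **Trait enrichment** — upper-tail hypergeometric `P(X ≥ q)` with inputs
  `q, m, n, k` (carriers scoring positive; positive and negative
  background; total carriers), with tri-state trait handling (unknowns
  dropped consistently and audited).
* **Polydomain scores (PDS)** — `PD(o) = Σ_p c(o,p)(f(p) − f̄)` with
  `f(p) = log2(Σ_o c(o,p) / ΣΣ c)`, flagging lineage-specific expansions
  of architecturally diverse repertoires.
* **Structure trees** — all-vs-all Z-score matrices converted to
  distances (`d = Zmax − Z`) and clustered by average linkage (UPGMA),
  written as Newick.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(`01_simulate.R` … `06_trees.R`); outputs land in `results/`. Running the
first two scripts simulates a 12-genome cohort with one 4-gene cassette
planted in 6 taxa across 3 phyla, re-reads the annotation tables, and
scans for conserved neighborhoods around the cassette's anchor domain:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_neighborhoods.R
```

```
wrote 12 genomes to results/cohort/annotations
phylum composition: Actinobacteria=3, Chloroflexi=3, Cyanobacteria=3, Proteobacteria=3
cassette carriers: t04, t06, t08, t07, t10, t09 spanning phyla: Chloroflexi, Cyanobacteria, Proteobacteria
loaded 12 genomes
6 anchored neighborhoods before filtering
1 conserved group(s) pass all three filters
planted carriers: t04,t06,t07,t08,t09,t10
recovered taxa:   t04,t06,t07,t08,t09,t10
exact recovery: TRUE
```

Exactly one group survives the distance, directionality and phylum
filters, and its member taxa are precisely the planted carriers. The
later scripts print, for their stages:

```
positional bias of EAD: N=103 int=5 C=12, chi2=154.80 (df=2), p=2.43e-34
mean entropy: diversifying 1.553 bits vs conserved 0.089 bits
Welch t = 11.31, two-sided p = 5.04e-21
PDS of planted expansion organism org001: 51.3
background PDS: mean -0.58, 99th percentile of |PDS| 2.09
```

i.e. the planted N-terminal bias, entropy contrast and expansion outlier
are each detected by their respective statistics. The same stages are
available programmatically (`demo_pipeline(out_dir, seed)` runs them all
on a generated fixture and writes a parameter manifest; reruns with the
same seed are byte-identical).

A paired GenBank/TSV fixture under `inst/extdata/` shows the two
annotation input routes producing identical genomes:

```r
library(contextscan)
g <- read_genbank(system.file("extdata", "example.gbk", package = "contextscan"))
g
#> <genome> Demobacterium contextus (Unknown), 3 gene(s) on 2 replicon(s), 3 protein(s)
```

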
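# polyAspeed

Tools for analysing how RNA polymerase II elongation rate shapes poly(A) site
choice at nucleotide resolution, for people working with 3' READS-style
poly(A) profiling and NET-seq-style nascent 3'-end data (yeast or mammalian).

Most genes produce many 3' mRNA isoforms whose endpoints fall in *clusters*
(consecutive endpoints ≤ 4 nt apart) inside the 3'UTR. Comparing a Pol II
speed mutant with wild type, the utilization ratio of isoform *p*,

    u(p) = rel_expr_mut(p) / rel_expr_wt(p),

declines (slow mutants) or rises (fast mutants) steadily from one nucleotide
to the next *within* a cluster, while pairs of isoforms bounding adjacent
clusters barely shift even over long distances. The package implements:

* **3' READS preprocessing** — 4-nt random-tag stripping, leading-T counting,
  species-specific truncation (17 nt yeast / 77 nt human), the
  internal-priming filter (a read survives iff the genomic sense-strand A-run
  at its 3' end is shorter than its T-count), replicate consolidation and
  scaling to 25 million reads, and strand-aware assignment of endpoints to
  genes as transcript offsets downstream of the stop codon;
* **isoform catalogues** — ≥1000-read gene floor (yeast), the ≥5%-of-maximum
  major-isoform rule with the human low-depth variant, and common-major
  utilization series;
* **cluster detection** at a configurable gap (default 4 nt, sweep 3–7) plus
  genome-wide cluster-size frequency tables;
* **a permutation null** — 100,000 draws of major-isoform positions from the
  non-A 3'UTR positions per gene, exact pattern-histogram matching, the
  p = 1/100,000 floor, an exact-enumeration oracle, and genome-wide null
  size frequencies (C++ kernel, seed-reproducible);
* **shift statistics** — per-cluster least-squares slopes of u with Pearson-R
  quality gates (|R| > 0.7 yeast / 0.6 human), within-cluster spacing medians
  (all pairs, 1–15 nt), between-cluster boundary-pair medians, and
  cluster-independent neighboring-pair differences;
* **GC elements** — 10-nt sliding-window GC vs cluster-slope correlations
  over +1..+100 / −100..−1 with Benjamini–Hochberg FDR, and the quintile
  analysis of percent GC change at +13..+30 against a 3'UTR background;
* **occupancy metagenes** — MAPQ-filtered 3'-end collapsing, matched
  downsampling, poly(A) anchors (≥20 reads in ±100 nt, ≥1 downstream) and
  decoy intronic AATAAA anchors (introns > 10 kb, hexamer re-centred to
  −25..−20), −100..+100 signal and percent-AT profiles;
* **a synthetic-data generator** with complete ground truth (clustered
  endpoints on non-A bases, per-cluster tilt r with mutant usage r^d and a
  0.98 boundary factor, GC elements coupled to |log r|, internal-priming
  artifact reads, dip/biphasic-bump occupancy tracks).

Standard formats go through standard tools: FASTA via Biostrings, bedGraph
via rtracklayer, TSV tables everywhere else.

## Worked example

Simulate 60 genes, sequence a wild type and a slow mutant (tilt r = 0.9) to
100,000 reads/gene, and recover the shift statistics:

```r
library(polyAspeed)

sim <- make_genome(n_genes = 60, seed = 1)
wt  <- simulate_endpoint_counts(sim, "wt",     depth = 1e5, seed = 2)
mut <- simulate_endpoint_counts(sim, "mutant", depth = 1e5, tilt = 0.9, seed = 3)

ser <- combine_genotypes(
  select_major_isoforms(build_catalog(wt,  "yeast"), "yeast"),
  select_major_isoforms(build_catalog(mut, "yeast"), "yeast"))

head(cluster_slopes(ser), 3)
#>   gene_id cluster n start end       slope  pearson_R   ok
#> 1   g0001       1 6    20  25 -0.12349198 -0.9944164 TRUE
#> 2   g0001       2 5    65  69 -0.07433747 -0.9903235 TRUE
#> 3   g0002       1 6    20  25 -0.12904378 -0.9974424 TRUE

within_cluster_spacing_medians(ser, R_threshold = 0.7)
#>   spacing    median n_pairs
#> 1       1 0.8988262     540
#> 2       2 0.8096563     420
#> 3       3 0.7286352     300
#> 4       4 0.6556159     180
#> 5       5 0.5891659      60

between_cluster_spacing_medians(ser)
#>   spacing    median n_pairs
#> 1      40 0.9670419      20
#> 2      50 0.9772074      26
#> 3      60 0.9892632      14
```

The within-cluster medians track r^d (0.9, 0.81, 0.729, 0.656, 0.59): the
mutant/WT ratio falls ~10% per nucleotide of spacing inside a cluster. The
between-cluster medians hover near the boundary constant 0.98 at any
distance — the near-flat inter-cluster behaviour.

How unlikely is one gene's observed cluster pattern under random placement?

```r
gene <- sim$genes[1, ]
obs  <- ser$offset[ser$gene_id == gene$gene_id]
pattern_probability(eligible_positions(gene, sim$genome), obs,
                    n_shuffles = 1e5, seed = 4)[c("matches", "p", "neg_log10_p")]
#> $matches  [1] 0
#> $p        [1] 1e-05
#> $neg_log10_p [1] 5
```

No shuffle of 100,000 reproduces the observed two-cluster pattern, so the
probability is reported at the floor 1/100,000 (−log10 p = 5, far above the
significance line at 2).

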
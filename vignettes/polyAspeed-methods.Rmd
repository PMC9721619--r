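---
title: "Methods: poly(A) site clusters and Pol II elongation-rate shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A) site clusters and Pol II elongation-rate shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Most eukaryotic genes produce many 3' mRNA isoforms that differ only in the
position where the poly(A) tail is added. In yeast these endpoints fall in an
"end zone" of roughly 200 nt downstream of the stop codon, and they are not
spread uniformly: endpoints occur in *clusters* of closely spaced sites.
RNA polymerase II (Pol II) elongation rate reshapes this profile: slow Pol II
derivatives shift usage toward upstream (ORF-proximal) isoforms, fast
derivatives toward downstream ones, and the shift proceeds nucleotide by
nucleotide *within* a cluster while isoforms in *different* clusters barely
shift relative to one another.

`polyAspeed` implements the computational side of this analysis as a reusable,
tested pipeline: 3' READS-style read preprocessing, isoform cataloguing,
cluster detection, a permutation null for cluster patterns, utilization-shift
statistics, downstream GC-element correlation, and single-base nascent-3'-end
occupancy metagenes — together with a synthetic-data generator that provides
full ground truth for every one of those steps.

# Core definitions and statistics

**Transcript coordinates.** Genomic coordinates are 0-based half-open
internally; all reported isoform positions are 1-based transcript offsets,
nt downstream of the last base of the stop codon, with minus-strand genes
mapped into transcript space at load time so every downstream analysis is
strand-agnostic.

**Internal-priming filter.** A 3' READS read begins (after removal of 4
random nt) with a run of Ts — the reverse complement of terminal As. A read
whose mapped 3' end is followed on the sense strand by an uninterrupted
genomic A-run at least as long as its T-count cannot be distinguished from an
internally primed artifact and is discarded; a read is retained iff
`run < t_count`. The same logic motivates excluding genomic-A positions from
the permutation null below.

**Isoform catalogue.** Scaled endpoint counts (replicates consolidated, then
scaled to 25 million reads by default) are tabulated per gene; genes need
1000 reads in the 3'UTR window under the yeast profile. Major isoforms hold
at least 5% of the reads of the gene's maximal isoform (inclusive boundary
under the yeast profile; the human profile uses a strict `>` plus a low-depth
rule: when the maximal isoform has fewer than 100 reads in either genotype,
any isoform with 5 or more reads is major). Utilization of isoform *p* is
`u(p) = rel_mut(p) / rel_wt(p)`, with relative expression computed over the
isoforms that are major in both genotypes. Any gene-constant denominator
yields the same downstream ratio-of-ratio statistics; the common-major
denominator was chosen because it makes `u` comparable across genes.

**Clusters.** A cluster is a maximal run of major-isoform offsets with
consecutive differences of at most `max_gap` (default 4 nt, sweepable 3–7).
The gap is the positional difference, so adjacent bases are 1 nt apart.

**Permutation null.** For each gene, the same number of positions as major
isoforms is drawn uniformly *without replacement* from the non-A positions of
the 3'UTR, 100,000 times; the pattern probability is the fraction of draws
whose cluster-size histogram is exactly identical to the observed one,
floored at 1/100,000 when no draw matches. Sampling without replacement
reflects that endpoints are distinct positions. An exact-enumeration oracle
(`exact_pattern_probability`) verifies the Monte-Carlo estimator in the test
suite; probabilities are reported as −log10 p with 2 as the conventional
significance line.

**Shift statistics.** Within clusters of ≥4 common majors, the ordinary
least-squares slope of `u` versus offset is computed with its Pearson R.
Quality gates: |R| > 0.7 (yeast) or 0.6 (human) for spacing analyses,
|R| > 0.5 for sequence-composition analyses. Within-cluster spacing medians
use *all* isoform pairs (including non-adjacent ones) grouped by spacing
(1–15 nt yeast, 1–14 human); between-cluster statistics use one pair per
adjacent cluster boundary (3'-most of the upstream cluster vs 5'-most of the
downstream one). Because the figure legends describe relative ratios
(downstream/upstream) while the methods text describes percent differences,
both are implemented behind `stat`, with `relative_ratio` the default for
cluster analyses and plain `difference` for the cluster-independent
neighboring-pair analysis. Medians, never means, are reported.

**GC elements.** For gated clusters, GC content in 10-nt sliding windows
(window "starting at s" spans offsets s..s+9) across +1..+100 downstream of
the 3'-most isoform (and −100..−1 upstream of the 5'-most) is correlated with
cluster slope; two-sided correlation p-values are Benjamini–Hochberg
corrected across window positions within a region and called significant at
q < 0.05. The quintile analysis sorts gated slopes ascending, splits them
into five near-equal groups (stable on ties), and reports each quintile's
mean percent change of GC at +13..+30 relative to background. The background
is the median GC over all 18-nt windows fully contained in the analyzed
genes' 3'UTR windows — the most reproducible reading of "equivalent genomic
positions within 3'UTRs" — and is exposed as a parameter, as is the FDR
cutoff.

**Occupancy metagenes.** Nascent 3'-end reads with MAPQ > 10 are collapsed to
the single base of the RNA 3'-OH end; libraries are downsampled without
replacement to a common total before comparison. Poly(A) anchors require ≥20
reads within ±100 nt and ≥1 read in +1..+100 in every library; decoy anchors
are sense-strand AATAAA hexamers in introns > 10 kb, re-centred so the
hexamer occupies −25..−20 relative to a nominal cleavage site, with ≥10 reads
within ±100 nt. Profiles sum strand-oriented coverage per offset over
−100..+100 (a per-site mean is available behind `stat`), and AT composition
is the per-position percentage of anchors with A or T on the sense strand
(the per-site median variant is a flag; for a binary indicator the percent is
the reproducible statistic).

# The synthetic-data generator

`make_genome()` builds one chromosome per gene: a gene body ending in TAA, a
3'UTR of 200 nt (the end-zone scale), and pads wide enough for +100 windows
and metagene flanks. Its defaults are the study conditions used throughout
the test suite:

* clusters of 6 and 5 isoforms at 1-nt spacing, the first endpoint at offset
  20, inter-cluster gaps drawn from {40, 50, 60} nt — discrete so that each
  between-cluster distance bin collects enough boundary pairs for a stable
  median, and large enough that a cluster's +13..+30 element never overlaps
  the next cluster;
* baseline usage weights uniform in [0.8, 1.25], so every true endpoint stays
  above the 5% major rule in both genotypes even under a strong tilt
  (r = 0.8 over an 11-isoform gene), keeping the truth recoverable;
* endpoints placed only on non-A sense bases, mirroring the analysis-side
  exclusion, so the permutation null and the internal-priming filter can both
  recover the truth;
* per-cluster tilt factors r in [0.78, 0.98] (or one fixed value): mutant/WT
  usage scales as r^d at d nt into a cluster, and crossing a cluster boundary
  multiplies utilization by a single constant 0.98, so boundary pairs sit at
  0.98 regardless of distance — the near-flat inter-cluster behaviour;
* when `gc_coupling > 0`, the GC fraction of the 18-nt element at +13..+30
  downstream of each cluster rises linearly with |log r| from 25% to up to
  75%, coupling sequence composition to speed sensitivity;
* non-templated tails are 1 + geometric with mean 8 (at least one
  non-templated A is required; the distribution is otherwise a modelling
  choice), and artifact reads end just upstream of genomic A-runs with
  T-counts never exceeding the run, so the filter should remove exactly them;
* occupancy tracks multiply a flat Poisson baseline by 0.6 over −40..−1
  (the pre-site dip) and by 1.5 over +10..+25 and 2.5 over +30..+100 (the
  biphasic downstream increase, second phase stronger).

**What the generator does not emulate.** No sequencing errors, no splicing,
no overlapping genes, no mappability structure, and utilization noise is
purely multinomial. Passing tests therefore demonstrate correctness of the
*computations* under controlled conditions, not robustness to every artefact
of real libraries.

**A deliberate confound to know about.** Because the boundary ratio is held
at exactly 0.98, a cluster's absolute utilization level — and hence its raw
slope — depends on the tilt of the clusters upstream of it. In multi-cluster
genes this genuinely (not spuriously) correlates a cluster's slope with its
neighbour's GC element. The GC analyses are therefore exercised on
single-cluster genes, which isolate the +13..+30 element; this is a property
of the generator's utilization model, not of the scan.

# Numerical choices and problem sizes

* The shuffle kernel is implemented in C++ (partial Fisher–Yates over the
  eligible positions, R's own RNG, so `set.seed()` reproduces results
  exactly); 100,000 shuffles of a typical gene take well under a second.
* Exact pattern enumeration refuses more than 10^6 subsets.
* Pattern identity is exact equality of the size→count histogram.
* Zero-variance utilization within a cluster leaves Pearson R undefined; the
  record is flagged and excluded from gated analyses rather than silently
  dropped.
* Degenerate inputs error loudly: more isoforms than eligible positions,
  all-zero counts at scaling, windows off the contig in sequence fetches
  (metagene anchors near contig ends are dropped and counted instead, since
  losing a flank is expected at fixture scale).
* Test and acceptance runs use 50–300 genes, 10^5 reads/gene for count-level
  simulations, 10^5 shuffles, and 10^6-read occupancy tracks; medians at
  these sizes are stable to well under the tolerances asserted.

# Known limitations

* The naive exact-match aligner exists only so fixture-scale end-to-end runs
  are possible; production data should arrive pre-mapped.
* With ~90 heavily overlapping sliding windows and a strong localized signal,
  BH at q < 0.05 admits on the order of one borderline false window per scan
  by construction of FDR control; localization conclusions should rest on the
  strongly significant windows.
* The human low-depth major rule needs the other genotype's per-gene maxima
  (`other_max`); when absent, only the own-genotype maximum decides.
* Between-cluster "difference" statistics scale with the upstream isoform's
  utilization, so their magnitude is not comparable across mutants of
  different strength (the relative ratio is).
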
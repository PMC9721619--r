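Package: polyAspeed
Title: Poly(A) Site Clusters and RNA Polymerase II Elongation-Rate Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking RNA polymerase II elongation rate to
    nucleotide-level poly(A) site choice. Implements 3' READS-style read
    preprocessing with internal-priming filtering against the genome, per-gene
    poly(A) isoform catalogues with major-isoform rules for yeast and human
    depth regimes, detection of isoform clusters at a configurable inter-isoform
    gap, a permutation null for per-gene cluster patterns over non-A 3'UTR
    positions (with an exact-enumeration oracle), mutant/wild-type utilization
    shift statistics within and between clusters, sliding-window GC correlation
    with cluster slopes under FDR control, and single-base nascent 3'-end
    occupancy metagenes around poly(A) and decoy intronic AATAAA sites.
    Includes a synthetic-data generator with full ground truth for all of the
    above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
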
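# Shared fixtures and independent oracles, all built in code.

# genome with a single plus-strand gene whose 3'UTR is the given string
utr_fixture <- function(utr, lead = 30L, tail = 10L, gene_id = "g1", chrom = "chr1") {
  seq <- paste0(strrep("G", lead - 3L), "TAA", utr, strrep("G", tail))
  genome <- Biostrings::DNAStringSet(stats::setNames(seq, chrom))
  gene <- data.frame(gene_id = gene_id, chrom = chrom, strand = "+",
                     stop_codon_end = lead - 1L, utr_upstream = 0L,
                     utr_downstream = nchar(utr))
  list(genome = genome, gene = gene)
}

# engineered permutation-floor gene: one run of 6 consecutive non-A bases,
# every other eligible position isolated by >= 5 nt
floor_gene <- function(n_isolated = 120L) {
  utr_fixture(paste0(strrep("A", 19L), "CCGCGT",
                     strrep("AAAAG", n_isolated)))
}

# independent interval-merge oracle: connected components of the
# "within max_gap" graph, by iterated label propagation
oracle_clusters <- function(offsets, max_gap) {
  n <- length(offsets)
  if (n == 0L) return(integer(0))
  adj <- abs(outer(offsets, offsets, "-")) <= max_gap
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), 0L)
    if (identical(new, comp)) break
    comp <- new
  }
  match(comp, unique(comp))
}

# hand-built utilization series (one gene) from offsets and u values
series_fixture <- function(offsets, u, gene_id = "g1") {
  data.frame(gene_id = gene_id, offset = offsets,
             count_wt = 100, count_mut = 100,
             rel_wt = 1 / length(offsets), rel_mut = u / length(offsets), u = u)
}

# wild-type vs mutant utilization series straight from a simulation
sim_series <- function(sim, depth, tilt = NULL, seed_wt = 1L, seed_mut = 2L,
                       profile = "yeast") {
  wt <- simulate_endpoint_counts(sim, "wt", depth, seed = seed_wt)
  genotype <- if (is.null(tilt)) "mutant" else "mutant"
  mut <- simulate_endpoint_counts(sim, genotype, depth, tilt = tilt, seed = seed_mut)
  combine_genotypes(select_major_isoforms(build_catalog(wt, profile), profile),
                    select_major_isoforms(build_catalog(mut, profile), profile))
}
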
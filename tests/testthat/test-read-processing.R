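test_that("trimming follows the 4-nt strip / leading-T / truncation steps", {
  reads <- c(ok = paste0("NNNN", "TTT", "ACGTACGTACGTACGTACGTACGT"),
             not_t = "NNNNACGTACGT",
             short = "NNN")
  tagged <- preprocess_reads(reads, "yeast")
  expect_equal(nrow(tagged), 1L)
  expect_equal(tagged$t_count, 3L)
  expect_match(tagged$trimmed_seq, "^ACGT")
  expect_equal(nchar(tagged$trimmed_seq), 17L)  # yeast truncation
  drops <- attr(tagged, "drops")
  expect_equal(unname(drops["first_not_t"]), 1L)
  expect_equal(unname(drops["too_short"]), 1L)

  human <- preprocess_reads(c(r = paste0("NNNNT", strrep("ACGT", 25))), "human")
  expect_equal(nchar(human$trimmed_seq), 77L)

  # a read that is all Ts after the random 4-mer has no mappable remainder
  allt <- preprocess_reads(c(t = "NNNNTTTTTT"), "yeast")
  expect_equal(nrow(allt), 0L)
  expect_equal(unname(attr(allt, "drops")["all_t"]), 1L)
})

test_that("internal-priming filter applies the A-run rule literally", {
  # UTR layout: endpoint at offset 5 followed by AAAAA; endpoint at 15 followed
  # by AAG; endpoint at 25 followed by C
  utr <- paste0("CCCCG", "AAAAA", "CCCCG", "AAGCC", "CCCCG", "CCCCC")
  fx <- utr_fixture(utr)
  stop_end <- fx$gene$stop_codon_end
  mapped <- data.frame(chrom = "chr1",
                       pos = stop_end + c(5L, 15L, 25L),
                       strand = "+",
                       t_count = c(5L, 5L, 1L))
  kept <- attr(filter_internal_priming(mapped, fx$genome), "kept")
  expect_identical(kept, c(FALSE, TRUE, TRUE))  # run 5 >= 5; run 2 < 5; run 0 < 1

  # same decisions on the minus strand: sense A-run is a genomic T-run upstream
  mgenome <- Biostrings::DNAStringSet(c(m = as.character(
    Biostrings::reverseComplement(fx$genome[[1]]))))
  L <- length(fx$genome[[1]])
  mpos <- L - 1L - mapped$pos
  mmapped <- data.frame(chrom = "m", pos = mpos, strand = "-", t_count = mapped$t_count)
  expect_identical(attr(filter_internal_priming(mmapped, mgenome), "kept"),
                   c(FALSE, TRUE, TRUE))

  expect_error(filter_internal_priming(
    data.frame(chrom = "chr1", pos = 10000L, strand = "+", t_count = 2L), fx$genome),
    "outside")
})

test_that("consolidation sums replicates and scaling preserves proportions", {
  r1 <- data.frame(gene_id = "g", offset = c(1L, 2L), count = c(1, 1))
  r2 <- data.frame(gene_id = "g", offset = c(2L, 3L), count = c(2, 0))
  out <- consolidate_and_scale(list(r1, r2), target = 8)
  out <- out[order(out$offset), ]
  expect_equal(out$count, c(2, 6, 0))

  set.seed(6)
  big <- data.frame(gene_id = sprintf("g%d", 1:1e4), offset = 1L,
                    count = rexp(1e4) + 0.01)
  scaled <- consolidate_and_scale(big)
  expect_lt(abs(sum(scaled$count) - 25e6) / 25e6, 1e-6)  # default 25 million
  expect_equal(scaled$count / sum(scaled$count), big$count / sum(big$count))

  # idempotence at the target total
  twice <- consolidate_and_scale(scaled)
  expect_equal(twice$count, scaled$count, tolerance = 1e-12)

  expect_error(consolidate_and_scale(data.frame(k = 1, count = 0)), "zero")
})

test_that("gene assignment respects windows, strand, chrM and tie-breaks", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1", strand = "+",
                      stop_codon_end = c(1000L, 6100L),
                      utr_upstream = c(0L, 0L), utr_downstream = c(5000L, 5000L))
  eps <- data.frame(chrom = "chr1",
                    pos = c(1100L, 6001L, 6200L, 1000L),
                    strand = "+", count = c(3, 1, 2, 9))
  out <- assign_to_genes(eps, genes, "human")
  expect_equal(out$offset[out$gene_id == "gA" & out$count == 3], 100L)
  # 6001 is 5001 nt downstream of gA's stop but within gB? offset for gB is
  # negative; with gB upstream extent 0 it is unassigned entirely
  expect_false(1L %in% out$count)
  # overlap: 6200 fits gA (offset 5200 > 5000? no) -> belongs to gB at offset 100
  expect_equal(out$offset[out$gene_id == "gB"], 100L)
  # offset 0 (pos == stop_codon_end) is outside a 0-upstream window
  expect_false(any(out$count == 9))

  # human profile drops mitochondrial contigs
  chrm <- data.frame(chrom = "chrM", pos = 1100L, strand = "+", count = 5)
  expect_equal(nrow(assign_to_genes(chrm, transform(genes, chrom = "chrM"), "human")), 0L)
  # ... but yeast keeps them
  expect_gt(nrow(assign_to_genes(chrm, transform(genes, chrom = "chrM"), "yeast")), 0L)

  # nearest-upstream tie-break for genuinely overlapping windows
  over <- data.frame(gene_id = c("up", "down"), chrom = "c", strand = "+",
                     stop_codon_end = c(100L, 150L), utr_upstream = 0L,
                     utr_downstream = 500L)
  hit <- data.frame(chrom = "c", pos = 200L, strand = "+", count = 1)
  res <- assign_to_genes(hit, over, "yeast")
  expect_equal(res$gene_id, "down")  # offset 50 beats offset 100
  expect_equal(attr(res, "ambiguous"), 1L)

  # minus-strand genes count offsets in transcript direction
  mg <- data.frame(gene_id = "m", chrom = "c", strand = "-", stop_codon_end = 400L,
                   utr_upstream = 0L, utr_downstream = 300L)
  mres <- assign_to_genes(data.frame(chrom = "c", pos = 340L, strand = "-", count = 2),
                          mg, "yeast")
  expect_equal(mres$offset, 60L)
})

test_that("end-to-end: artifacts and only rule-violating reads are discarded", {
  sim <- make_genome(2, seed = 41)
  rd <- simulate_polyA_reads(sim, "wt", depth = 1200, artifact_rate = 0.3, seed = 42)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rd$reads, fq)
  tagged <- preprocess_reads(fq, "yeast")
  expect_equal(nrow(tagged), length(rd$reads))
  mapped <- align_reads_exact(tagged, sim$genome)
  filtered <- filter_internal_priming(mapped, sim$genome)
  cls <- rd$truth$class[match(filtered$read_id, rd$truth$read_id)]
  expect_equal(sum(cls == "artifact"), 0L)  # no artifact survives

  # every discard is either a labelled artifact or satisfies the genomic rule
  discarded <- mapped[!attr(filtered, "kept"), ]
  dcls <- rd$truth$class[match(discarded$read_id, rd$truth$read_id)]
  lens <- chrom_lengths(sim$genome)
  for (i in seq_len(nrow(discarded))) {
    if (dcls[i] == "artifact") next
    down <- fetch_seq(sim$genome, discarded$chrom[i], discarded$pos[i] + 1L,
                      min(lens[[discarded$chrom[i]]],
                          discarded$pos[i] + 1L + discarded$t_count[i]), "+")
    run <- attr(regexpr("^A*", down), "match.length")
    expect_gte(run, discarded$t_count[i])
  }

  # surviving reads reconstruct the truth endpoints
  counts <- assign_to_genes(tally_endpoints(filtered), sim$genes, "yeast")
  truth_keys <- paste(sim$truth$endpoints$gene_id, sim$truth$endpoints$offset)
  expect_true(all(paste(counts$gene_id, counts$offset) %in% truth_keys))
})
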
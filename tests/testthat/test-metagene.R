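test_that("read collapsing applies the strict MAPQ gate and 3'-end convention", {
  reads <- data.frame(chrom = "chr1", start = c(100L, 100L, 200L),
                      end = c(150L, 150L, 260L),
                      strand = c("+", "+", "-"), mapq = c(10, 30, 30))
  cov <- collapse_reads(reads)
  expect_equal(coverage_total(cov), 2)  # MAPQ 10 removed, > 10 kept
  expect_equal(coverage_query(cov, "chr1", 149L, "+"), 1)  # last aligned base
  expect_equal(coverage_query(cov, "chr1", 200L, "-"), 1)  # 3' end of minus read
  expect_equal(nrow(collapse_reads(reads[0, ])), 0L)

  # proximity and exclusion filters apply when annotations are given
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                      stop_codon_end = 120L, utr_upstream = 0L, utr_downstream = 100L)
  near <- collapse_reads(reads, genes = genes, near_genes_bp = 1000L)
  expect_equal(coverage_total(near), 2)
  far <- collapse_reads(reads, genes = transform(genes, stop_codon_end = 1e6L))
  expect_equal(coverage_total(far), 0)
  excl <- collapse_reads(reads, exclude = data.frame(chrom = "chr1",
                                                     start = 140L, end = 160L))
  expect_equal(coverage_total(excl), 1)
})

test_that("matched downsampling equalizes totals deterministically", {
  a <- end_coverage("c", 1:50, "+", rep(2, 50))    # total 100
  b <- end_coverage("c", 1:40, "+", rep(2, 40))    # total 80
  ds <- downsample_matched(list(a = a, b = b), seed = 5)
  expect_equal(coverage_total(ds$a), 80)
  expect_identical(ds$b, b)                        # already at the minimum
  ds2 <- downsample_matched(list(a = a, b = b), seed = 5)
  expect_identical(ds, ds2)

  # expected per-base counts scale by the sampling fraction
  set.seed(7)
  big <- end_coverage("c", 1:1000, "+", rpois(1000, 100) + 1)
  small <- end_coverage("c", 1L, "+", round(coverage_total(big) * 0.8))
  ds3 <- downsample_matched(list(big = big, small = small), seed = 6)
  kept <- coverage_query(ds3$big, "c", 1:1000, rep("+", 1000))
  expect_equal(sum(kept), coverage_total(small))
  expect_lt(mean(abs(kept - 0.8 * big$count)) / mean(big$count), 0.1)
})

test_that("poly(A) anchor selection enforces both read filters per library", {
  mk <- function(n_in, n_down) {
    pos <- c(seq(-90, -1, length.out = n_in - n_down), seq(1, 90, length.out = n_down))
    end_coverage("c", 500L + as.integer(round(pos)), "+", rep(1, n_in))
  }
  sites <- data.frame(chrom = "c", pos = 500L, strand = "+")
  expect_equal(nrow(select_polyA_anchors(sites, list(mk(25, 5), mk(19, 5)))), 0L)
  expect_equal(nrow(select_polyA_anchors(sites, list(mk(25, 5), mk(25, 0)))), 0L)
  expect_equal(nrow(select_polyA_anchors(sites, list(mk(25, 5), mk(20, 1)))), 1L)
  expect_equal(nrow(select_polyA_anchors(sites[0, ], list(mk(25, 5)))), 0L)
})

test_that("decoy anchors re-centre AATAAA to -25..-20 in long introns only", {
  hex_at <- 5000L
  s <- strrep("C", 12000L)
  substr(s, hex_at + 1L, hex_at + 6L) <- "AATAAA"
  genome <- Biostrings::DNAStringSet(c(I = s))
  cov <- end_coverage("I", as.integer(seq(4950, 5100)), "+", rep(1, 151))
  introns <- data.frame(chrom = "I", start = 0L, end = 12000L, strand = "+")
  anch <- find_decoy_anchors(genome, introns, list(cov, cov))
  expect_equal(anch$pos, hex_at + 25L)
  expect_identical(fetch_seq(genome, "I", anch$pos - 25L, anch$pos - 19L, "+"), "AATAAA")

  # intron of exactly 10 kb is excluded (strictly > 10 kb)
  short <- data.frame(chrom = "I", start = 0L, end = 10000L, strand = "+")
  expect_equal(nrow(find_decoy_anchors(genome, short, list(cov, cov))), 0L)
  # no hexamer, no anchors
  empty <- Biostrings::DNAStringSet(c(I = strrep("C", 12000L)))
  expect_equal(nrow(find_decoy_anchors(empty, introns, list(cov, cov))), 0L)
})

test_that("metagene profiles are exact deltas with conserved mass", {
  genome <- Biostrings::DNAStringSet(c(c = strrep("AT", 300)))
  anchors <- data.frame(chrom = "c", pos = 300L, strand = "+")
  cov <- end_coverage("c", 307L, "+", 3)
  prof <- build_metagene(anchors, list(lib = cov), genome)
  expect_equal(prof$lib[prof$offset == 7], 3)
  expect_equal(sum(prof$lib), 3)                     # mass conservation
  expect_true(all(prof$at_percent == 100))           # all-AT fixture

  # minus-strand anchors flip into transcript orientation
  manchors <- data.frame(chrom = "c", pos = 300L, strand = "-")
  mcov <- end_coverage("c", 293L, "-", 2)
  mprof <- build_metagene(manchors, list(lib = mcov), genome)
  expect_equal(mprof$lib[mprof$offset == 7], 2)

  # off-contig anchors are dropped; with none left this is an error
  edge <- data.frame(chrom = "c", pos = c(10L, 300L), strand = "+")
  pe <- build_metagene(edge, list(lib = cov), genome)
  expect_equal(attr(pe, "n_anchors"), 1L)
  expect_error(build_metagene(data.frame(chrom = "c", pos = 10L, strand = "+"),
                              list(lib = cov), genome), "contig")
})
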
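test_that("generator is deterministic under a fixed seed", {
  a <- make_genome(3, gc_coupling = 0.5, seed = 11)
  b <- make_genome(3, gc_coupling = 0.5, seed = 11)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$endpoints, b$truth$endpoints)
  expect_identical(a$truth$clusters, b$truth$clusters)

  ra <- simulate_polyA_reads(a, "wt", 50, seed = 3)
  rb <- simulate_polyA_reads(b, "wt", 50, seed = 3)
  expect_identical(ra$reads, rb$reads)
  expect_identical(simulate_enetseq(a, 1e4, seed = 5), simulate_enetseq(b, 1e4, seed = 5))
})

test_that("degenerate generator inputs behave per contract", {
  empty <- make_genome(0, seed = 1)
  expect_equal(length(empty$genome), 0L)
  expect_equal(nrow(empty$genes), 0L)
  expect_equal(nrow(empty$truth$endpoints), 0L)

  expect_error(make_genome(1, utr_len = 60L, seed = 1), "utr_len")

  sim <- make_genome(2, seed = 2)
  expect_equal(nrow(simulate_endpoint_counts(sim, "wt", 0)), 0L)
  expect_equal(length(simulate_polyA_reads(sim, "wt", 0)$reads), 0L)
  expect_equal(nrow(simulate_enetseq(sim, 0)), 0L)
})

test_that("true endpoints always sit on non-A sense bases", {
  sim <- make_genome(10, gc_coupling = 1, seed = 13)
  ep <- sim$truth$endpoints
  for (i in seq_len(nrow(ep))) {
    gene <- sim$genes[match(ep$gene_id[i], sim$genes$gene_id), ]
    pos <- offset_to_genomic(gene, ep$offset[i])
    expect_false(fetch_seq(sim$genome, gene$chrom, pos, pos + 1L, gene$strand) == "A")
  }
})

test_that("endpoint sampling converges to the truth weights", {
  sim <- make_genome(1, cluster_sizes = c(1L, 1L), seed = 17)
  sim$truth$endpoints$weight <- c(3, 1)  # 3:1 target
  counts <- simulate_endpoint_counts(sim, "wt", 2e5, seed = 18)
  p_hat <- counts$count[1] / sum(counts$count)
  se <- sqrt(0.75 * 0.25 / 2e5)
  expect_lt(abs(p_hat - 0.75), 3 * se)
})

test_that("mutant utilization tilts usage by r^d within a cluster", {
  sim <- make_genome(1, cluster_sizes = 5L, seed = 19)
  u <- mutant_utilization(sim, tilt = 0.9)
  d <- sim$truth$endpoints$offset - min(sim$truth$endpoints$offset)
  expect_equal(u, 0.9^d)

  # boundary factor: two clusters, ratio across the boundary is between_factor
  sim2 <- make_genome(1, cluster_sizes = c(3L, 3L), seed = 20)
  u2 <- mutant_utilization(sim2, tilt = 0.9, between_factor = 0.95)
  ep <- sim2$truth$endpoints
  up_end <- which.max(ep$offset[ep$cluster == 1])
  expect_equal(u2[ep$cluster == 2][1] / u2[ep$cluster == 1][up_end], 0.95)
})

test_that("GC at +13..+30 couples to tilt magnitude when requested", {
  sim <- make_genome(40, cluster_sizes = 6L, gc_coupling = 1, seed = 23)
  cl <- sim$truth$clusters
  expect_gt(cor(cl$gc_elem, abs(log(cl$r))), 0.8)

  sim0 <- make_genome(40, cluster_sizes = 6L, gc_coupling = 0, seed = 24)
  cl0 <- sim0$truth$clusters
  expect_lt(abs(cor(cl0$gc_elem, abs(log(cl0$r)))), 0.4)
})

test_that("simulated occupancy reproduces dip and biphasic bumps", {
  sim <- make_genome(30, cluster_sizes = 1L, first_offset = 100L, seed = 25)
  params <- occupancy_params()
  params$bump1 <- 2.0
  cov <- simulate_enetseq(sim, depth = 1e6, params = params, seed = 26)
  ep <- sim$truth$endpoints
  gi <- match(ep$gene_id, sim$genes$gene_id)
  pa <- sim$genes$stop_codon_end[gi] + ep$offset
  win_mean <- function(lo, hi) {
    tot <- 0; n <- 0
    for (i in seq_along(pa)) {
      p <- (pa[i] + lo):(pa[i] + hi)
      tot <- tot + sum(coverage_query(cov, rep(sim$genes$chrom[gi[i]], length(p)), p, rep("+", length(p))))
      n <- n + length(p)
    }
    tot / n
  }
  base <- win_mean(-100, -50)
  expect_lt(abs(win_mean(10, 25) / base - 2.0), 0.1)        # amplitude recovered
  expect_lt(abs(win_mean(-40, -1) / base - params$dip), 0.06)
  expect_gt(win_mean(30, 100), win_mean(10, 25) * 2 / 2.5 * 0.9)  # second bump stronger
})

test_that("catalog recovers >= 95% of true endpoints as majors at depth 1e5", {
  sim <- make_genome(5, seed = 27)
  counts <- simulate_endpoint_counts(sim, "wt", 1e5, seed = 28)
  majors <- select_major_isoforms(build_catalog(counts, "yeast"), "yeast")
  truth_keys <- paste(sim$truth$endpoints$gene_id, sim$truth$endpoints$offset)
  found <- paste(majors$gene_id, majors$offset)
  expect_gte(mean(truth_keys %in% found), 0.95)
})

test_that("decoy fixture plants AATAAA hexamers where it says", {
  fix <- make_decoy_fixture(n_introns = 1, hexamers_per_intron = 5, seed = 29)
  for (i in seq_len(nrow(fix$hexamers))) {
    h <- fix$hexamers[i, ]
    expect_identical(fetch_seq(fix$genome, h$chrom, h$start, h$start + 6L, "+"), "AATAAA")
  }
  flat <- simulate_flat_coverage(fix$genome, "+", 5000, seed = 30)
  expect_lt(abs(coverage_total(flat) - 5000) / 5000, 0.1)
})

test_that("synthetic datasets write to standard formats alongside truth", {
  sim <- make_genome(2, seed = 31)
  dir <- withr::local_tempdir()
  write_synthetic(sim, dir)
  expect_identical(as.character(read_genome(file.path(dir, "genome.fa"))),
                   as.character(sim$genome))
  back <- read_annotation(file.path(dir, "genes.tsv"), "yeast")
  expect_equal(back$gene_id, sim$genes$gene_id)
  tr <- read.delim(file.path(dir, "truth_endpoints.tsv"))
  expect_equal(nrow(tr), nrow(sim$truth$endpoints))
})
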
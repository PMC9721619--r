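#' Default nascent-occupancy model parameters
#'
#' Occupancy around a poly(A) site is modelled as a flat baseline multiplied by
#' a dip over the 40 nt upstream of the site (decreasing occupancy as Pol II
#' approaches the site) and a biphasic increase downstream: a first bump at
#' +10..+25 and a second, stronger bump at +30..+100, all in transcript
#' coordinates relative to the cleavage base.
#'
#' @return A list of window/amplitude parameters.
#' @export
occupancy_params <- function() {
  list(dip_window = c(-40L, -1L), dip = 0.6,
       bump1_window = c(10L, 25L), bump1 = 1.5,
       bump2_window = c(30L, 100L), bump2 = 2.5)
}

#' Generate a synthetic genome with clustered poly(A) ground truth
#'
#' Builds one chromosome per gene: a gene body ending in a TAA stop codon, a
#' 3'UTR of `utr_len` nt (the ~200-nt end zone scale) carrying clustered
#' poly(A) endpoints, and a downstream pad wide enough for +100 windows and
#' metagene flanks. Every true endpoint is placed on a non-A sense base, so the
#' internal-priming exclusion used on the analysis side can recover the truth.
#'
#' Each cluster gets a tilt factor `r`: in a speed-mutant genotype the
#' mutant/wild-type usage of positions within the cluster scales as `r^d` for a
#' position `d` nt into the cluster, and crossing a cluster boundary multiplies
#' utilization by a single constant (`between_factor`, default 0.98), so
#' boundary pairs sit at 0.98 regardless of distance. When `gc_coupling > 0`,
#' the GC fraction of the 18-nt element at +13..+30 downstream of each
#' cluster's 3'-most endpoint increases linearly with `|log r|`, coupling
#' sequence composition to elongation-rate sensitivity.
#'
#' @param n_genes Number of genes (one chromosome each).
#' @param utr_len 3'UTR length in nt (default 200, the end-zone scale).
#' @param cluster_sizes Integer vector of isoform counts per cluster, applied
#'   to every gene.
#' @param intra_spacing Spacing in nt between consecutive endpoints within a
#'   cluster (must be <= the 4-nt cluster gap).
#' @param inter_gaps Candidate distances (3'-most of one cluster to 5'-most of
#'   the next) sampled per boundary; all must exceed the cluster gap + the
#'   18-nt GC element offset so elements never overlap the next cluster.
#' @param first_offset Transcript offset of the first endpoint.
#' @param tilt Scalar cluster tilt factor applied to all clusters, or `NULL`
#'   to sample per cluster from `tilt_range`.
#' @param tilt_range Range for per-cluster tilt factors when `tilt` is `NULL`.
#' @param between_factor Utilization factor applied at each cluster boundary.
#' @param gc_coupling Strength in [0, 1] of the GC / |log r| coupling; 0 leaves
#'   the +13..+30 sequence at background composition.
#' @param base_gc Background genome GC fraction.
#' @param lead_len,tail_len Pad lengths around the UTR.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `pa_sim`: `genome` (DNAStringSet), `genes`
#'   (annotation data.frame with window overrides), and `truth` with
#'   `endpoints` (gene_id, offset, weight, cluster, r, u_mut), `clusters`
#'   (gene_id, cluster, size, start, end, r, gc_elem), `occupancy` parameters
#'   and the generator parameters.
#' @export
make_genome <- function(n_genes, utr_len = 200L, cluster_sizes = c(6L, 5L),
                        intra_spacing = 1L, inter_gaps = c(40L, 50L, 60L),
                        first_offset = 20L, tilt = NULL, tilt_range = c(0.78, 0.98),
                        between_factor = 0.98, gc_coupling = 0, base_gc = 0.4,
                        lead_len = 150L, tail_len = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_genes >= 0, utr_len > 0, all(cluster_sizes >= 1), intra_spacing >= 1,
            gc_coupling >= 0, gc_coupling <= 1)
  if (any(inter_gaps <= 4L)) stop("inter-cluster gaps must exceed the 4-nt cluster gap")

  empty <- function() {
    list(genome = Biostrings::DNAStringSet(),
         genes = make_gene_models(data.frame(gene_id = character(0), chrom = character(0),
                                             strand = character(0), stop_codon_end = integer(0))[0, ],
                                  "yeast")[0, ],
         truth = list(endpoints = data.frame(gene_id = character(0), offset = integer(0),
                                             weight = numeric(0), cluster = integer(0),
                                             r = numeric(0), u_mut = numeric(0)),
                      clusters = data.frame(gene_id = character(0), cluster = integer(0),
                                            size = integer(0), start = integer(0),
                                            end = integer(0), r = numeric(0), gc_elem = numeric(0)),
                      occupancy = occupancy_params(),
                      params = list(utr_len = utr_len, between_factor = between_factor,
                                    gc_coupling = gc_coupling, base_gc = base_gc)))
  }
  if (n_genes == 0L) {
    out <- empty()
    class(out) <- "pa_sim"
    return(out)
  }

  # worst-case span check before drawing anything per gene
  max_span <- first_offset +
    sum((cluster_sizes - 1L) * intra_spacing) +
    (length(cluster_sizes) - 1L) * max(inter_gaps)
  if (max_span + 30L > utr_len) {
    stop("cluster layout needs up to ", max_span + 30L, " nt but utr_len is ", utr_len)
  }

  chrom_len <- lead_len + utr_len + tail_len
  base_probs <- c(A = (1 - base_gc) / 2, C = base_gc / 2, G = base_gc / 2, T = (1 - base_gc) / 2)
  lr_lo <- abs(log(max(tilt_range))); lr_hi <- abs(log(min(tilt_range)))

  seqs <- character(n_genes)
  genes <- vector("list", n_genes)
  eps <- vector("list", n_genes)
  cls <- vector("list", n_genes)

  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("g%04d", g)
    chrom <- sprintf("chr%04d", g)
    stop_end <- lead_len - 1L

    # endpoint layout
    offs <- integer(0); cluster_of <- integer(0)
    start <- first_offset
    for (j in seq_along(cluster_sizes)) {
      members <- start + intra_spacing * (seq_len(cluster_sizes[j]) - 1L)
      offs <- c(offs, members)
      cluster_of <- c(cluster_of, rep(j, cluster_sizes[j]))
      if (j < length(cluster_sizes)) start <- members[length(members)] + sample(inter_gaps, 1L)
    }
    n_ep <- length(offs)
    weight <- stats::runif(n_ep, 0.8, 1.25)
    r_cluster <- if (is.null(tilt)) stats::runif(length(cluster_sizes), tilt_range[1], tilt_range[2])
                 else rep(tilt, length(cluster_sizes))

    # sequence
    s <- sample(names(base_probs), chrom_len, replace = TRUE, prob = base_probs)
    s[(lead_len - 2L):lead_len] <- c("T", "A", "A")
    ep_genomic <- lead_len + offs  # 0-based pos = stop_end + off; index = pos + 1
    is_a <- s[ep_genomic] == "A"
    if (any(is_a)) s[ep_genomic[is_a]] <- sample(c("C", "G", "T"), sum(is_a), replace = TRUE)

    # GC element at +13..+30 of each cluster's 3'-most endpoint
    cl_start <- tapply(offs, cluster_of, min)
    cl_end <- tapply(offs, cluster_of, max)
    gc_elem <- numeric(length(cluster_sizes))
    for (j in seq_along(cluster_sizes)) {
      idx <- (lead_len + cl_end[j] + 13L):(lead_len + cl_end[j] + 30L)  # 1-based
      if (gc_coupling > 0) {
        z <- (abs(log(r_cluster[j])) - lr_lo) / (lr_hi - lr_lo)
        if (!is.finite(z)) z <- 0.5
        z <- min(max(z, 0), 1)
        target <- 0.25 + 0.5 * gc_coupling * z
        n_gc <- round(18L * target)
        pick <- sample(idx, n_gc)
        s[pick] <- sample(c("G", "C"), n_gc, replace = TRUE)
        s[setdiff(idx, pick)] <- sample(c("A", "T"), 18L - n_gc, replace = TRUE)
      }
      gc_elem[j] <- mean(s[idx] %in% c("G", "C"))
    }
    seqs[g] <- paste(s, collapse = "")

    # mutant utilization: r^d within a cluster, x between_factor per boundary
    u_start <- 1
    u_mut <- numeric(n_ep)
    for (j in seq_along(cluster_sizes)) {
      sel <- cluster_of == j
      d <- offs[sel] - cl_start[j]
      u_mut[sel] <- u_start * r_cluster[j]^d
      u_start <- u_start * r_cluster[j]^(cl_end[j] - cl_start[j]) * between_factor
    }

    genes[[g]] <- data.frame(gene_id = gene_id, chrom = chrom, strand = "+",
                             stop_codon_end = stop_end,
                             utr_upstream = 0L, utr_downstream = utr_len)
    eps[[g]] <- data.frame(gene_id = gene_id, offset = offs, weight = weight,
                           cluster = cluster_of, r = r_cluster[cluster_of], u_mut = u_mut)
    cls[[g]] <- data.frame(gene_id = gene_id, cluster = seq_along(cluster_sizes),
                           size = as.integer(cluster_sizes),
                           start = as.integer(cl_start), end = as.integer(cl_end),
                           r = r_cluster, gc_elem = gc_elem)
  }

  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- sprintf("chr%04d", seq_len(n_genes))
  out <- list(genome = genome,
              genes = do.call(rbind, genes),
              truth = list(endpoints = do.call(rbind, eps),
                           clusters = do.call(rbind, cls),
                           occupancy = occupancy_params(),
                           params = list(utr_len = utr_len, between_factor = between_factor,
                                         gc_coupling = gc_coupling, base_gc = base_gc,
                                         tilt = tilt, tilt_range = tilt_range)))
  class(out) <- "pa_sim"
  out
}

#' Per-endpoint mutant/wild-type utilization implied by the truth
#'
#' Recomputes (or overrides) the generator's utilization model: usage scales as
#' `r^d` within a cluster and by `between_factor` across each cluster boundary.
#'
#' @param sim A `pa_sim` object.
#' @param tilt Optional scalar tilt overriding the per-cluster truth factors.
#' @param between_factor Per-boundary factor.
#' @return Numeric vector parallel to `sim$truth$endpoints`.
#' @export
mutant_utilization <- function(sim, tilt = NULL, between_factor = NULL) {
  ep <- sim$truth$endpoints
  if (is.null(tilt) && is.null(between_factor)) return(ep$u_mut)
  bf <- if (is.null(between_factor)) sim$truth$params$between_factor else between_factor
  u <- numeric(nrow(ep))
  for (gid in unique(ep$gene_id)) {
    sel <- ep$gene_id == gid
    e <- ep[sel, ]
    u_start <- 1; ug <- numeric(nrow(e))
    for (j in sort(unique(e$cluster))) {
      csel <- e$cluster == j
      r <- if (is.null(tilt)) e$r[csel][1] else tilt
      d <- e$offset[csel] - min(e$offset[csel])
      ug[csel] <- u_start * r^d
      u_start <- u_start * r^max(d) * bf
    }
    u[sel] <- ug
  }
  u
}

#' Simulate poly(A) endpoint read counts
#'
#' Draws, per gene, a multinomial sample of `depth` reads over the gene's true
#' endpoints. Wild-type probabilities are the baseline weights; the mutant
#' genotype reweights them by the utilization model (see
#' [mutant_utilization()]), so empirical endpoint frequencies converge to the
#' truth as depth grows.
#'
#' @param sim A `pa_sim` object.
#' @param genotype `"wt"` or `"mutant"`.
#' @param depth Reads per gene.
#' @param tilt Optional scalar tilt override for the mutant genotype.
#' @param between_factor Optional per-boundary factor override.
#' @param seed Integer seed.
#' @return Endpoint-count data.frame (gene_id, offset, count), zero-count
#'   endpoints omitted.
#' @export
simulate_endpoint_counts <- function(sim, genotype = c("wt", "mutant"), depth,
                                     tilt = NULL, between_factor = NULL, seed = NULL) {
  genotype <- match.arg(genotype)
  if (depth < 0) stop("depth must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ep <- sim$truth$endpoints
  if (nrow(ep) == 0L || depth == 0) {
    return(data.frame(gene_id = character(0), offset = integer(0), count = numeric(0)))
  }
  w <- ep$weight
  if (genotype == "mutant") w <- w * mutant_utilization(sim, tilt, between_factor)
  counts <- numeric(nrow(ep))
  for (i in split(seq_len(nrow(ep)), ep$gene_id)) {
    counts[i] <- as.numeric(stats::rmultinom(1, depth, w[i]))
  }
  out <- ep[c("gene_id", "offset")]
  out$count <- counts
  out <- out[out$count > 0, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$gene_id, out$offset), ]
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate 3' READS-style raw reads
#'
#' Each read carries 4 random nt, then a run of Ts standing in for the
#' reverse-complemented poly(A) tail (length 1 + geometric, mean `tail_mean`),
#' then the reverse complement of the sense-strand sequence ending at the
#' sampled endpoint. A fraction `artifact_rate` of reads are internal-priming
#' artifacts: their 3' ends sit immediately upstream of a genomic sense-strand
#' A-run and their T count never exceeds that run, so the genome fully accounts
#' for their tails and the analysis-side filter discards them.
#'
#' @param sim A `pa_sim` object.
#' @param genotype `"wt"` or `"mutant"`.
#' @param depth Total number of reads.
#' @param artifact_rate Fraction in [0, 1) of internal-priming artifact reads.
#' @param tilt Optional scalar mutant tilt override.
#' @param seed Integer seed.
#' @param tail_mean Mean non-templated tail length (minimum 1).
#' @param body_len Genome-matching read body length before truncation.
#' @return A list: `reads` (named character vector of read sequences),
#'   `truth` (data.frame read_id, chrom, pos, strand, class, gene_id, offset).
#' @export
simulate_polyA_reads <- function(sim, genotype = c("wt", "mutant"), depth,
                                 artifact_rate = 0, tilt = NULL, seed = NULL,
                                 tail_mean = 8, body_len = 40L) {
  genotype <- match.arg(genotype)
  if (depth < 0) stop("depth must be >= 0")
  if (artifact_rate < 0 || artifact_rate >= 1) stop("artifact_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  empty <- list(reads = stats::setNames(character(0), character(0)),
                truth = data.frame(read_id = character(0), chrom = character(0),
                                   pos = integer(0), strand = character(0),
                                   class = character(0), gene_id = character(0),
                                   offset = integer(0)))
  if (depth == 0) return(empty)
  ep <- sim$truth$endpoints
  if (nrow(ep) == 0L) return(empty)
  genes <- sim$genes
  gidx <- match(ep$gene_id, genes$gene_id)

  n_art <- stats::rbinom(1, depth, artifact_rate)
  n_true <- depth - n_art

  w <- ep$weight
  if (genotype == "mutant") w <- w * mutant_utilization(sim, tilt)
  # genes sampled uniformly, endpoints by weight within gene
  gene_pick <- sample(unique(ep$gene_id), n_true, replace = TRUE)
  rows <- integer(n_true)
  for (gid in unique(gene_pick)) {
    sel <- gene_pick == gid
    cand <- which(ep$gene_id == gid)
    rows[sel] <- cand[sample.int(length(cand), sum(sel), replace = TRUE, prob = w[cand])]
  }

  make_read <- function(chrom, pos, strand, t_len) {
    body <- if (strand == "+") {
      lo <- max(0L, pos - body_len + 1L)
      fetch_seq(sim$genome, chrom, lo, pos + 1L, "+")
    } else {
      hi <- min(chrom_lengths(sim$genome)[[chrom]], pos + body_len)
      fetch_seq(sim$genome, chrom, pos, hi, "-")
    }
    paste0(paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE), collapse = ""),
           strrep("T", t_len), revcomp_chr(body))
  }

  tails <- 1L + stats::rgeom(n_true, 1 / tail_mean)
  true_reads <- character(n_true)
  true_truth <- vector("list", n_true)
  for (i in seq_len(n_true)) {
    e <- ep[rows[i], ]
    gene <- genes[gidx[rows[i]], ]
    pos <- offset_to_genomic(gene, e$offset)
    true_reads[i] <- make_read(gene$chrom, pos, gene$strand, tails[i])
    true_truth[[i]] <- data.frame(read_id = sprintf("true|%d|%s|%d", i, e$gene_id, e$offset),
                                  chrom = gene$chrom, pos = pos, strand = gene$strand,
                                  class = "true", gene_id = e$gene_id, offset = e$offset)
  }

  art_reads <- character(0); art_truth <- list()
  if (n_art > 0) {
    # candidate artifact sites: UTR positions followed by a sense A-run
    cand <- list()
    for (g in seq_len(nrow(genes))) {
      gene <- genes[g, ]
      gpos <- offset_to_genomic(gene, c(1L, gene$utr_downstream))
      utr <- fetch_seq(sim$genome, gene$chrom, min(gpos), max(gpos) + 1L, gene$strand)
      bases <- strsplit(utr, "")[[1]]
      # run_after[o]: length of the sense A-run starting at offset o+1
      run_after <- integer(length(bases))
      run <- 0L
      for (o in rev(seq_along(bases))) {
        run_after[o] <- run
        run <- if (bases[o] == "A") run + 1L else 0L
      }
      ok <- which(run_after >= 1L & bases != "A")
      if (length(ok)) cand[[length(cand) + 1L]] <-
        data.frame(gene_id = gene$gene_id, offset = ok, run = run_after[ok])
    }
    cand <- do.call(rbind, cand)
    if (!is.null(cand) && nrow(cand) > 0) {
      pick <- cand[sample.int(nrow(cand), n_art, replace = TRUE), ]
      t_art <- pmin(1L + stats::rgeom(n_art, 1 / tail_mean), pick$run)
      art_reads <- character(n_art)
      art_truth <- vector("list", n_art)
      for (i in seq_len(n_art)) {
        gene <- genes[match(pick$gene_id[i], genes$gene_id), ]
        pos <- offset_to_genomic(gene, pick$offset[i])
        art_reads[i] <- make_read(gene$chrom, pos, gene$strand, t_art[i])
        art_truth[[i]] <- data.frame(read_id = sprintf("art|%d|%s|%d", i, pick$gene_id[i], pick$offset[i]),
                                     chrom = gene$chrom, pos = pos, strand = gene$strand,
                                     class = "artifact", gene_id = pick$gene_id[i],
                                     offset = pick$offset[i])
      }
    }
  }

  truth <- do.call(rbind, c(true_truth, art_truth))
  reads <- stats::setNames(c(true_reads, art_reads), truth$read_id)
  list(reads = reads, truth = truth)
}

#' Write reads to FASTQ
#'
#' @param reads Named character vector of read sequences.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- names(reads)
  q <- Biostrings::PhredQuality(vapply(nchar(reads), function(n) strrep("I", n), ""))
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(x, q), path)
  invisible(path)
}

#' Simulate a nascent 3'-end occupancy track
#'
#' Expected coverage at each base is a flat baseline multiplied by the dip and
#' bump factors of the occupancy model around every true endpoint (in
#' transcript direction); observed counts are Poisson. The baseline is chosen
#' so that the expected track total equals `depth`.
#'
#' @param sim A `pa_sim` object.
#' @param depth Expected total read count of the track.
#' @param params Occupancy model (default the simulation's truth parameters).
#' @param seed Integer seed.
#' @return Coverage data.frame (see [end_coverage()]).
#' @export
simulate_enetseq <- function(sim, depth, params = NULL, seed = NULL) {
  if (depth < 0) stop("depth must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- sim$truth$occupancy
  if (depth == 0 || nrow(sim$genes) == 0L) return(end_coverage())
  lens <- chrom_lengths(sim$genome)
  lam <- lapply(seq_len(nrow(sim$genes)), function(g) {
    gene <- sim$genes[g, ]
    f <- rep(1, lens[[gene$chrom]])
    eps <- sim$truth$endpoints[sim$truth$endpoints$gene_id == gene$gene_id, ]
    apply_win <- function(f, pos, win, amp) {
      offs <- seq.int(win[1], win[2])
      p <- if (gene$strand == "+") pos + offs else pos - offs
      p <- p[p >= 0 & p < length(f)]
      f[p + 1L] <- f[p + 1L] * amp
      f
    }
    for (off in eps$offset) {
      pos <- offset_to_genomic(gene, off)
      f <- apply_win(f, pos, params$dip_window, params$dip)
      f <- apply_win(f, pos, params$bump1_window, params$bump1)
      f <- apply_win(f, pos, params$bump2_window, params$bump2)
    }
    f
  })
  total_units <- sum(vapply(lam, sum, 0))
  base <- depth / total_units
  parts <- lapply(seq_len(nrow(sim$genes)), function(g) {
    gene <- sim$genes[g, ]
    counts <- stats::rpois(length(lam[[g]]), base * lam[[g]])
    keep <- counts > 0
    data.frame(chrom = gene$chrom, pos = which(keep) - 1L,
               strand = gene$strand, count = counts[keep])
  })
  do.call(rbind, parts)
}

#' Synthetic long-intron fixture with decoy AATAAA hexamers
#'
#' Builds one chromosome per intron with AATAAA hexamers planted at regular
#' spacing on the plus strand, for exercising decoy-anchor selection and
#' metagenes on bump-free occupancy.
#'
#' @param n_introns Number of introns (one chromosome each).
#' @param intron_len Intron length in nt (> 10 kb to pass the length filter).
#' @param hexamers_per_intron Number of planted AATAAA instances.
#' @param base_gc Background GC fraction.
#' @param seed Integer seed.
#' @return A list: `genome`, `introns` (chrom, start, end, strand),
#'   `hexamers` (chrom, start, strand).
#' @export
make_decoy_fixture <- function(n_introns = 2L, intron_len = 12000L,
                               hexamers_per_intron = 30L, base_gc = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - base_gc) / 2, C = base_gc / 2, G = base_gc / 2, T = (1 - base_gc) / 2)
  starts <- round(seq(400, intron_len - 400, length.out = hexamers_per_intron))
  seqs <- character(n_introns); hx <- vector("list", n_introns)
  for (i in seq_len(n_introns)) {
    s <- sample(names(probs), intron_len, replace = TRUE, prob = probs)
    for (st in starts) s[(st + 1L):(st + 6L)] <- c("A", "A", "T", "A", "A", "A")
    seqs[i] <- paste(s, collapse = "")
    hx[[i]] <- data.frame(chrom = sprintf("intron%02d", i), start = starts, strand = "+")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- sprintf("intron%02d", seq_len(n_introns))
  list(genome = genome,
       introns = data.frame(chrom = names(genome), start = 0L, end = intron_len, strand = "+"),
       hexamers = do.call(rbind, hx))
}

#' Simulate a flat (bump-free) coverage track
#'
#' Poisson counts at a constant per-base rate over every chromosome of a
#' genome; the expected total equals `depth`.
#'
#' @param genome A `DNAStringSet`.
#' @param strand Strand of the track.
#' @param depth Expected total count.
#' @param seed Integer seed.
#' @return Coverage data.frame.
#' @export
simulate_flat_coverage <- function(genome, strand = "+", depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- chrom_lengths(genome)
  rate <- depth / sum(lens)
  parts <- lapply(names(lens), function(ch) {
    counts <- stats::rpois(lens[[ch]], rate)
    keep <- counts > 0
    data.frame(chrom = ch, pos = which(keep) - 1L, strand = strand, count = counts[keep])
  })
  do.call(rbind, parts)
}

#' Write a synthetic dataset to disk
#'
#' Writes the genome FASTA, the annotation TSV and the ground-truth endpoint
#' and cluster tables alongside each other.
#'
#' @param sim A `pa_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  write_annotation(sim$genes, file.path(dir, "genes.tsv"))
  utils::write.table(sim$truth$endpoints, file.path(dir, "truth_endpoints.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$clusters, file.path(dir, "truth_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
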
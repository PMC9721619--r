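#' Collapse mapped nascent reads to 3'-end coverage
#'
#' Removes reads with mapping quality <= 10 and counts each surviving read at
#' the single base corresponding to the RNA 3' end: the last aligned base in
#' transcript direction (alignment end for plus-strand reads, alignment start
#' for minus-strand reads). Optional region filters keep only reads within
#' `near_genes_bp` of a protein-coding gene and drop reads overlapping
#' excluded (e.g. snoRNA) intervals, when those annotations are provided.
#'
#' @param reads data.frame (chrom, start, end, strand, mapq); `start`/`end`
#'   0-based half-open.
#' @param min_mapq Strict lower bound on mapping quality (default 10: MAPQ 10
#'   itself is removed).
#' @param genes Optional gene-model data.frame for the proximity filter.
#' @param near_genes_bp Proximity window around gene stop codons.
#' @param exclude Optional data.frame (chrom, start, end) of intervals whose
#'   reads are dropped.
#' @return Coverage data.frame (see [end_coverage()]).
#' @export
collapse_reads <- function(reads, min_mapq = 10, genes = NULL, near_genes_bp = 5000L,
                           exclude = NULL) {
  if (nrow(reads) == 0L) return(end_coverage())
  reads <- reads[reads$mapq > min_mapq, , drop = FALSE]
  if (!is.null(exclude) && nrow(reads) > 0L) {
    drop <- rep(FALSE, nrow(reads))
    for (i in seq_len(nrow(exclude))) {
      drop <- drop | (reads$chrom == exclude$chrom[i] &
                        reads$end > exclude$start[i] & reads$start < exclude$end[i])
    }
    reads <- reads[!drop, , drop = FALSE]
  }
  if (!is.null(genes) && nrow(reads) > 0L) {
    keep <- rep(FALSE, nrow(reads))
    for (g in seq_len(nrow(genes))) {
      gene <- genes[g, ]
      keep <- keep | (reads$chrom == gene$chrom &
                        reads$start < gene$stop_codon_end + near_genes_bp &
                        reads$end > gene$stop_codon_end - near_genes_bp)
    }
    reads <- reads[keep, , drop = FALSE]
  }
  if (nrow(reads) == 0L) return(end_coverage())
  pos <- ifelse(reads$strand == "+", reads$end - 1L, reads$start)
  end_coverage(reads$chrom, pos, reads$strand, rep(1, nrow(reads)))
}

#' Downsample coverage tracks to a matched total
#'
#' Subsamples each library's reads without replacement to the minimum library
#' total, so the compared tracks carry the same number of reads. Seeded and
#' deterministic; libraries already at the minimum are returned unchanged.
#'
#' @param libraries Named list of coverage data.frames.
#' @param seed Integer seed.
#' @return List of coverage data.frames with equal totals.
#' @export
downsample_matched <- function(libraries, seed = NULL) {
  if (length(libraries) < 2L) stop("need at least 2 libraries to match")
  if (!is.null(seed)) set.seed(seed)
  totals <- vapply(libraries, coverage_total, 0)
  target <- min(totals)
  lapply(libraries, function(cov) {
    tot <- coverage_total(cov)
    if (tot == target) return(cov)
    picked <- sample.int(tot, target)  # reads without replacement from the multiset
    ends <- cumsum(cov$count)
    row_of <- findInterval(picked - 1L, ends) + 1L
    counts <- tabulate(row_of, nbins = nrow(cov))
    out <- cov[counts > 0, , drop = FALSE]
    out$count <- counts[counts > 0]
    rownames(out) <- NULL
    out
  })
}

#' Select poly(A) anchor sites by read support
#'
#' Keeps the poly(A) sites that carry, in every library, at least `min_total`
#' reads within `flank` nt of the site and at least `min_downstream` reads in
#' the first `flank` nt downstream (+1..+flank in transcript direction).
#'
#' @param sites data.frame (chrom, pos, strand) of candidate poly(A) sites,
#'   `pos` 0-based cleavage base.
#' @param libraries Named list of coverage data.frames (downsampled).
#' @param min_total Minimum reads within +/- `flank` nt (default 20).
#' @param min_downstream Minimum reads in +1..+flank (default 1).
#' @param flank Window half-width in nt (default 100).
#' @return The selected rows of `sites`, with a `class` column set to
#'   `"polyA"`.
#' @export
select_polyA_anchors <- function(sites, libraries, min_total = 20, min_downstream = 1,
                                 flank = 100L) {
  if (nrow(sites) == 0L) return(cbind(sites, class = character(0)))
  keep <- rep(TRUE, nrow(sites))
  for (cov in libraries) {
    for (i in which(keep)) {
      offs <- -flank:flank
      p <- if (sites$strand[i] == "+") sites$pos[i] + offs else sites$pos[i] - offs
      counts <- coverage_query(cov, rep(sites$chrom[i], length(p)), p,
                               rep(sites$strand[i], length(p)))
      if (sum(counts) < min_total || sum(counts[offs >= 1]) < min_downstream) keep[i] <- FALSE
    }
  }
  out <- sites[keep, , drop = FALSE]
  out$class <- rep("polyA", nrow(out))
  rownames(out) <- NULL
  out
}

#' Find decoy intronic AATAAA anchor sites
#'
#' Locates sense-strand AATAAA hexamers in introns strictly longer than
#' `min_intron_len` (10 kb), re-centres each so the hexamer occupies offsets
#' -25..-20 relative to a decoy cleavage site (anchor = hexamer 5' start + 25
#' in transcript direction), and keeps anchors with at least `min_total` reads
#' within `flank` nt and at least one read in +1..+flank, in every library.
#'
#' @param genome A `DNAStringSet`.
#' @param introns data.frame (chrom, start, end, strand), 0-based half-open.
#' @param libraries Named list of coverage data.frames.
#' @param min_intron_len Strict minimum intron length (default 10,000).
#' @param min_total Minimum reads within +/- `flank` (default 10).
#' @param flank Window half-width in nt.
#' @return data.frame (chrom, pos, strand, class = "decoy").
#' @export
find_decoy_anchors <- function(genome, introns, libraries, min_intron_len = 10000L,
                               min_total = 10, flank = 100L) {
  introns <- introns[introns$end - introns$start > min_intron_len, , drop = FALSE]
  anchors <- list()
  for (i in seq_len(nrow(introns))) {
    intr <- introns[i, ]
    s <- fetch_seq(genome, intr$chrom, intr$start, intr$end, intr$strand)
    hits <- Biostrings::matchPattern("AATAAA", Biostrings::DNAString(s))
    if (length(hits) == 0L) next
    q <- BiocGenerics::start(hits)  # 1-based sense position of hexamer start
    pos <- if (intr$strand == "+") intr$start + (q - 1L) + 25L
           else intr$end - q - 25L
    anchors[[length(anchors) + 1L]] <- data.frame(chrom = intr$chrom, pos = pos,
                                                  strand = intr$strand)
  }
  anchors <- do.call(rbind, anchors)
  if (is.null(anchors)) {
    return(data.frame(chrom = character(0), pos = integer(0), strand = character(0),
                      class = character(0)))
  }
  out <- select_polyA_anchors(anchors, libraries, min_total = min_total,
                              min_downstream = 1, flank = flank)
  out$class <- rep("decoy", nrow(out))
  out
}

#' Build an occupancy and base-composition metagene
#'
#' Aggregates strand-oriented coverage across anchors at each offset of a
#' fixed flank (default -100..+100 in transcript direction; minus-strand
#' anchors are flipped so offsets always increase 5' to 3'). Per offset the
#' signal is the sum (or per-site mean) of coverage across anchors per
#' library, and the AT composition is the percentage of anchors whose
#' sense-strand base at that offset is A or T (a per-site median variant is
#' available). Anchors whose flank runs off the contig are dropped.
#'
#' @param anchors data.frame (chrom, pos, strand).
#' @param libraries Named list of coverage data.frames.
#' @param genome A `DNAStringSet`.
#' @param flank Flank half-width in nt (default 100).
#' @param stat `"sum"` (default) or `"mean"` per-site signal aggregation.
#' @param at_stat `"percent"` (default) or `"median"` AT statistic.
#' @return data.frame with `offset`, one signal column per library, and
#'   `at_percent`; the `n_anchors` attribute gives the anchors used.
#' @export
build_metagene <- function(anchors, libraries, genome, flank = 100L,
                           stat = c("sum", "mean"), at_stat = c("percent", "median")) {
  stat <- match.arg(stat); at_stat <- match.arg(at_stat)
  if (nrow(anchors) == 0L) stop("no anchor sites")
  lens <- chrom_lengths(genome)
  lo <- ifelse(anchors$strand == "+", anchors$pos - flank, anchors$pos - flank)
  hi <- anchors$pos + flank
  ok <- lo >= 0L & hi < lens[anchors$chrom]
  anchors <- anchors[ok, , drop = FALSE]
  if (nrow(anchors) == 0L) stop("all anchor flanks run off the contig")

  offs <- seq.int(-flank, flank)
  n_off <- length(offs)
  sig <- matrix(0, nrow = n_off, ncol = length(libraries),
                dimnames = list(NULL, names(libraries)))
  at <- matrix(FALSE, nrow = nrow(anchors), ncol = n_off)
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    p <- if (a$strand == "+") a$pos + offs else a$pos - offs
    for (l in seq_along(libraries)) {
      sig[, l] <- sig[, l] + coverage_query(libraries[[l]], rep(a$chrom, n_off), p,
                                            rep(a$strand, n_off))
    }
    s <- fetch_seq(genome, a$chrom, min(p), max(p) + 1L, a$strand)
    at[i, ] <- strsplit(s, "")[[1]] %in% c("A", "T")
  }
  if (stat == "mean") sig <- sig / nrow(anchors)
  at_col <- if (at_stat == "percent") 100 * colMeans(at) else 100 * apply(at, 2L, stats::median)
  out <- data.frame(offset = offs)
  for (l in colnames(sig)) out[[l]] <- sig[, l]
  out$at_percent <- as.numeric(at_col)
  attr(out, "n_anchors") <- nrow(anchors)
  out
}
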
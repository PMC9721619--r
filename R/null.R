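#' Eligible shuffle positions of a gene
#'
#' All 3'UTR transcript offsets whose sense-strand base is not an A: positions
#' with genomic A residues are excluded because a genomically encoded terminal
#' A cannot be distinguished from an A derived from the poly(A) tail.
#'
#' @param gene One row of a gene-model data.frame.
#' @param genome A `DNAStringSet`.
#' @param utr_len 3'UTR extent in nt (default the gene's downstream window).
#' @return Integer offsets (subset of 1..utr_len), ascending.
#' @export
eligible_positions <- function(gene, genome, utr_len = NULL) {
  if (is.null(utr_len)) utr_len <- gene$utr_downstream
  gpos <- offset_to_genomic(gene, c(1L, utr_len))
  utr <- fetch_seq(genome, gene$chrom, min(gpos), max(gpos) + 1L, gene$strand)
  which(strsplit(utr, "")[[1]] != "A")
}

pattern_to_hist <- function(pattern, k) {
  hist <- integer(k)
  if (length(pattern)) {
    sizes <- as.integer(names(pattern))
    if (any(sizes > k)) return(NULL)  # impossible for k isoforms
    hist[sizes] <- as.integer(pattern)
  }
  hist
}

#' Monte-Carlo probability of an observed cluster pattern
#'
#' Repeatedly draws, without replacement, as many positions as the gene has
#' major isoforms, uniformly from the eligible (non-A) 3'UTR positions, and
#' counts the shuffles whose cluster-size pattern is identical (all sizes, all
#' counts) to the observed pattern. The probability is `matches / n_shuffles`;
#' when no shuffle matches, it is floored at `1 / n_shuffles` (so 100,000
#' shuffles give p = 0.00001).
#'
#' @param eligible Integer vector of eligible offsets.
#' @param observed Observed major-isoform offsets (preferred), or a named
#'   cluster-size pattern as returned by [pattern_of()] together with `k`.
#' @param n_shuffles Number of shuffles (default 100,000).
#' @param max_gap Maximal intra-cluster gap in nt.
#' @param k Number of major isoforms (required when `observed` is a pattern).
#' @param seed Optional integer seed.
#' @return A list: `n_isoforms`, `n_shuffles`, `matches`, `p_raw`
#'   (matches/n, unfloored), `p` (floored), `neg_log10_p`, and
#'   `null_size_counts` (numeric, cluster counts per size 1..k accumulated
#'   over all shuffles, for genome-wide aggregation).
#' @export
pattern_probability <- function(eligible, observed, n_shuffles = 1e5, max_gap = 4L,
                                k = NULL, seed = NULL) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(observed))) {
    offs <- sort(as.integer(observed))
    k <- length(offs)
    hist <- pattern_to_hist(pattern_of(summarize_clusters(offs, max_gap)$size), k)
  } else {
    if (is.null(k)) stop("k is required when observed is a pattern")
    hist <- pattern_to_hist(observed, k)
  }
  if (k < 1) stop("need at least one isoform")
  if (k > length(eligible)) {
    stop("gene has ", k, " major isoforms but only ", length(eligible), " eligible positions")
  }
  if (is.null(hist)) {  # pattern names a size larger than k: unreachable
    res <- list(matches = 0, null_size_counts = numeric(k))
  } else {
    res <- cpp_pattern_shuffle(as.integer(eligible), as.integer(k),
                               as.integer(n_shuffles), as.integer(max_gap), hist)
  }
  p_raw <- res$matches / n_shuffles
  p <- max(p_raw, 1 / n_shuffles)
  list(n_isoforms = k, n_shuffles = as.integer(n_shuffles), matches = res$matches,
       p_raw = p_raw, p = p, neg_log10_p = -log10(p),
       null_size_counts = res$null_size_counts)
}

#' Exact probability of an observed cluster pattern
#'
#' Full enumeration over all `choose(|eligible|, k)` position subsets; the
#' exact-oracle counterpart of [pattern_probability()]. Errors when the
#' enumeration exceeds `max_subsets`.
#'
#' @param eligible Integer vector of eligible offsets.
#' @param observed Observed offsets, or a named pattern with `k` supplied.
#' @param max_gap Maximal intra-cluster gap in nt.
#' @param k Number of isoforms when `observed` is a pattern.
#' @param max_subsets Combinatorial budget (default 1e6).
#' @return Exact probability in [0, 1].
#' @export
exact_pattern_probability <- function(eligible, observed, max_gap = 4L, k = NULL,
                                      max_subsets = 1e6) {
  if (is.null(names(observed))) {
    offs <- sort(as.integer(observed))
    k <- length(offs)
    target <- pattern_to_hist(pattern_of(summarize_clusters(offs, max_gap)$size), k)
  } else {
    if (is.null(k)) stop("k is required when observed is a pattern")
    target <- pattern_to_hist(observed, k)
  }
  if (is.null(target)) return(0)
  dist <- exact_pattern_distribution(eligible, k, max_gap, max_subsets)
  key <- paste(target, collapse = ",")
  p <- dist$probability[match(key, dist$pattern_key)]
  if (is.na(p)) 0 else p
}

#' Exact null distribution over cluster patterns
#'
#' Enumerates every k-subset of the eligible positions and tabulates the
#' probability of each distinct cluster-size pattern. Probabilities sum to 1.
#'
#' @param eligible Integer vector of eligible offsets.
#' @param k Number of isoforms drawn.
#' @param max_gap Maximal intra-cluster gap in nt.
#' @param max_subsets Combinatorial budget.
#' @return data.frame (pattern_key, probability); `pattern_key` is the
#'   comma-joined histogram of cluster counts for sizes 1..k.
#' @export
exact_pattern_distribution <- function(eligible, k, max_gap = 4L, max_subsets = 1e6) {
  m <- length(eligible)
  if (k < 1 || k > m) stop("k must be in 1..|eligible|")
  if (choose(m, k) > max_subsets) {
    stop("enumeration of choose(", m, ", ", k, ") subsets exceeds the budget")
  }
  elig <- sort(as.integer(eligible))
  combos <- utils::combn(m, k)
  keys <- apply(combos, 2L, function(ix) {
    sizes <- summarize_clusters(elig[ix], max_gap)$size
    paste(pattern_to_hist(pattern_of(sizes), k), collapse = ",")
  })
  tab <- table(keys)
  data.frame(pattern_key = names(tab),
             probability = as.numeric(tab) / ncol(combos))
}

#' Per-gene cluster-pattern probabilities across a catalog
#'
#' Runs [pattern_probability()] for every gene with at least two major
#' isoforms, drawing eligible positions from the genome.
#'
#' @param majors data.frame with `gene_id` and `offset` (major isoforms).
#' @param genes Gene-model data.frame.
#' @param genome A `DNAStringSet`.
#' @param n_shuffles Shuffles per gene (default 100,000).
#' @param max_gap Maximal intra-cluster gap in nt.
#' @param seed Optional integer seed (one RNG stream across genes).
#' @return data.frame (gene_id, n_isoforms, matches, p, neg_log10_p) plus a
#'   `null_size_counts` attribute (list per gene) for [aggregate_null()].
#' @export
gene_pattern_probabilities <- function(majors, genes, genome, n_shuffles = 1e5,
                                       max_gap = 4L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  by_gene <- split(majors$offset, majors$gene_id)
  by_gene <- by_gene[lengths(by_gene) >= 2L]
  rows <- vector("list", length(by_gene))
  nulls <- vector("list", length(by_gene))
  for (i in seq_along(by_gene)) {
    gid <- names(by_gene)[i]
    gene <- genes[match(gid, genes$gene_id), ]
    res <- pattern_probability(eligible_positions(gene, genome),
                               sort(by_gene[[i]]), n_shuffles, max_gap)
    rows[[i]] <- data.frame(gene_id = gid, n_isoforms = res$n_isoforms,
                            matches = res$matches, p = res$p,
                            neg_log10_p = res$neg_log10_p)
    nulls[[i]] <- res$null_size_counts
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), n_isoforms = integer(0),
                      matches = numeric(0), p = numeric(0), neg_log10_p = numeric(0))
  }
  structure(out, null_size_counts = nulls)
}

#' Aggregate shuffled cluster-size frequencies genome-wide
#'
#' Combines the per-gene null size-count accumulators across genes and all
#' shuffles, and converts them into percentages of all null clusters (the
#' shuffled analogue of [genomewide_frequencies()]).
#'
#' @param null_size_counts List of numeric vectors (counts per size 1..k) as
#'   produced by [pattern_probability()] / [gene_pattern_probabilities()].
#' @param max_bin Largest individually reported size.
#' @return data.frame (size, n, percent); `percent` sums to 100.
#' @export
aggregate_null <- function(null_size_counts, max_bin = 20L) {
  if (length(null_size_counts) < 1L) stop("need results from at least one gene")
  width <- max(lengths(null_size_counts))
  tot <- numeric(width)
  for (x in null_size_counts) tot[seq_along(x)] <- tot[seq_along(x)] + x
  binned <- numeric(max_bin + 1L)
  for (s in seq_along(tot)) {
    b <- if (s > max_bin) max_bin + 1L else s
    binned[b] <- binned[b] + tot[s]
  }
  data.frame(size = c(as.character(seq_len(max_bin)), paste0(">", max_bin)),
             n = binned, percent = 100 * binned / sum(binned))
}
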
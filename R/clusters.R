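#' Partition isoform endpoints into clusters
#'
#' A cluster is a maximal run of strictly increasing endpoint offsets in which
#' each consecutive pair differs by at most `max_gap` nt (gap measured as the
#' positional difference, so adjacent bases are 1 nt apart). Isoforms more
#' than `max_gap` from every other isoform form single-isoform clusters.
#'
#' @param offsets Strictly increasing integer offsets.
#' @param max_gap Maximal intra-cluster gap in nt (default 4).
#' @return Integer cluster index (1, 2, ...) per offset.
#' @export
detect_clusters <- function(offsets, max_gap = 4L) {
  if (max_gap < 1L) stop("max_gap must be >= 1")
  if (length(offsets) == 0L) return(integer(0))
  if (is.unsorted(offsets, strictly = TRUE)) stop("offsets must be strictly increasing")
  c(0L, cumsum(diff(offsets) > max_gap)) + 1L
}

#' Summarize clusters of one gene
#'
#' @param offsets Strictly increasing integer offsets.
#' @param max_gap Maximal intra-cluster gap in nt.
#' @return data.frame (cluster, size, start, end) with the 5'-most and
#'   3'-most member offset of each cluster.
#' @export
summarize_clusters <- function(offsets, max_gap = 4L) {
  cl <- detect_clusters(offsets, max_gap)
  if (length(cl) == 0L) {
    return(data.frame(cluster = integer(0), size = integer(0),
                      start = integer(0), end = integer(0)))
  }
  data.frame(cluster = sort(unique(cl)),
             size = as.integer(tabulate(cl)),
             start = as.integer(tapply(offsets, cl, min)),
             end = as.integer(tapply(offsets, cl, max)))
}

#' Cluster-size pattern of one gene
#'
#' The multiset of cluster sizes, as a named count vector: `pattern["3"]` is
#' the number of clusters containing exactly 3 isoforms.
#'
#' @param sizes Integer cluster sizes (e.g. `summarize_clusters()$size`).
#' @return Named integer vector, names ascending sizes; empty for no clusters.
#' @export
pattern_of <- function(sizes) {
  if (length(sizes) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(sizes)
  stats::setNames(as.integer(tab), names(tab))
}

#' Genome-wide cluster-size frequency table
#'
#' Tabulates clusters of every gene in a utilization series or major-isoform
#' catalog, and converts the size frequencies into percentages of all
#' clusters. Sizes are reported in bins 1..`max_bin` plus a `">max_bin"` bin.
#'
#' @param catalog data.frame with `gene_id` and `offset` columns (majors).
#' @param max_gap Maximal intra-cluster gap in nt.
#' @param max_bin Largest individually reported size (default 20).
#' @return data.frame (size, n, percent); `percent` sums to 100.
#' @export
genomewide_frequencies <- function(catalog, max_gap = 4L, max_bin = 20L) {
  sizes <- unlist(lapply(split(catalog$offset, catalog$gene_id), function(o) {
    summarize_clusters(sort(o), max_gap)$size
  }), use.names = FALSE)
  if (length(sizes) == 0L) stop("no clusters: catalog is empty")
  binned <- ifelse(sizes > max_bin, max_bin + 1L, sizes)
  n <- tabulate(binned, nbins = max_bin + 1L)
  data.frame(size = c(as.character(seq_len(max_bin)), paste0(">", max_bin)),
             n = n, percent = 100 * n / sum(n))
}

#' Attach cluster indices to a utilization series
#'
#' @param series data.frame with `gene_id` and `offset`, sorted by offset
#'   within gene.
#' @param max_gap Maximal intra-cluster gap in nt.
#' @return `series` with a `cluster` column (per-gene indices).
#' @export
add_clusters <- function(series, max_gap = 4L) {
  series <- series[order(series$gene_id, series$offset), , drop = FALSE]
  series$cluster <- unlist(lapply(split(series$offset, series$gene_id),
                                  detect_clusters, max_gap = max_gap),
                           use.names = FALSE)
  rownames(series) <- NULL
  series
}
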
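#' Least-squares slopes of utilization across clusters
#'
#' For every cluster with at least `min_size` (default 4) common major
#' isoforms, fits the ordinary least-squares slope of the mutant/WT
#' utilization ratio `u` against isoform offset, along with the Pearson
#' correlation of the same pairs. Clusters with no variance in `u` get an
#' undefined R and are flagged (`ok = FALSE`) so quality-gated analyses can
#' exclude them; smaller clusters are skipped entirely.
#'
#' @param series Utilization series from [combine_genotypes()].
#' @param max_gap Maximal intra-cluster gap in nt.
#' @param min_size Minimum isoforms per cluster for a slope (default 4).
#' @return data.frame (gene_id, cluster, n, start, end, slope, pearson_R, ok).
#' @export
cluster_slopes <- function(series, max_gap = 4L, min_size = 4L) {
  series <- add_clusters(series, max_gap)
  parts <- lapply(split(series, list(series$gene_id, series$cluster), drop = TRUE),
                  function(cl) {
    if (nrow(cl) < min_size) return(NULL)
    x <- cl$offset; y <- cl$u
    vx <- stats::var(x); vy <- stats::var(y)
    slope <- stats::cov(x, y) / vx
    r <- if (vy == 0) NA_real_ else stats::cor(x, y)
    data.frame(gene_id = cl$gene_id[1], cluster = cl$cluster[1], n = nrow(cl),
               start = min(x), end = max(x), slope = slope, pearson_R = r,
               ok = vy > 0)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), cluster = integer(0), n = integer(0),
                      start = integer(0), end = integer(0), slope = numeric(0),
                      pearson_R = numeric(0), ok = logical(0))
  }
  out <- out[order(out$gene_id, out$cluster), ]
  rownames(out) <- NULL
  out
}

pair_stat <- function(u_up, u_down, stat) {
  switch(stat,
         relative_ratio = u_down / u_up,
         percent_difference = 100 * (u_down - u_up) / u_up,
         difference = u_down - u_up,
         stop("unknown stat kind: ", stat))
}

#' Median utilization statistics by spacing within clusters
#'
#' Draws all ordered isoform pairs (including non-adjacent pairs) from
#' clusters passing the Pearson-R quality gate (|R| > `R_threshold`; 0.7 for
#' yeast, 0.6 for human), groups them by their nt spacing up to `max_spacing`
#' (15 yeast / 14 human), and reports the median of the chosen statistic per
#' spacing across all genes. The default statistic is the relative ratio
#' (downstream utilization / upstream utilization); `percent_difference` and
#' plain `difference` are also available.
#'
#' @param series Utilization series from [combine_genotypes()].
#' @param max_gap Maximal intra-cluster gap in nt.
#' @param R_threshold Quality gate on |Pearson R| of the cluster.
#' @param stat `"relative_ratio"`, `"percent_difference"` or `"difference"`.
#' @param max_spacing Largest spacing bin reported.
#' @param min_size Minimum isoforms for a sloped cluster.
#' @return data.frame (spacing, median, n_pairs); empty bins are omitted.
#' @export
within_cluster_spacing_medians <- function(series, max_gap = 4L, R_threshold = 0.7,
                                           stat = "relative_ratio", max_spacing = 15L,
                                           min_size = 4L) {
  slopes <- cluster_slopes(series, max_gap, min_size)
  gated <- slopes[slopes$ok & abs(slopes$pearson_R) > R_threshold, , drop = FALSE]
  series <- add_clusters(series, max_gap)
  vals <- list()
  for (i in seq_len(nrow(gated))) {
    cl <- series[series$gene_id == gated$gene_id[i] & series$cluster == gated$cluster[i], ]
    n <- nrow(cl)
    pairs <- utils::combn(n, 2L)
    d <- cl$offset[pairs[2L, ]] - cl$offset[pairs[1L, ]]
    s <- pair_stat(cl$u[pairs[1L, ]], cl$u[pairs[2L, ]], stat)
    keep <- d <= max_spacing
    if (any(keep)) vals[[length(vals) + 1L]] <- data.frame(spacing = d[keep], value = s[keep])
  }
  summarize_spacing(do.call(rbind, vals))
}

#' Median utilization statistics across cluster boundaries
#'
#' One pair per adjacent cluster boundary within a gene: the 3'-most isoform
#' of the upstream cluster against the 5'-most isoform of the downstream
#' cluster, grouped by the inter-cluster distance (downstream 5'-most offset
#' minus upstream 3'-most offset). Clusters of any size contribute boundary
#' pairs by default; set `min_size` to restrict to sloped clusters.
#'
#' @param series Utilization series from [combine_genotypes()].
#' @param max_gap Maximal intra-cluster gap in nt.
#' @param stat Statistic kind (see [within_cluster_spacing_medians()]).
#' @param min_size Minimum isoforms per cluster for its boundary to count.
#' @return data.frame (spacing, median, n_pairs).
#' @export
between_cluster_spacing_medians <- function(series, max_gap = 4L,
                                            stat = "relative_ratio", min_size = 1L) {
  series <- add_clusters(series, max_gap)
  vals <- list()
  for (g in split(series, series$gene_id)) {
    sizes <- tabulate(g$cluster)
    ok_cl <- which(sizes >= min_size)
    ok_cl <- ok_cl[order(ok_cl)]
    if (length(ok_cl) < 2L) next
    for (j in seq_len(length(ok_cl) - 1L)) {
      up <- g[g$cluster == ok_cl[j], ]; down <- g[g$cluster == ok_cl[j + 1L], ]
      i_up <- which.max(up$offset); i_down <- which.min(down$offset)
      vals[[length(vals) + 1L]] <- data.frame(
        spacing = down$offset[i_down] - up$offset[i_up],
        value = pair_stat(up$u[i_up], down$u[i_down], stat))
    }
  }
  summarize_spacing(do.call(rbind, vals))
}

#' Cluster-independent neighboring-pair differences
#'
#' Ignores clusters entirely: every pair of neighboring major isoforms (no
#' other major isoform between them) contributes the difference of its
#' mutant/WT utilization ratios (downstream minus upstream), grouped by the
#' distance between the two isoforms.
#'
#' @param series Utilization series from [combine_genotypes()].
#' @param stat Statistic kind (default plain `difference`).
#' @param max_spacing Largest spacing bin reported (default unlimited).
#' @return data.frame (spacing, median, n_pairs).
#' @export
neighboring_pair_differences <- function(series, stat = "difference",
                                         max_spacing = Inf) {
  vals <- list()
  for (g in split(series, series$gene_id)) {
    g <- g[order(g$offset), ]
    if (nrow(g) < 2L) next
    n <- nrow(g)
    d <- diff(g$offset)
    s <- pair_stat(g$u[-n], g$u[-1L], stat)
    keep <- d <= max_spacing
    if (any(keep)) vals[[length(vals) + 1L]] <- data.frame(spacing = d[keep], value = s[keep])
  }
  summarize_spacing(do.call(rbind, vals))
}

summarize_spacing <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(spacing = integer(0), median = numeric(0), n_pairs = integer(0)))
  }
  med <- tapply(df$value, df$spacing, stats::median)
  data.frame(spacing = as.integer(names(med)), median = as.numeric(med),
             n_pairs = as.integer(table(df$spacing)), row.names = NULL)
}
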
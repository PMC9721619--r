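#' GC fraction of a window anchored at a transcript offset
#'
#' A window "starting at s" relative to an anchor offset spans transcript
#' offsets `anchor+s .. anchor+s+width-1` inclusive, on the sense strand.
#' Returns `NA` when the window falls off the contig.
#'
#' @param genome A `DNAStringSet`.
#' @param gene One row of a gene-model data.frame.
#' @param anchor Anchor transcript offset (e.g. a cluster boundary).
#' @param window_start Signed offset of the window start relative to `anchor`.
#' @param width Window width in nt (default 10).
#' @return GC fraction in [0, 1], or `NA` if out of range.
#' @export
window_gc <- function(genome, gene, anchor, window_start, width = 10L) {
  offs <- anchor + window_start + c(0L, width - 1L)
  gpos <- offset_to_genomic(gene, offs)
  lo <- min(gpos); hi <- max(gpos) + 1L
  len <- chrom_lengths(genome)[[gene$chrom]]
  if (lo < 0L || hi > len) return(NA_real_)
  s <- fetch_seq(genome, gene$chrom, lo, hi, gene$strand)
  gc_frac(s)
}

gc_frac <- function(s) {
  b <- strsplit(s, "")[[1]]
  mean(b %in% c("G", "C"))
}

# sense-strand sequence over anchor+from .. anchor+to (transcript offsets)
anchor_region_seq <- function(genome, gene, anchor, from, to) {
  gpos <- offset_to_genomic(gene, anchor + c(from, to))
  lo <- min(gpos); hi <- max(gpos) + 1L
  if (lo < 0L || hi > chrom_lengths(genome)[[gene$chrom]]) return(NA_character_)
  fetch_seq(genome, gene$chrom, lo, hi, gene$strand)
}

#' Sliding-window GC vs cluster-slope correlation scan
#'
#' For clusters whose data quality passes `|R| > R_gate` (default 0.5),
#' correlates the GC content of a 10-nt window with the cluster slopes across
#' clusters, at every window start position within the region: downstream
#' windows lie in +1..+100 relative to each cluster's 3'-most isoform,
#' upstream windows in -100..-1 relative to the 5'-most isoform. Two-sided
#' correlation P values are corrected by Benjamini-Hochberg across the window
#' positions of the region; positions are significant at `q < q_cutoff`.
#' Clusters whose window runs off the contig are excluded at that position;
#' positions with no GC variance are skipped (NA).
#'
#' @param slopes Slope table from [cluster_slopes()].
#' @param genes Gene-model data.frame.
#' @param genome A `DNAStringSet`.
#' @param region `"downstream"` or `"upstream"`.
#' @param width Window width in nt.
#' @param R_gate Quality gate on |Pearson R| of the cluster fit.
#' @param q_cutoff FDR significance cutoff (default 0.05).
#' @return data.frame (start, n, R, p, q, significant), one row per window
#'   start position.
#' @export
slope_gc_scan <- function(slopes, genes, genome, region = c("downstream", "upstream"),
                          width = 10L, R_gate = 0.5, q_cutoff = 0.05) {
  region <- match.arg(region)
  gated <- slopes[slopes$ok & abs(slopes$pearson_R) > R_gate, , drop = FALSE]
  if (nrow(gated) < 3L) stop("need at least 3 quality-gated clusters")
  span <- if (region == "downstream") c(1L, 100L) else c(-100L, -1L)
  starts <- seq.int(span[1], span[2] - width + 1L)

  # pre-fetch each cluster's 100-nt region once; windows are substrings
  regs <- character(nrow(gated))
  for (i in seq_len(nrow(gated))) {
    gene <- genes[match(gated$gene_id[i], genes$gene_id), ]
    regs[i] <- if (region == "downstream") {
      anchor_region_seq(genome, gene, gated$end[i], 1L, 100L)
    } else {
      anchor_region_seq(genome, gene, gated$start[i], -100L, -1L)
    }
  }
  mat <- do.call(rbind, lapply(regs, function(s) {
    if (is.na(s)) rep(NA, span[2] - span[1] + 1L) else strsplit(s, "")[[1]] %in% c("G", "C")
  }))

  out <- data.frame(start = starts, n = NA_integer_, R = NA_real_, p = NA_real_)
  for (w in seq_along(starts)) {
    cols <- w:(w + width - 1L)
    gc <- rowMeans(mat[, cols, drop = FALSE])
    okrow <- !is.na(gc)
    if (sum(okrow) < 3L || stats::var(gc[okrow]) == 0) next
    ct <- stats::cor.test(gc[okrow], gated$slope[okrow])
    out$n[w] <- sum(okrow); out$R[w] <- unname(ct$estimate); out$p[w] <- ct$p.value
  }
  out$q <- NA_real_
  out$q[!is.na(out$p)] <- stats::p.adjust(out$p[!is.na(out$p)], method = "BH")
  out$significant <- !is.na(out$q) & out$q < q_cutoff
  out
}

#' Quintile analysis of GC change at +13..+30 downstream of clusters
#'
#' Sorts quality-gated cluster slopes ascending (stable on ties), splits them
#' into five near-equal groups, and reports each quintile's mean percent
#' change in GC content at +13..+30 relative to background, together with the
#' quintile's median slope. Per cluster, percent change is
#' `100 * (gc_cluster - background) / background`, where the background
#' defaults to the median GC over all width-18 windows fully contained in the
#' analyzed genes' 3'UTR windows.
#'
#' @param slopes Slope table from [cluster_slopes()].
#' @param genes Gene-model data.frame.
#' @param genome A `DNAStringSet`.
#' @param region GC element window relative to the 3'-most isoform (default
#'   +13..+30).
#' @param background Background GC fraction; `NULL` to compute the 3'UTR
#'   window median.
#' @param R_gate Quality gate on |Pearson R|.
#' @return data.frame (quintile, n, mean_pct_change, median_slope), quintile 1
#'   holding the most negative slopes.
#' @export
quintile_gc_change <- function(slopes, genes, genome, region = c(13L, 30L),
                               background = NULL, R_gate = 0.5) {
  gated <- slopes[slopes$ok & abs(slopes$pearson_R) > R_gate, , drop = FALSE]
  if (nrow(gated) < 5L) stop("need at least 5 quality-gated clusters")
  width <- region[2] - region[1] + 1L
  gc <- numeric(nrow(gated))
  for (i in seq_len(nrow(gated))) {
    gene <- genes[match(gated$gene_id[i], genes$gene_id), ]
    gc[i] <- window_gc(genome, gene, gated$end[i], region[1], width)
  }
  keep <- !is.na(gc)
  gated <- gated[keep, , drop = FALSE]; gc <- gc[keep]

  if (is.null(background)) background <- utr_background_gc(genes, genome, width)
  if (is.na(background) || background == 0) stop("degenerate background GC (0)")
  pct <- 100 * (gc - background) / background

  ord <- order(gated$slope)  # stable: order() preserves input order on ties
  qi <- integer(nrow(gated))
  bounds <- floor(seq(0, nrow(gated), length.out = 6L))
  qi[ord] <- rep(1:5, diff(bounds))
  data.frame(quintile = 1:5,
             n = as.integer(tabulate(qi, 5L)),
             mean_pct_change = as.numeric(tapply(pct, qi, mean)),
             median_slope = as.numeric(tapply(gated$slope, qi, stats::median)),
             row.names = NULL)
}

#' Median GC of all fixed-width windows within 3'UTR analysis windows
#'
#' @param genes Gene-model data.frame.
#' @param genome A `DNAStringSet`.
#' @param width Window width in nt.
#' @return Median GC fraction across all windows of all genes.
#' @export
utr_background_gc <- function(genes, genome, width = 18L) {
  vals <- list()
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    s <- anchor_region_seq(genome, gene, 0L, 1L, gene$utr_downstream)
    if (is.na(s)) next
    isgc <- strsplit(s, "")[[1]] %in% c("G", "C")
    if (length(isgc) < width) next
    cs <- c(0, cumsum(isgc))
    n <- length(isgc) - width + 1L
    vals[[length(vals) + 1L]] <- (cs[(width + 1):(width + n)] - cs[1:n]) / width
  }
  stats::median(unlist(vals))
}
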
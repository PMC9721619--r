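#' Build per-gene isoform tables
#'
#' Applies the gene-eligibility floor (total 3'UTR reads, 1000 under the yeast
#' profile) and sorts each gene's isoforms by transcript offset.
#'
#' @param endpoints data.frame (gene_id, offset, count) of scaled counts.
#' @param profile Species name or [species_profile()] object.
#' @param gene_min_reads Optional override of the profile's gene floor.
#' @return data.frame (gene_id, offset, count) restricted to eligible genes.
#' @export
build_catalog <- function(endpoints, profile = "yeast", gene_min_reads = NULL) {
  profile <- as_profile(profile)
  floor_ <- if (is.null(gene_min_reads)) profile$gene_min_reads else gene_min_reads
  if (nrow(endpoints) == 0L) {
    return(data.frame(gene_id = character(0), offset = integer(0), count = numeric(0)))
  }
  totals <- rowsum(endpoints$count, endpoints$gene_id)
  ok <- rownames(totals)[totals[, 1L] >= floor_]
  out <- endpoints[endpoints$gene_id %in% ok, , drop = FALSE]
  out <- out[order(out$gene_id, out$offset), ]
  rownames(out) <- NULL
  out
}

#' Flag and retain major isoforms
#'
#' Yeast rule: an isoform is major when its count is at least
#' `major_fraction` (5%) of the gene's maximal isoform (the boundary is
#' inclusive under the yeast profile; set `major_inclusive = FALSE` in the
#' profile for a strict `>`). Human low-depth rule: when the maximal isoform
#' holds fewer than 100 reads in either genotype, isoforms with >= 5 reads are
#' major; otherwise majors must exceed 5% of the maximum. Minor isoforms are
#' removed and relative expression is recomputed over the retained majors.
#'
#' @param catalog data.frame (gene_id, offset, count) from [build_catalog()].
#' @param profile Species name or profile object.
#' @param other_max Named numeric vector of the other genotype's per-gene
#'   maximal-isoform counts (required for the human low-depth rule; ignored
#'   under the yeast profile).
#' @return data.frame (gene_id, offset, count, rel) of major isoforms; the
#'   `major_mass` attribute gives the fraction of catalog read mass carried by
#'   majors.
#' @export
select_major_isoforms <- function(catalog, profile = "yeast", other_max = NULL) {
  profile <- as_profile(profile)
  if (nrow(catalog) == 0L) {
    return(structure(data.frame(gene_id = character(0), offset = integer(0),
                                count = numeric(0), rel = numeric(0)),
                     major_mass = NA_real_))
  }
  parts <- lapply(split(catalog, catalog$gene_id), function(tab) {
    mx <- max(tab$count)
    low_depth <- FALSE
    if (!is.na(profile$low_depth_max_threshold)) {
      mx_other <- if (!is.null(other_max)) other_max[[tab$gene_id[1]]] else NA_real_
      low_depth <- mx < profile$low_depth_max_threshold ||
        (!is.na(mx_other) && mx_other < profile$low_depth_max_threshold)
    }
    major <- if (low_depth) {
      tab$count >= profile$low_depth_min_reads
    } else if (profile$major_inclusive) {
      tab$count >= profile$major_fraction * mx
    } else {
      tab$count > profile$major_fraction * mx
    }
    tab[major, , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rel_tot <- rowsum(out$count, out$gene_id)
  out$rel <- out$count / rel_tot[out$gene_id, 1L]
  rownames(out) <- NULL
  structure(out, major_mass = sum(out$count) / sum(catalog$count))
}

#' Combine genotype catalogs into utilization series
#'
#' Retains, per gene, the isoforms that are major in both genotypes, recomputes
#' relative expression over that common set in each genotype, and computes the
#' mutant/wild-type utilization ratio `u = rel_mut / rel_wt` per isoform.
#' Genes with fewer than two common majors are dropped.
#'
#' @param wt,mut Major-isoform data.frames from [select_major_isoforms()].
#' @return data.frame (gene_id, offset, count_wt, count_mut, rel_wt, rel_mut, u).
#' @export
combine_genotypes <- function(wt, mut) {
  m <- merge(wt[c("gene_id", "offset", "count")],
             mut[c("gene_id", "offset", "count")],
             by = c("gene_id", "offset"), suffixes = c("_wt", "_mut"))
  if (nrow(m) == 0L) {
    return(data.frame(gene_id = character(0), offset = integer(0),
                      count_wt = numeric(0), count_mut = numeric(0),
                      rel_wt = numeric(0), rel_mut = numeric(0), u = numeric(0)))
  }
  n_per_gene <- table(m$gene_id)
  m <- m[m$gene_id %in% names(n_per_gene)[n_per_gene >= 2L], , drop = FALSE]
  if (nrow(m) == 0L) return(m[c("gene_id", "offset", "count_wt", "count_mut")])
  tot_wt <- rowsum(m$count_wt, m$gene_id)
  tot_mut <- rowsum(m$count_mut, m$gene_id)
  m$rel_wt <- m$count_wt / tot_wt[m$gene_id, 1L]
  m$rel_mut <- m$count_mut / tot_mut[m$gene_id, 1L]
  m$u <- m$rel_mut / m$rel_wt
  m <- m[order(m$gene_id, m$offset), ]
  rownames(m) <- NULL
  m
}
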
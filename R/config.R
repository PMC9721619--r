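#' Species analysis profiles
#'
#' Bundles the per-species analysis parameters so they cannot be silently
#' mixed: the maximal intra-cluster gap, the major-isoform rule, the gene
#' read floor, the library scaling target, the Pearson-R quality gates for
#' cluster-slope and GC analyses, the within-cluster spacing-bin range, the
#' default 3'UTR analysis window relative to the stop codon, and the read
#' truncation length used before mapping.
#'
#' The yeast profile uses the deep-coverage major rule (an isoform is major
#' when it holds at least 5% of the reads of the gene's maximal isoform) and a
#' 1000-read gene floor. The human profile adds the low-depth rule: when the
#' maximal isoform has fewer than 100 reads in either genotype, isoforms with
#' at least 5 reads are major; otherwise majors must exceed 5% of the maximum.
#' The human 3'UTR window spans 1 kb upstream to 5 kb downstream of the stop
#' codon; human gene eligibility has no read floor beyond requiring two common
#' majors downstream (set `gene_min_reads` yourself to impose one).
#'
#' @param species `"yeast"` or `"human"`.
#' @return A list of class `pa_profile`.
#' @export
species_profile <- function(species = c("yeast", "human")) {
  species <- match.arg(species)
  p <- switch(species,
    yeast = list(
      species = "yeast",
      max_gap = 4L,
      major_fraction = 0.05,
      major_inclusive = TRUE,
      low_depth_min_reads = NA_real_,
      low_depth_max_threshold = NA_real_,
      gene_min_reads = 1000,
      scale_target = 25e6,
      slope_R_threshold = 0.7,
      gc_R_threshold = 0.5,
      spacing_max = 15L,
      utr_window = c(upstream = 0L, downstream = 500L),
      read_truncate = 17L,
      exclude_chroms = character(0)
    ),
    human = list(
      species = "human",
      max_gap = 4L,
      major_fraction = 0.05,
      major_inclusive = FALSE,
      low_depth_min_reads = 5,
      low_depth_max_threshold = 100,
      gene_min_reads = 0,
      scale_target = 25e6,
      slope_R_threshold = 0.6,
      gc_R_threshold = 0.5,
      spacing_max = 14L,
      utr_window = c(upstream = 1000L, downstream = 5000L),
      read_truncate = 77L,
      exclude_chroms = c("chrM", "chrMT", "MT")
    )
  )
  structure(p, class = "pa_profile")
}

as_profile <- function(profile) {
  if (inherits(profile, "pa_profile")) return(profile)
  if (is.character(profile) && length(profile) == 1L) return(species_profile(profile))
  stop("profile must be 'yeast', 'human', or a pa_profile object")
}

#' Assemble a run configuration
#'
#' A thin validated container over [species_profile()] allowing individual
#' parameter overrides (e.g. a different intra-cluster gap for a gap sweep, or
#' a gene read floor for human data).
#'
#' @param species `"yeast"` or `"human"`.
#' @param ... Named overrides of profile fields.
#' @param n_shuffles Number of permutations for the cluster-pattern null.
#' @param rng_seed Integer seed recorded for the run.
#' @return A `pa_profile` with `n_shuffles` and `rng_seed` attached.
#' @export
run_config <- function(species = c("yeast", "human"), ..., n_shuffles = 1e5, rng_seed = 1L) {
  p <- species_profile(species)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown profile fields: ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  for (f in c("max_gap", "major_fraction", "scale_target", "slope_R_threshold", "gc_R_threshold", "spacing_max")) {
    if (!is.na(p[[f]]) && p[[f]] <= 0) stop(f, " must be positive")
  }
  p$n_shuffles <- as.integer(n_shuffles)
  p$rng_seed <- as.integer(rng_seed)
  p
}
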
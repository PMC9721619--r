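#' Read a gene annotation table
#'
#' Reads a TSV with columns `gene_id`, `chrom`, `strand`, `stop_codon_end`
#' (0-based genomic coordinate of the last base of the stop codon) and
#' optional `utr_upstream` / `utr_downstream` window overrides (nt relative to
#' the stop codon). Missing windows are filled from the species profile.
#' Transcript offset 1 is the first nucleotide 3' of `stop_codon_end` on the
#' sense strand.
#'
#' @param path TSV path.
#' @param profile Species name or [species_profile()] object.
#' @return A data.frame of gene models.
#' @export
read_annotation <- function(path, profile = "yeast") {
  profile <- as_profile(profile)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(ann) == 0L) {
    return(data.frame(gene_id = character(0), chrom = character(0), strand = character(0),
                      stop_codon_end = integer(0), utr_upstream = integer(0),
                      utr_downstream = integer(0)))
  }
  req <- c("gene_id", "chrom", "strand", "stop_codon_end")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  make_gene_models(ann, profile)
}

#' Build gene models from an annotation data.frame
#'
#' @param ann data.frame with `gene_id`, `chrom`, `strand`, `stop_codon_end`
#'   and optional window override columns.
#' @param profile Species name or profile object supplying default windows.
#' @return A validated gene-model data.frame.
#' @export
make_gene_models <- function(ann, profile = "yeast") {
  profile <- as_profile(profile)
  if (nrow(ann) == 0L) {
    return(data.frame(gene_id = character(0), chrom = character(0), strand = character(0),
                      stop_codon_end = integer(0), utr_upstream = integer(0),
                      utr_downstream = integer(0)))
  }
  dup <- anyDuplicated(ann$gene_id)
  if (dup) stop("duplicate gene_id: ", ann$gene_id[dup])
  bad <- !ann$strand %in% c("+", "-")
  if (any(bad)) stop("unknown strand symbol '", ann$strand[which(bad)[1]], "' for gene ", ann$gene_id[which(bad)[1]])
  if (is.null(ann$utr_upstream)) ann$utr_upstream <- NA_integer_
  if (is.null(ann$utr_downstream)) ann$utr_downstream <- NA_integer_
  ann$utr_upstream[is.na(ann$utr_upstream)] <- profile$utr_window[["upstream"]]
  ann$utr_downstream[is.na(ann$utr_downstream)] <- profile$utr_window[["downstream"]]
  if (any(ann$utr_downstream <= 0)) stop("utr_downstream must be > 0")
  ann[c("gene_id", "chrom", "strand", "stop_codon_end", "utr_upstream", "utr_downstream")]
}

#' Write a gene annotation table
#'
#' @param genes Gene-model data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert transcript offsets to genomic coordinates
#'
#' Offset 1 is the first base 3' of the stop codon in transcript direction;
#' offsets may be zero or negative for positions at/upstream of the stop codon
#' (used by the human window). Returns 0-based genomic positions.
#'
#' @param gene One row of a gene-model data.frame.
#' @param offsets Integer transcript offsets.
#' @return Integer 0-based genomic coordinates.
#' @export
offset_to_genomic <- function(gene, offsets) {
  if (gene$strand == "+") gene$stop_codon_end + offsets else gene$stop_codon_end - offsets
}

#' Convert genomic coordinates to transcript offsets
#'
#' Inverse of [offset_to_genomic()].
#'
#' @param gene One row of a gene-model data.frame.
#' @param pos 0-based genomic positions.
#' @return Integer transcript offsets.
#' @export
genomic_to_offset <- function(gene, pos) {
  if (gene$strand == "+") pos - gene$stop_codon_end else gene$stop_codon_end - pos
}
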
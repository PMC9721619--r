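#' Read a genome FASTA
#'
#' Loads all records of a FASTA file into a [Biostrings::DNAStringSet] keyed by
#' the first whitespace-delimited token of each header. The object supports
#' random access by chromosome and strand via [fetch_seq()].
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one element per record.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  genome <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  names(genome) <- sub("\\s.*$", "", names(genome))
  dup <- anyDuplicated(names(genome))
  if (dup) stop("malformed FASTA '", path, "': duplicate record name '", names(genome)[dup], "'")
  genome
}

#' Write a genome FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Fetch genomic sequence with strand awareness
#'
#' Coordinates are 0-based, half-open (`[start, end)`), the package-wide
#' genomic convention. `strand = "-"` returns the reverse complement, i.e. the
#' sense-strand sequence of a minus-strand feature. Out-of-range requests are
#' errors, never silent truncation.
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return A character scalar of length `end - start`.
#' @export
fetch_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-', got '", strand, "'")
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start > end) {
    stop("requested [", start, ", ", end, ") outside ", chrom, " (length ", len, ")")
  }
  if (start == end) return("")
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Chromosome lengths of a genome
#'
#' @param genome A `DNAStringSet`.
#' @return Named integer vector of record lengths.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}
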
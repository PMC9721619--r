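#' Preprocess raw 3' READS reads
#'
#' Strips the 4 random nt added during library construction, requires the
#' first non-random nt to be a T (an A at the mRNA 3' end), counts and removes
#' the leading T-run (the number of terminal As of the sequenced fragment),
#' and truncates the remainder to the species mapping length (17 nt yeast,
#' 77 nt human). Reads failing any rule are dropped and tallied by reason.
#'
#' @param x FASTQ path, or a named character vector of read sequences.
#' @param profile Species name or [species_profile()] object.
#' @return data.frame (read_id, t_count, trimmed_seq) with a `drops` attribute
#'   (named counts: too_short, first_not_t, all_t).
#' @export
preprocess_reads <- function(x, profile = "yeast") {
  profile <- as_profile(profile)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x, format = "fastq")
    reads <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else {
    reads <- x
    if (is.null(names(reads))) names(reads) <- sprintf("read%d", seq_along(reads))
  }
  drops <- c(too_short = 0L, first_not_t = 0L, all_t = 0L)

  n <- nchar(reads)
  short <- n < 5L
  drops["too_short"] <- sum(short)
  reads <- reads[!short]

  body <- substr(reads, 5L, nchar(reads))
  not_t <- substr(body, 1L, 1L) != "T"
  drops["first_not_t"] <- sum(not_t)
  body <- body[!not_t]

  t_count <- attr(regexpr("^T+", body), "match.length")
  rest <- substr(body, t_count + 1L, nchar(body))
  all_t <- nchar(rest) == 0L
  drops["all_t"] <- sum(all_t)

  out <- data.frame(read_id = names(body)[!all_t],
                    t_count = as.integer(t_count[!all_t]),
                    trimmed_seq = substr(rest[!all_t], 1L, profile$read_truncate),
                    row.names = NULL)
  attr(out, "drops") <- drops
  out
}

#' Naive exact-match aligner for fixture-scale tests
#'
#' Maps each trimmed read to its unique full-length exact match in the genome
#' and records the strand-aware 3'-end coordinate of the sequenced fragment.
#' A trimmed 3' READS read is the reverse complement of the sense-strand
#' sequence ending at the poly(A) endpoint, so a plus-strand fragment matches
#' the reverse complement of the read and ends at the match's last base, while
#' a minus-strand fragment matches the read itself and ends at the match's
#' first base. Reads without a unique genome-wide match are dropped.
#'
#' Production-scale mapping is expected to be done externally; this aligner
#' exists so the end-to-end path can be exercised on small fixtures.
#'
#' @param tagged data.frame from [preprocess_reads()].
#' @param genome A `DNAStringSet`.
#' @return data.frame (read_id, chrom, pos, strand, t_count); `pos` is the
#'   0-based genomic coordinate of the fragment 3' end.
#' @export
align_reads_exact <- function(tagged, genome) {
  if (nrow(tagged) == 0L) {
    return(data.frame(read_id = character(0), chrom = character(0), pos = integer(0),
                      strand = character(0), t_count = integer(0)))
  }
  uniq <- unique(tagged$trimmed_seq)
  hit <- stats::setNames(vector("list", length(uniq)), uniq)
  for (s in uniq) {
    pat_plus <- Biostrings::DNAString(revcomp_chr(s))
    pat_minus <- Biostrings::DNAString(s)
    found <- list()
    for (ch in names(genome)) {
      mp <- Biostrings::matchPattern(pat_plus, genome[[ch]])
      if (length(mp)) found[[length(found) + 1L]] <-
        data.frame(chrom = ch, pos = BiocGenerics::end(mp) - 1L, strand = "+")
      mm <- Biostrings::matchPattern(pat_minus, genome[[ch]])
      if (length(mm)) found[[length(found) + 1L]] <-
        data.frame(chrom = ch, pos = BiocGenerics::start(mm) - 1L, strand = "-")
    }
    found <- do.call(rbind, found)
    if (!is.null(found) && nrow(found) == 1L) hit[[s]] <- found
  }
  keep <- !vapply(hit[tagged$trimmed_seq], is.null, TRUE)
  mapped <- do.call(rbind, hit[tagged$trimmed_seq[keep]])
  out <- data.frame(read_id = tagged$read_id[keep],
                    chrom = mapped$chrom, pos = mapped$pos, strand = mapped$strand,
                    t_count = tagged$t_count[keep], row.names = NULL)
  out
}

#' Filter internally primed reads against the genome
#'
#' A mapped poly(A) read is retained only if its leading-T count exceeds the
#' length of the uninterrupted sense-strand A-run starting immediately 3' of
#' its mapped 3' end: when the genomic As fully account for the Ts, the read
#' may not represent a bona fide polyadenylated product and is discarded.
#' The A-run is clipped at the contig end; a 3'-end coordinate outside the
#' genome is an error.
#'
#' @param mapped data.frame (chrom, pos, strand, t_count, ...), `pos` 0-based.
#' @param genome A `DNAStringSet`.
#' @return The retained rows of `mapped`, with a `kept` attribute giving the
#'   per-row decision for the full input.
#' @export
filter_internal_priming <- function(mapped, genome) {
  if (nrow(mapped) == 0L) {
    attr(mapped, "kept") <- logical(0)
    return(mapped)
  }
  if (any(mapped$t_count < 1L)) stop("t_count must be >= 1 for every mapped read")
  lens <- chrom_lengths(genome)
  kept <- logical(nrow(mapped))
  for (i in seq_len(nrow(mapped))) {
    ch <- mapped$chrom[i]; pos <- mapped$pos[i]; tc <- mapped$t_count[i]
    if (!ch %in% names(lens) || pos < 0L || pos >= lens[[ch]]) {
      stop("mapped coordinate ", ch, ":", pos, " outside genome")
    }
    down <- if (mapped$strand[i] == "+") {
      fetch_seq(genome, ch, pos + 1L, min(lens[[ch]], pos + 1L + tc), "+")
    } else {
      fetch_seq(genome, ch, max(0L, pos - tc), pos, "-")
    }
    run <- attr(regexpr("^A*", down), "match.length")
    kept[i] <- run < tc
  }
  out <- mapped[kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kept") <- kept
  out
}

#' Consolidate replicate endpoint counts and scale to a target total
#'
#' Sums counts per endpoint across replicates and multiplies by
#' `target / total`, so the output totals `target` (default 25 million) while
#' preserving all proportions exactly. Fractional counts are allowed after
#' scaling.
#'
#' @param replicates A single data.frame or list of data.frames sharing the
#'   same key columns plus `count`.
#' @param target Positive total to scale to.
#' @return One data.frame with summed, scaled counts.
#' @export
consolidate_and_scale <- function(replicates, target = 25e6) {
  if (target <= 0) stop("target must be > 0")
  if (is.data.frame(replicates)) replicates <- list(replicates)
  if (length(replicates) < 1L) stop("need at least one replicate")
  df <- do.call(rbind, replicates)
  keys <- setdiff(names(df), "count")
  key <- do.call(paste, c(df[keys], sep = "\r"))
  agg <- rowsum(df$count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- df[first, keys, drop = FALSE]
  out$count <- as.numeric(agg[match(key[first], rownames(agg)), 1L])
  total <- sum(out$count)
  if (total == 0) stop("cannot scale: all counts are zero")
  out$count <- out$count * (target / total)
  rownames(out) <- NULL
  out
}

#' Assign genomic endpoints to genes and transcript offsets
#'
#' An endpoint is assigned to a gene when it lies on the matching strand
#' within the gene's 3'UTR analysis window: transcript offsets `o` with
#' `-utr_upstream < o <= utr_downstream` relative to the stop codon. Under the
#' human profile, mitochondrial contigs are excluded first. When windows
#' overlap, the endpoint goes to the gene whose stop codon is nearest upstream
#' (smallest positive offset, falling back to the smallest offset magnitude);
#' ambiguous assignments are counted in the `ambiguous` attribute.
#'
#' @param endpoints data.frame (chrom, pos, strand, count), `pos` 0-based.
#' @param genes Gene-model data.frame.
#' @param profile Species name or profile object.
#' @return data.frame (gene_id, offset, count), offsets in nt downstream of
#'   the stop codon.
#' @export
assign_to_genes <- function(endpoints, genes, profile = "yeast") {
  profile <- as_profile(profile)
  if (nrow(endpoints) > 0L && length(profile$exclude_chroms)) {
    endpoints <- endpoints[!endpoints$chrom %in% profile$exclude_chroms, , drop = FALSE]
  }
  if (nrow(endpoints) == 0L || nrow(genes) == 0L) {
    return(structure(data.frame(gene_id = character(0), offset = integer(0), count = numeric(0)),
                     ambiguous = 0L))
  }
  cand <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    sel <- endpoints$chrom == gene$chrom & endpoints$strand == gene$strand
    if (!any(sel)) next
    o <- genomic_to_offset(gene, endpoints$pos[sel])
    inside <- o > -gene$utr_upstream & o <= gene$utr_downstream
    if (!any(inside)) next
    cand[[g]] <- data.frame(ep = which(sel)[inside], gene_id = gene$gene_id,
                            offset = o[inside])
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand)) {
    return(structure(data.frame(gene_id = character(0), offset = integer(0), count = numeric(0)),
                     ambiguous = 0L))
  }
  n_amb <- sum(table(cand$ep) > 1L)
  # nearest upstream stop codon: smallest positive offset, then smallest |offset|
  pref <- order(cand$ep, cand$offset <= 0, abs(cand$offset))
  cand <- cand[pref, ]
  cand <- cand[!duplicated(cand$ep), ]
  out <- data.frame(gene_id = cand$gene_id, offset = as.integer(cand$offset),
                    count = endpoints$count[cand$ep])
  key <- paste(out$gene_id, out$offset)
  if (anyDuplicated(key)) {
    agg <- rowsum(out$count, key, reorder = FALSE)
    first <- !duplicated(key)
    out <- out[first, ]
    out$count <- as.numeric(agg[match(key[first], rownames(agg)), 1L])
  }
  out <- out[order(out$gene_id, out$offset), ]
  rownames(out) <- NULL
  structure(out, ambiguous = n_amb)
}

#' Tally mapped reads into per-base endpoint counts
#'
#' Collapses retained reads to their 3'-end coordinate, one count per read.
#'
#' @param mapped data.frame (chrom, pos, strand, ...).
#' @return data.frame (chrom, pos, strand, count).
#' @export
tally_endpoints <- function(mapped) {
  end_coverage(mapped$chrom, mapped$pos, mapped$strand, rep(1, nrow(mapped)))
}
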
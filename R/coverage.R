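#' Single-base stranded 3'-end coverage
#'
#' Coverage is held as a data.frame with columns `chrom`, `pos` (0-based base
#' coordinate), `strand` and `count`, one row per covered base. This is the
#' container for nascent 3'-end (NET-seq-style) signal and for collapsed
#' poly(A) read endpoints.
#'
#' @param chrom,pos,strand,count Parallel vectors.
#' @return A coverage data.frame with duplicate bases aggregated.
#' @export
end_coverage <- function(chrom = character(0), pos = integer(0),
                         strand = character(0), count = numeric(0)) {
  if (any(count < 0)) stop("negative count in coverage")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand), count = as.numeric(count))
  if (nrow(df) == 0L) return(df)
  key <- paste(df$chrom, df$pos, df$strand)
  if (anyDuplicated(key)) {
    agg <- rowsum(df$count, key)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    df <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                     pos = as.integer(vapply(parts, `[`, "", 2L)),
                     strand = vapply(parts, `[`, "", 3L),
                     count = as.numeric(agg[, 1L]))
  }
  df[df$count > 0, , drop = FALSE]
}

#' Read stranded bedGraph coverage
#'
#' Reads a pair of bedGraph files (one per strand) into a per-base coverage
#' data.frame. Interval counts must be non-negative; a width-w interval with
#' count c expands to w bases of count c, so the total equals the sum of
#' interval counts times widths.
#'
#' @param plus_path,minus_path bedGraph file for each strand (`NULL` to skip).
#' @return A coverage data.frame (see [end_coverage()]).
#' @export
read_end_coverage <- function(plus_path, minus_path = NULL) {
  one <- function(path, strand) {
    if (is.null(path)) return(NULL)
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0L) return(NULL)
    score <- as.numeric(GenomicRanges::mcols(gr)$score)
    if (any(score < 0)) stop("negative count in bedGraph ", path)
    w <- GenomicRanges::width(gr)
    data.frame(
      chrom = rep(as.character(GenomicRanges::seqnames(gr)), w),
      pos = as.integer(unlist(lapply(seq_along(gr), function(i)
        seq.int(GenomicRanges::start(gr)[i] - 1L, length.out = w[i])))),
      strand = strand,
      count = rep(score, w)
    )
  }
  parts <- rbind(one(plus_path, "+"), one(minus_path, "-"))
  if (is.null(parts)) return(end_coverage())
  end_coverage(parts$chrom, parts$pos, parts$strand, parts$count)
}

#' Write stranded bedGraph coverage
#'
#' @param cov Coverage data.frame.
#' @param plus_path,minus_path Output bedGraph paths per strand.
#' @return Invisibly, the two paths.
#' @export
write_end_coverage <- function(cov, plus_path, minus_path) {
  one <- function(df, path) {
    if (nrow(df) == 0L) {
      writeLines(character(0), path)
      return()
    }
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(start = df$pos + 1L, width = 1L),
                                 score = df$count)
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  one(cov[cov$strand == "+", , drop = FALSE], plus_path)
  one(cov[cov$strand == "-", , drop = FALSE], minus_path)
  invisible(c(plus_path, minus_path))
}

#' Total signal in a coverage track
#'
#' @param cov Coverage data.frame.
#' @return Numeric total of all per-base counts.
#' @export
coverage_total <- function(cov) sum(cov$count)

#' Point-query a coverage track
#'
#' @param cov Coverage data.frame.
#' @param chrom,pos,strand Parallel query vectors (0-based positions).
#' @return Numeric counts, 0 for uncovered bases.
#' @export
coverage_query <- function(cov, chrom, pos, strand) {
  idx <- match(paste(chrom, pos, strand), paste(cov$chrom, cov$pos, cov$strand))
  out <- cov$count[idx]
  out[is.na(out)] <- 0
  out
}
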
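#' @importFrom GenomicRanges GRanges reduce intersect setdiff findOverlaps width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

BASES <- c("A", "C", "G", "T")

## All user-facing interval tables are BED-style: 0-based, half-open [start, end).
## GRanges (1-based, closed) is used internally for set arithmetic.

#' Convert a BED-style interval data frame to GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @return A `GRanges` object (1-based closed).
#' @keywords internal
bed_to_gr <- function(df) {
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

#' Convert GRanges back to a BED-style data frame
#' @keywords internal
gr_to_bed <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Total basepairs covered by the union of a set of intervals
#'
#' @param df BED-style data.frame (`chrom`, `start`, `end`).
#' @return Number of distinct genomic positions covered.
#' @export
coverage_bp <- function(df) {
  if (nrow(df) == 0L) {
    return(0)
  }
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(bed_to_gr(df)))))
}

#' Union (reduce) of BED-style intervals
#' @keywords internal
interval_union <- function(df) {
  gr_to_bed(GenomicRanges::reduce(bed_to_gr(df)))
}

#' Set difference of BED-style interval sets (a \ b)
#' @keywords internal
interval_setdiff <- function(a, b) {
  if (nrow(a) == 0L) {
    return(a[0, c("chrom", "start", "end")])
  }
  if (nrow(b) == 0L) {
    return(interval_union(a))
  }
  gr_to_bed(GenomicRanges::setdiff(bed_to_gr(a), bed_to_gr(b)))
}

#' Intersection of BED-style interval sets
#' @keywords internal
interval_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(a[0, c("chrom", "start", "end")])
  }
  gr_to_bed(GenomicRanges::intersect(bed_to_gr(a), bed_to_gr(b)))
}

#' Read a two-column chromosome sizes file
#'
#' @param path Path to a tab-separated file with columns chrom, length.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$length, tab$chrom)
}

#' Write chromosome sizes
#' @keywords internal
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), unname(sizes)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write BED-style intervals
#'
#' Writes the first three BED columns plus any extra columns present, in order.
#' @keywords internal
write_bed <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     scipen = 50L)
}

#' Write a per-base score track as bedGraph with run-length merging
#'
#' Consecutive positions with equal score are merged into one record.
#'
#' @param chrom Chromosome name (scalar) or vector parallel to `pos`.
#' @param pos 0-based positions.
#' @param score Numeric scores, one per position.
#' @param path Output path.
#' @export
write_bedgraph <- function(chrom, pos, score, path) {
  stopifnot(length(pos) == length(score))
  chrom <- rep_len(chrom, length(pos))
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; score <- score[ord]
  ## runs of equal score on consecutive positions of the same chromosome
  n <- length(pos)
  if (n == 0L) {
    file.create(path)
    return(invisible(path))
  }
  brk <- c(TRUE, chrom[-1] != chrom[-n] | pos[-1] != pos[-n] + 1 |
             score[-1] != score[-n])
  grp <- cumsum(brk)
  first <- which(brk)
  len <- tabulate(grp)
  out <- data.frame(chrom = chrom[first], start = pos[first],
                    end = pos[first] + len, score = score[first])
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     scipen = 50L)
  invisible(path)
}

#' Read a bedGraph score track
#'
#' @param path bedGraph file path (chrom, start, end, score; 0-based half-open).
#' @return data.frame with columns chrom, start, end, score.
#' @export
read_bedgraph <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "score"),
                          data.table = FALSE)
  df$chrom <- as.character(df$chrom)
  df
}

## round half away from zero at `digits` decimals (base round() is half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
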
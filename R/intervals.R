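#' Distance between two genomic intervals
#'
#' The gap, in bp, between two intervals: 0 when they overlap or are
#' book-ended, the number of intervening bases when they are disjoint on
#' the same chromosome, and `NA` when they lie on different chromosomes
#' (a cross-chromosome distance is deliberately undefined rather than
#' infinite, so callers must handle it explicitly).
#'
#' @param a,b `GRanges` of equal length (distances are computed pairwise).
#' @return Integer vector of gaps, `NA` for cross-chromosome pairs.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(901, 1000))
#' interval_distance(a, b)  # 700
#' @export
interval_distance <- function(a, b) {
  .check_granges(a)
  .check_granges(b)
  suppressWarnings(GenomicRanges::distance(a, b, ignore.strand = TRUE))
}

#' Merge intervals into a sorted non-redundant set
#'
#' Overlapping and book-ended intervals are merged; the result is sorted
#' and pairwise disjoint, and covers exactly the union of input bases.
#'
#' @param x a `GRanges`; may be empty.
#' @return A sorted, disjoint `GRanges`.
#' @export
merge_intervals <- function(x) {
  .check_granges(x)
  GenomicRanges::reduce(x, ignore.strand = TRUE)
}

#' Fraction of the genome covered by a set of intervals
#'
#' Intervals are merged first, so duplicated or overlapping intervals do
#' not inflate the estimate.
#'
#' @param x a `GRanges` of regions.
#' @param genome a `Seqinfo` genome index.
#' @return Covered fraction in `[0, 1]`.
#' @export
genome_fraction_covered <- function(x, genome) {
  .check_granges(x, genome)
  if (length(x) == 0L) return(0)
  sum(as.numeric(GenomicRanges::width(merge_intervals(x)))) /
    genome_size(genome)
}
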
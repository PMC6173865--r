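#' Construct a genome index
#'
#' A genome index records the ordered chromosomes of the working genome and
#' their lengths. It is represented as a [GenomeInfoDb::Seqinfo] object,
#' the standard Bioconductor container, so that all `GRanges` produced by
#' the package carry chromosome bounds and can be validated against them.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (all > 0).
#' @return A `Seqinfo` object.
#' @examples
#' gi <- genome_index(c("chr1", "chr2"), c(1e6, 1e6))
#' genome_size(gi)
#' @export
genome_index <- function(chrom, length) {
  if (length(chrom) != length(length)) {
    stop("'chrom' and 'length' must have the same length")
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("all chromosome lengths must be positive")
  }
  GenomeInfoDb::Seqinfo(seqnames = as.character(chrom),
                        seqlengths = as.integer(length))
}

#' Total genome length
#'
#' @param genome a `Seqinfo` genome index.
#' @return Total genome length in bp.
#' @export
genome_size <- function(genome) {
  sum(as.numeric(GenomeInfoDb::seqlengths(genome)))
}

#' Read / write a chromosome-sizes file
#'
#' Two tab-separated columns: chromosome name and length.
#'
#' @param file path to the chrom.sizes file.
#' @return `read_chrom_sizes()` returns a `Seqinfo`; `write_chrom_sizes()`
#'   invisibly returns `file`.
#' @export
read_chrom_sizes <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome_index(tab$chrom, tab$length)
}

#' @rdname read_chrom_sizes
#' @param genome a `Seqinfo` genome index to write.
#' @export
write_chrom_sizes <- function(genome, file) {
  tab <- data.frame(chrom = GenomeInfoDb::seqnames(genome),
                    length = GenomeInfoDb::seqlengths(genome))
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

# internal: validate that a GRanges is consistent with a genome index
.check_granges <- function(gr, genome = NULL) {
  if (!methods::is(gr, "GRanges")) stop("expected a GRanges object")
  if (!is.null(genome)) {
    if (!all(as.character(GenomicRanges::seqnames(gr)) %in%
             GenomeInfoDb::seqnames(genome))) {
      stop("interval on a chromosome absent from the genome index")
    }
    sl <- GenomeInfoDb::seqlengths(genome)
    ends <- GenomicRanges::end(gr)
    lim <- sl[as.character(GenomicRanges::seqnames(gr))]
    if (any(GenomicRanges::start(gr) < 1L) || any(ends > lim)) {
      stop("interval out of chromosome bounds")
    }
  }
  invisible(TRUE)
}
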
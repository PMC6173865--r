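#' Read and write BED files
#'
#' Thin wrappers around [rtracklayer::import()]/[rtracklayer::export()]
#' converting between the 0-based half-open on-disk convention and 1-based
#' `GRanges` in memory. Round-tripping a BED record reproduces its
#' coordinates exactly.
#'
#' @param file path to a BED3/BED6 file.
#' @param genome optional `Seqinfo` used to validate coordinates.
#' @return A `GRanges`.
#' @export
read_bed <- function(file, genome = NULL) {
  gr <- rtracklayer::import(file, format = "BED")
  if (!is.null(genome)) .check_granges(gr, genome)
  gr
}

#' @rdname read_bed
#' @param x a `GRanges` to write.
#' @export
write_bed <- function(x, file) {
  rtracklayer::export(x, file, format = "BED")
  invisible(file)
}

#' Construct a peak set
#'
#' Peaks are `GRanges` with metadata columns `summit` (1-based point
#' within the peak), `enrichment` (non-negative score from the peak
#' caller) and `fdr` (in `[0, 1]`). When no summit is available it
#' defaults to the interval midpoint (floored).
#'
#' @param gr a `GRanges` of peak intervals.
#' @param summit integer vector of 1-based summit positions, or `NULL`.
#' @param enrichment numeric vector of non-negative enrichment scores.
#' @param fdr numeric vector of false-discovery rates in `[0, 1]`.
#' @return A `GRanges` with peak metadata columns.
#' @export
peak_set <- function(gr, summit = NULL, enrichment = 1, fdr = 0) {
  .check_granges(gr)
  n <- length(gr)
  if (is.null(summit)) {
    s0 <- GenomicRanges::start(gr) - 1L
    e0 <- GenomicRanges::end(gr)           # 0-based exclusive end
    summit <- floor((s0 + e0) / 2) + 1L    # 0-based midpoint -> 1-based
  }
  summit <- as.integer(summit)
  enrichment <- rep_len(as.numeric(enrichment), n)
  fdr <- rep_len(as.numeric(fdr), n)
  if (any(summit < GenomicRanges::start(gr) | summit > GenomicRanges::end(gr))) {
    stop("summit outside its peak interval")
  }
  if (any(enrichment < 0)) stop("enrichment must be non-negative")
  if (any(fdr < 0 | fdr > 1)) stop("fdr must lie in [0, 1]")
  GenomicRanges::mcols(gr)$summit <- summit
  GenomicRanges::mcols(gr)$enrichment <- enrichment
  GenomicRanges::mcols(gr)$fdr <- fdr
  gr
}

#' Read and write narrowPeak-style peak files
#'
#' Ten tab-separated columns (chrom, start, end, name, score, strand,
#' signalValue, pValue, qValue, peak). Column 7 is taken as the
#' enrichment score; column 9 holds the FDR as a plain probability (not
#' -log10); column 10 is the 0-based summit offset from the peak start,
#' or -1 when absent (the summit then defaults to the interval midpoint).
#'
#' @param file path to a narrowPeak file.
#' @param genome optional `Seqinfo` for validation.
#' @return A peak `GRanges` (see [peak_set()]).
#' @export
read_narrowpeak <- function(file, genome = NULL) {
  tab <- utils::read.table(file, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand", "signalValue",
                                         "pValue", "qValue", "peak"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "numeric", "character",
                                          "numeric", "numeric", "numeric",
                                          "integer"))
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start + 1L, tab$end))
  if (!is.null(genome)) .check_granges(gr, genome)
  summit <- ifelse(tab$peak >= 0L, tab$start + tab$peak + 1L, NA_integer_)
  if (anyNA(summit)) {
    mid <- floor((tab$start + tab$end) / 2) + 1L
    summit[is.na(summit)] <- mid[is.na(summit)]
  }
  names(gr) <- tab$name
  peak_set(gr, summit = summit, enrichment = tab$signalValue, fdr = tab$qValue)
}

#' @rdname read_narrowpeak
#' @param x a peak `GRanges` with `summit`, `enrichment` and `fdr` columns.
#' @export
write_narrowpeak <- function(x, file) {
  m <- GenomicRanges::mcols(x)
  nm <- names(x)
  if (is.null(nm)) nm <- paste0("peak_", seq_along(x))
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                    start = GenomicRanges::start(x) - 1L,
                    end = GenomicRanges::end(x),
                    name = nm,
                    score = 0L,
                    strand = ".",
                    signalValue = m$enrichment,
                    pValue = -1,
                    qValue = m$fdr,
                    peak = m$summit - GenomicRanges::start(x))
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read gene annotation from a GTF file
#'
#' Extracts per-transcript TSSs (strand-aware: the start coordinate on
#' `+`, the end coordinate on `-`) and gene-body intervals from
#' `transcript` records.
#'
#' @param file path to a GTF file.
#' @param genome optional `Seqinfo` for validation.
#' @return A list with elements `tss` (data.frame: `gene_id`,
#'   `transcript_id`, `chrom`, `pos`, `strand`) and `genes` (`GRanges` of
#'   gene bodies, one per transcript, named by `gene_id`).
#' @export
read_gtf_annotation <- function(file, genome = NULL) {
  gr <- rtracklayer::import(file, format = "gtf")
  tx <- gr[gr$type == "transcript"]
  if (length(tx) == 0L) stop("no transcript records in GTF")
  if (!is.null(genome)) .check_granges(tx, genome)
  plus <- as.character(GenomicRanges::strand(tx)) != "-"
  pos <- ifelse(plus, GenomicRanges::start(tx), GenomicRanges::end(tx))
  tss <- data.frame(gene_id = tx$gene_id,
                    transcript_id = tx$transcript_id,
                    chrom = as.character(GenomicRanges::seqnames(tx)),
                    pos = as.integer(pos),
                    strand = as.character(GenomicRanges::strand(tx)),
                    stringsAsFactors = FALSE)
  genes <- GenomicRanges::GRanges(GenomicRanges::seqnames(tx),
                                  IRanges::IRanges(GenomicRanges::start(tx),
                                                   GenomicRanges::end(tx)),
                                  strand = GenomicRanges::strand(tx))
  names(genes) <- tx$gene_id
  list(tss = tss, genes = genes)
}

#' Read a genome FASTA file
#'
#' @param file path to a (optionally faidx-indexed) FASTA file.
#' @return A `DNAStringSet`; names are truncated at the first whitespace.
#' @export
read_genome_fasta <- function(file) {
  seqs <- Biostrings::readDNAStringSet(file)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}
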
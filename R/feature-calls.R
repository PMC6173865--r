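#' Accessible-TSS calls from an ATAC track
#'
#' A TSS is accessible when any bin whose midpoint lies within
#' `dist` bp of the TSS (a 2-kb window by default) exceeds the signal
#' threshold on the 1x-normalized, input-subtracted ATAC track.
#'
#' @param atac a normalized/subtracted ATAC `coverage_track`.
#' @param chrom,pos TSS chromosomes and 1-based positions.
#' @param threshold signal threshold (default 10).
#' @param dist half-window around the TSS in bp (default 1000).
#' @return Logical vector, one call per TSS.
#' @export
call_accessible_tss <- function(atac, chrom, pos, threshold = 10,
                                dist = 1000) {
  stopifnot(inherits(atac, "coverage_track"))
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  bad <- !(chrom %in% names(atac$values))
  if (any(bad)) stop("TSS on a chromosome absent from the track")
  bs <- atac$bin_size
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    v <- atac$values[[ch]]
    k <- .bins_in_window(pos[idx] - 1 - dist, pos[idx] - 1 + dist, bs)
    lo <- pmax(k$lo, 1L)
    hi <- pmin(k$hi, length(v))
    if (any(hi < lo)) stop("TSS window entirely outside the chromosome")
    out[idx] <- vapply(seq_along(idx),
                       function(j) any(v[lo[j]:hi[j]] > threshold),
                       logical(1))
  }
  out
}

#' Call putative enhancers from ATAC and Pol II tracks
#'
#' Bins jointly exceeding the ATAC and Pol II thresholds whose midpoints
#' lie more than `tss_dist` bp from every TSS are selected; runs of
#' selected bins (with up to `merge_gap` unselected bins tolerated
#' between them) are merged into regions of at least `min_width` bins.
#' Each region is reported with its midpoint, mean signals over its
#' bins, and the distance from the midpoint to the nearest TSS.
#'
#' @param atac,polII normalized/subtracted `coverage_track`s on the same
#'   bin grid.
#' @param tss data.frame with `chrom` and `pos` columns (TSS points).
#' @param atac_min,polII_min per-bin signal thresholds (defaults 10, 5).
#' @param tss_dist minimum bin-midpoint distance from any TSS in bp
#'   (strict `>`, default 2000).
#' @param merge_gap tolerated gap between selected bins, in bins
#'   (default 0).
#' @param min_width minimum region width in bins (default 1).
#' @return A `GRanges` of enhancer regions with metadata columns
#'   `midpoint` (1-based), `mean_atac`, `mean_polII`, `tss_distance`.
#' @export
call_enhancers <- function(atac, polII, tss, atac_min = 10, polII_min = 5,
                           tss_dist = 2000, merge_gap = 0, min_width = 1) {
  stopifnot(inherits(atac, "coverage_track"),
            inherits(polII, "coverage_track"))
  if (!.track_compatible(atac, polII)) {
    stop("incompatible tracks: genome or bin size differ")
  }
  bs <- atac$bin_size
  sl <- GenomeInfoDb::seqlengths(atac$genome)
  out <- list()
  for (ch in names(atac$values)) {
    a <- atac$values[[ch]]
    p <- polII$values[[ch]]
    mids0 <- (seq_along(a) - 1) * bs + bs / 2
    tpos0 <- tss$pos[tss$chrom == ch] - 1
    dmin <- .dist_to_nearest_point(mids0, tpos0)
    sel <- a > atac_min & p > polII_min & dmin > tss_dist
    if (!any(sel)) next
    ks <- which(sel)
    ir <- IRanges::reduce(IRanges::IRanges(ks, ks),
                          min.gapwidth = merge_gap + 1L)
    ir <- ir[IRanges::width(ir) >= min_width]
    if (length(ir) == 0L) next
    k1 <- BiocGenerics::start(ir)
    k2 <- BiocGenerics::end(ir)
    s0 <- (k1 - 1L) * bs
    e0 <- pmin(k2 * bs, sl[[ch]])
    mid0 <- floor((s0 + e0) / 2)
    stats_fn <- function(v) {
      vapply(seq_along(k1), function(i) mean(v[k1[i]:k2[i]]), numeric(1))
    }
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(s0 + 1L, e0))
    GenomicRanges::mcols(gr)$midpoint <- mid0 + 1L
    GenomicRanges::mcols(gr)$mean_atac <- stats_fn(a)
    GenomicRanges::mcols(gr)$mean_polII <- stats_fn(p)
    GenomicRanges::mcols(gr)$tss_distance <- .dist_to_nearest_point(mid0,
                                                                    tpos0)
    out[[ch]] <- gr
  }
  if (length(out) == 0L) {
    gr <- GenomicRanges::GRanges()
    GenomicRanges::mcols(gr)$midpoint <- integer(0)
    GenomicRanges::mcols(gr)$mean_atac <- numeric(0)
    GenomicRanges::mcols(gr)$mean_polII <- numeric(0)
    GenomicRanges::mcols(gr)$tss_distance <- numeric(0)
    return(gr)
  }
  res <- suppressWarnings(do.call(c, unname(out)))
  stopifnot(all(GenomicRanges::mcols(res)$tss_distance > tss_dist))
  res
}

# distance from each query position to the nearest of a sorted point set
# (Inf when the point set is empty)
.dist_to_nearest_point <- function(q, pts) {
  if (length(pts) == 0L) return(rep(Inf, length(q)))
  pts <- sort(pts)
  i <- findInterval(q, pts)
  d_lo <- ifelse(i >= 1L, q - pts[pmax(i, 1L)], Inf)
  d_hi <- ifelse(i < length(pts), pts[pmin(i + 1L, length(pts))] - q, Inf)
  pmin(d_lo, d_hi)
}

#' Write enhancer calls
#'
#' BED6 with the mean ATAC signal in the score column, plus a companion
#' TSV with both signal means and the TSS distance.
#'
#' @param enhancers a `GRanges` from [call_enhancers()].
#' @param bed_file,tsv_file output paths (`NULL` to skip either).
#' @export
write_enhancers <- function(enhancers, bed_file = NULL, tsv_file = NULL) {
  m <- GenomicRanges::mcols(enhancers)
  if (!is.null(bed_file)) {
    tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(enhancers)),
                      start = GenomicRanges::start(enhancers) - 1L,
                      end = GenomicRanges::end(enhancers),
                      name = paste0("enh_", seq_along(enhancers)),
                      score = sprintf("%.4f", m$mean_atac),
                      strand = ".")
    utils::write.table(tab, bed_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_file)) {
    tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(enhancers)),
                      start = GenomicRanges::start(enhancers) - 1L,
                      end = GenomicRanges::end(enhancers),
                      midpoint = m$midpoint,
                      mean_atac = m$mean_atac,
                      mean_polII = m$mean_polII,
                      tss_distance = m$tss_distance)
    utils::write.table(tab, tsv_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(enhancers)
}
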
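#' Binned genome coverage tracks
#'
#' A `coverage_track` stores one numeric value per fixed-width genomic bin
#' (50 bp by default, matching common ChIP-seq practice), per chromosome.
#' Bin `k` of a chromosome covers 0-based coordinates
#' `[(k-1)*bin_size, k*bin_size)`; the last bin is truncated at the
#' chromosome end. Values may be negative after input subtraction.
#'
#' @param values named list of numeric vectors, one per chromosome, or a
#'   single numeric vector when `genome` has one chromosome.
#' @param genome a `Seqinfo` genome index.
#' @param bin_size bin width in bp (> 0).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, genome, bin_size = 50) {
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size <= 0L) stop("bin_size must be positive")
  chroms <- GenomeInfoDb::seqnames(genome)
  if (is.numeric(values) && length(chroms) == 1L) {
    values <- stats::setNames(list(values), chroms)
  }
  if (!is.list(values) || is.null(names(values))) {
    stop("'values' must be a named list of per-chromosome numeric vectors")
  }
  if (!setequal(names(values), chroms)) {
    stop("track chromosomes do not match the genome index")
  }
  values <- values[chroms]
  nb <- .n_bins(genome, bin_size)
  for (ch in chroms) {
    if (length(values[[ch]]) != nb[[ch]]) {
      stop(sprintf("chromosome %s: expected %d bins, got %d",
                   ch, nb[[ch]], length(values[[ch]])))
    }
    values[[ch]] <- as.numeric(values[[ch]])
  }
  structure(list(values = values, genome = genome, bin_size = bin_size),
            class = "coverage_track")
}

.n_bins <- function(genome, bin_size) {
  sl <- GenomeInfoDb::seqlengths(genome)
  stats::setNames(as.integer(ceiling(sl / bin_size)), names(sl))
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosome(s), bin %d bp, %d bins\n",
              length(x$values), x$bin_size,
              sum(lengths(x$values))))
  invisible(x)
}

.track_compatible <- function(a, b) {
  identical(a$bin_size, b$bin_size) &&
    identical(GenomeInfoDb::seqlengths(a$genome),
              GenomeInfoDb::seqlengths(b$genome))
}

.all_bins <- function(track) unlist(track$values, use.names = FALSE)

#' Scale a track to 1x genome-wide coverage
#'
#' Multiplies the track by the single global scalar that makes the
#' genome-wide mean bin value exactly 1, so that tracks from libraries of
#' different depth become comparable and input subtraction is meaningful.
#'
#' @param track a `coverage_track` with non-zero mean.
#' @return The rescaled `coverage_track`.
#' @export
normalize_1x <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  m <- mean(.all_bins(track))
  if (!is.finite(m) || m == 0) {
    stop("degenerate track: genome-wide mean is zero, cannot normalize")
  }
  track$values <- lapply(track$values, function(v) v / m)
  track
}

#' Subtract an input track from a ChIP track
#'
#' Element-wise subtraction of two tracks on the same genome and bin
#' grid; both are expected to be 1x-normalized first. Negative values are
#' preserved (depletion relative to input is informative).
#'
#' @param chip,input `coverage_track` objects on the same grid.
#' @return A `coverage_track` of differences.
#' @export
subtract_input <- function(chip, input) {
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  if (!.track_compatible(chip, input)) {
    stop("incompatible tracks: genome or bin size differ")
  }
  chip$values <- Map(`-`, chip$values, input$values)
  chip
}

# bin index range whose midpoints fall in [lo, hi) (0-based coords)
.bins_in_window <- function(lo, hi, bin_size) {
  k_lo <- as.integer(ceiling(lo / bin_size + 0.5 - 1e-9))
  k_hi <- as.integer(ceiling(hi / bin_size + 0.5 - 1e-9)) - 1L
  list(lo = k_lo, hi = k_hi)
}

#' Mean signal in windows centred on genomic points
#'
#' For each centre, averages the bins whose midpoints lie within
#' `[centre - width/2, centre + width/2)`. Windows truncated at a
#' chromosome end average only the existing bins; a window entirely off
#' the chromosome is an error.
#'
#' @param track a `coverage_track`.
#' @param chrom character vector of chromosome names (recycled if length 1).
#' @param pos integer vector of 1-based centre positions.
#' @param width window width in bp (default 2000, i.e. a 2-kb locus).
#' @return Numeric vector of window means, one per centre.
#' @export
window_means <- function(track, chrom, pos, width = 2000) {
  stopifnot(inherits(track, "coverage_track"))
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  if (length(chrom) != length(pos)) stop("'chrom' and 'pos' lengths differ")
  bad <- !(chrom %in% names(track$values))
  if (any(bad)) stop("position on a chromosome absent from the track")
  out <- numeric(length(pos))
  bs <- track$bin_size
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    v <- track$values[[ch]]
    cs <- c(0, cumsum(v))
    p0 <- pos[idx] - 1
    k <- .bins_in_window(p0 - width / 2, p0 + width / 2, bs)
    lo <- pmax(k$lo, 1L)
    hi <- pmin(k$hi, length(v))
    if (any(hi < lo)) stop("window entirely outside the chromosome")
    out[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

#' @rdname window_means
#' @param center a single 1-based centre position.
#' @export
window_mean <- function(track, chrom, center, width = 2000) {
  window_means(track, chrom, center, width)
}

#' Thresholded log transform for signal display
#'
#' `log2(1 + max(x, floor))`: clips values below `floor` (by default
#' negative post-subtraction values) before a log2(1 + x) transform, the
#' conventional scale for visualising normalized ChIP signal.
#'
#' @param x numeric vector.
#' @param floor lower clip value (default 0).
#' @return Transformed numeric vector.
#' @export
threshold_log <- function(x, floor = 0) {
  log2(1 + pmax(x, floor))
}

#' CpG density track from a genome sequence
#'
#' Counts CG dinucleotide start positions per bin (a CG straddling a bin
#' boundary is assigned to the bin containing its C) and expresses the
#' count as a percentage of bin positions, so that 5 CpG sites in a 50-bp
#' window score 10%. Matching is case-insensitive and any dinucleotide
#' containing an ambiguous base contributes nothing.
#'
#' @param seqs a `DNAStringSet` (one entry per chromosome) or the path to
#'   a FASTA file.
#' @param bin_size bin width in bp (default 50).
#' @param genome optional `Seqinfo`; must agree with the sequence lengths.
#' @return A `coverage_track` in percent units.
#' @export
cpg_density_track <- function(seqs, bin_size = 50, genome = NULL) {
  if (is.character(seqs)) seqs <- read_genome_fasta(seqs)
  stopifnot(methods::is(seqs, "DNAStringSet"))
  sl <- stats::setNames(Biostrings::width(seqs), names(seqs))
  if (is.null(genome)) {
    genome <- genome_index(names(sl), sl)
  } else if (!identical(as.integer(GenomeInfoDb::seqlengths(genome)[names(sl)]),
                        as.integer(sl)) ||
             !setequal(GenomeInfoDb::seqnames(genome), names(sl))) {
    stop("FASTA sequences do not match the genome index")
  }
  nb <- .n_bins(genome, bin_size)
  values <- lapply(names(sl), function(ch) {
    hits <- Biostrings::matchPattern("CG", seqs[[ch]], fixed = TRUE)
    starts0 <- BiocGenerics::start(hits) - 1L
    counts <- tabulate(starts0 %/% bin_size + 1L, nbins = nb[[ch]])
    100 * counts / bin_size
  })
  coverage_track(stats::setNames(values, names(sl)), genome, bin_size)
}

#' Signal matrix around a set of loci
#'
#' Heatmap-style matrix: one row per locus, one column per bin of the
#' `2 * flank` window centred on the locus (columns are the track bins
#' whose midpoints fall inside the window, left to right). Bins beyond a
#' chromosome end are `NA` and are excluded from row summaries. Rows may
#' be ordered by a sort key (e.g. target signal for TSS heatmaps, or
#' region size for CGI heatmaps).
#'
#' @param track a `coverage_track`.
#' @param chrom,pos locus chromosomes and 1-based centre positions.
#' @param flank half-window in bp (default 3000, i.e. 6-kb regions);
#'   must be a multiple of the bin size.
#' @param sort_by optional numeric key, one value per locus; rows are
#'   ordered by decreasing key.
#' @return A `signal_matrix` object: list with `values` (matrix),
#'   `chrom`, `pos`, `flank`, `bin_size`, `order`.
#' @export
build_signal_matrix <- function(track, chrom, pos, flank = 3000,
                                sort_by = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  bs <- track$bin_size
  if (flank %% bs != 0) stop("flank must be a multiple of the bin size")
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  ncol <- as.integer(2 * flank / bs)
  mat <- matrix(NA_real_, nrow = length(pos), ncol = ncol)
  for (i in seq_along(pos)) {
    v <- track$values[[chrom[i]]]
    if (is.null(v)) stop("locus on a chromosome absent from the track")
    p0 <- pos[i] - 1
    k <- .bins_in_window(p0 - flank, p0 + flank, bs)
    ks <- k$lo:(k$lo + ncol - 1L)
    ok <- ks >= 1L & ks <= length(v)
    mat[i, ok] <- v[ks[ok]]
  }
  ord <- seq_along(pos)
  if (!is.null(sort_by)) {
    if (length(sort_by) != length(pos)) stop("sort key length mismatch")
    ord <- order(sort_by, decreasing = TRUE)
    mat <- mat[ord, , drop = FALSE]
  }
  structure(list(values = mat, chrom = chrom[ord], pos = pos[ord],
                 flank = flank, bin_size = bs, order = ord),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d loci x %d bins (flank %d bp, bin %d bp)\n",
              nrow(x$values), ncol(x$values), x$flank, x$bin_size))
  invisible(x)
}

#' Read and write bedGraph coverage tracks
#'
#' `read_bedgraph_track()` imports a 4-column bedGraph (0-based
#' half-open) and re-bins it onto the track's fixed grid by
#' length-weighted averaging (uncovered bases count as 0);
#' `write_bedgraph()` writes one line per bin. A write/read round trip on
#' the same grid reproduces the bin values.
#'
#' @param file path to a bedGraph file.
#' @param genome a `Seqinfo` genome index.
#' @param bin_size target bin width in bp.
#' @return A `coverage_track`.
#' @export
read_bedgraph_track <- function(file, genome, bin_size = 50) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  .check_granges(gr, genome)
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome)
  GenomeInfoDb::seqinfo(gr) <- genome
  bins <- GenomicRanges::tileGenome(GenomeInfoDb::seqlengths(genome),
                                    tilewidth = bin_size,
                                    cut.last.tile.in.chrom = TRUE)
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  avg <- GenomicRanges::binnedAverage(bins, cov, "value")
  values <- split(avg$value, as.character(GenomicRanges::seqnames(avg)))
  coverage_track(values[GenomeInfoDb::seqnames(genome)], genome, bin_size)
}

#' @rdname read_bedgraph_track
#' @param track a `coverage_track` to write.
#' @export
write_bedgraph <- function(track, file) {
  stopifnot(inherits(track, "coverage_track"))
  bs <- track$bin_size
  sl <- GenomeInfoDb::seqlengths(track$genome)
  con <- file(file, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    start0 <- (seq_along(v) - 1L) * bs
    end0 <- pmin(start0 + bs, sl[[ch]])
    utils::write.table(data.frame(ch, start0, end0, sprintf("%.10g", v)),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}
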
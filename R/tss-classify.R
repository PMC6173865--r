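#' CGI status of TSS points
#'
#' A TSS is CGI-associated when its distance to the nearest CpG island is
#' below `max_dist` (default 1 kb; 0 when the TSS lies inside an island).
#'
#' @param chrom,pos TSS chromosomes and 1-based positions.
#' @param cgis `GRanges` of CpG islands.
#' @param max_dist distance threshold in bp (strict `<`).
#' @return Logical vector, one flag per TSS.
#' @export
classify_cgi_tss <- function(chrom, pos, cgis, max_dist = 1000) {
  .check_granges(cgis)
  pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  .near_any(pts, cgis, max_dist)
}

# distance from each point/interval in `x` to nearest interval in `y`,
# strict `< max_dist` flag; FALSE when `y` has nothing on the chromosome
.near_any <- function(x, y, max_dist) {
  out <- logical(length(x))
  if (length(y) == 0L) return(out)
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(x, y, ignore.strand = TRUE))
  out[S4Vectors::queryHits(hits)] <-
    S4Vectors::mcols(hits)$distance < max_dist
  out
}

#' Genomic category of peak summits
#'
#' Allocates each summit to the first matching category, in order:
#' \enumerate{
#'   \item `CGI_TSS` — within 1 kb of a TSS and inside or within 1 kb of
#'     a CGI;
#'   \item `CGI_genic` — inside a CGI and inside a gene body;
#'   \item `CGI_intergenic` — inside a CGI;
#'   \item `TSS` — within 1 kb of a TSS;
#'   \item `genic` — inside a gene body;
#'   \item `intergenic` — otherwise.
#' }
#' The categories are mutually exclusive and exhaustive, so the category
#' counts over a peak set always sum to the set size.
#'
#' @param chrom,pos summit chromosomes and 1-based positions.
#' @param tss data.frame with `chrom` and `pos` columns (TSS points).
#' @param genes `GRanges` of gene bodies.
#' @param cgis `GRanges` of CpG islands.
#' @param tss_dist,cgi_dist proximity thresholds in bp (strict `<`).
#' @return Factor with levels `CGI_TSS`, `CGI_genic`, `CGI_intergenic`,
#'   `TSS`, `genic`, `intergenic`.
#' @export
classify_summit <- function(chrom, pos, tss, genes, cgis,
                            tss_dist = 1000, cgi_dist = 1000) {
  pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  tss_pts <- GenomicRanges::GRanges(tss$chrom, IRanges::IRanges(tss$pos,
                                                                tss$pos))
  near_tss <- .near_any(pts, tss_pts, tss_dist)
  near_cgi <- .near_any(pts, cgis, cgi_dist)
  in_cgi <- GenomicRanges::countOverlaps(pts, cgis, ignore.strand = TRUE) > 0
  in_gene <- GenomicRanges::countOverlaps(pts, genes, ignore.strand = TRUE) > 0
  lv <- c("CGI_TSS", "CGI_genic", "CGI_intergenic", "TSS", "genic",
          "intergenic")
  cat <- ifelse(near_tss & near_cgi, "CGI_TSS",
         ifelse(in_cgi & in_gene, "CGI_genic",
         ifelse(in_cgi, "CGI_intergenic",
         ifelse(near_tss, "TSS",
         ifelse(in_gene, "genic", "intergenic")))))
  factor(cat, levels = lv)
}

#' Build the per-TSS record table
#'
#' Combines the annotation-derived TSS list with CGI status,
#' accessibility calls and per-gene expression classes into the table
#' consumed by the allocation and signal-model stages. A gene with
#' several TSSs receives per-TSS CGI and accessibility flags, while its
#' expression class is a gene-level property shared by all its TSSs.
#'
#' @param tss data.frame from [read_gtf_annotation()] (`gene_id`,
#'   `transcript_id`, `chrom`, `pos`, `strand`).
#' @param cgis `GRanges` of CpG islands.
#' @param atac optional 1x-normalized, input-subtracted ATAC
#'   `coverage_track` used for accessibility calls.
#' @param gene_classes optional data.frame from [classify_genes()] (row
#'   names = gene ids); genes absent from it are classed `other`.
#' @param cgi_dist CGI proximity threshold in bp.
#' @param atac_threshold,atac_dist accessibility rule parameters (see
#'   [call_accessible_tss()]).
#' @return The `tss` data.frame with added `is_cgi`, `is_accessible` and
#'   `gene_class` columns.
#' @export
build_tss_records <- function(tss, cgis, atac = NULL, gene_classes = NULL,
                              cgi_dist = 1000, atac_threshold = 10,
                              atac_dist = 1000) {
  tss$is_cgi <- classify_cgi_tss(tss$chrom, tss$pos, cgis, cgi_dist)
  tss$is_accessible <- if (is.null(atac)) NA else {
    call_accessible_tss(atac, tss$chrom, tss$pos,
                        threshold = atac_threshold, dist = atac_dist)
  }
  tss$gene_class <- if (is.null(gene_classes)) "other" else {
    cls <- gene_classes[tss$gene_id, "class"]
    ifelse(is.na(cls), "other", cls)
  }
  tss
}
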
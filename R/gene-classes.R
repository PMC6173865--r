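#' RPKM from a read count
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `count / ((length/1000) * (library_size/1e6))`.
#'
#' @param count non-negative read count.
#' @param transcript_length transcript length in bp (> 0).
#' @param library_size total mapped reads in the library (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, transcript_length, library_size) {
  if (any(transcript_length <= 0)) stop("transcript_length must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  count / ((transcript_length / 1000) * (library_size / 1e6))
}

#' Classify housekeeping genes from a multi-tissue RPKM matrix
#'
#' A gene is called housekeeping when it is expressed everywhere at a
#' near-constant level, under three clauses applied to its RPKM profile
#' across tissues:
#' \enumerate{
#'   \item RPKM >= `rpkm_floor` (default 0.1) in every tissue;
#'   \item standard deviation of log2(RPKM) < `sd_max` (default 1);
#'   \item no tissue with |log2(RPKM / mean RPKM)| > `ratio_log2_max`
#'     (default 2), i.e. all expression ratios to the (arithmetic) mean
#'     below 4 in either direction.
#' }
#' Logs are computed on values floored at `rpkm_floor` so they stay
#' finite; clause 1 uses the raw values. The standard deviation uses the
#' sample (n-1) denominator. Calls are invariant to tissue order.
#'
#' @param expr numeric matrix, genes in rows, tissues in columns; no
#'   missing values allowed.
#' @param rpkm_floor,sd_max,ratio_log2_max clause thresholds (see above).
#' @return A data.frame with per-gene statistics (`min_rpkm`, `sd_log2`,
#'   `max_abs_log2_ratio`) and the logical call `housekeeping`.
#' @export
classify_housekeeping <- function(expr, rpkm_floor = 0.1, sd_max = 1,
                                  ratio_log2_max = 2) {
  expr <- as.matrix(expr)
  if (anyNA(expr)) stop("missing expression values")
  if (ncol(expr) < 2L) stop("need at least two tissues")
  fl <- pmax(expr, rpkm_floor)
  lg <- log2(fl)
  sd_log2 <- apply(lg, 1L, stats::sd)
  mean_rpkm <- rowMeans(fl)
  max_ratio <- apply(abs(lg - log2(mean_rpkm)), 1L, max)
  res <- data.frame(min_rpkm = apply(expr, 1L, min),
                    sd_log2 = sd_log2,
                    max_abs_log2_ratio = max_ratio,
                    row.names = rownames(expr))
  res$housekeeping <- res$min_rpkm >= rpkm_floor &
    res$sd_log2 < sd_max & res$max_abs_log2_ratio <= ratio_log2_max
  res
}

#' Classify tissue-specific genes for a target cell type
#'
#' Two-step rule. A gene is a candidate ("normally non-expressed") when
#' either all reference-tissue RPKMs are <= `low` (default 0.1), or
#' strictly more than half of the tissues have RPKM <= `frac_low`
#' (default 10%) of the gene's maximum across tissues. A candidate is
#' tissue-specific in the target cell when its expression there is at
#' least `frac_high` (default 50%) of that maximum.
#'
#' Raising the cell expression never revokes the label (monotonicity).
#'
#' @param expr reference RPKM matrix, genes in rows, tissues in columns.
#' @param cell_expr per-gene RPKM in the target cell type, in row order
#'   of `expr` (for replicated samples, average them first).
#' @param low absolute low-expression threshold (RPKM).
#' @param frac_low fraction of the maximum defining "low" per tissue.
#' @param frac_high fraction of the maximum the target cell must reach.
#' @return A data.frame with `max_rpkm`, `n_low`, the logical
#'   `candidate` and the logical call `tissue_specific`.
#' @export
classify_tissue_specific <- function(expr, cell_expr, low = 0.1,
                                     frac_low = 0.1, frac_high = 0.5) {
  expr <- as.matrix(expr)
  if (anyNA(expr) || anyNA(cell_expr)) stop("missing expression values")
  if (length(cell_expr) != nrow(expr)) {
    stop("cell_expr must have one value per gene")
  }
  mx <- apply(expr, 1L, max)
  n_low <- rowSums(expr <= frac_low * mx)
  candidate <- mx <= low | n_low > ncol(expr) / 2
  data.frame(max_rpkm = mx, n_low = n_low, candidate = candidate,
             tissue_specific = candidate & cell_expr >= frac_high * mx,
             row.names = rownames(expr))
}

#' Read an RPKM matrix from a TSV file
#'
#' Genes in rows (first column = gene id), samples in columns, header
#' row required.
#'
#' @param file path to the TSV file.
#' @return Numeric matrix with gene ids as row names.
#' @export
read_rpkm_matrix <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = TRUE,
                           row.names = 1, check.names = FALSE)
  as.matrix(tab)
}

#' @rdname read_rpkm_matrix
#' @param expr numeric matrix to write (row names = gene ids).
#' @export
write_rpkm_matrix <- function(expr, file) {
  tab <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Combined gene-class table
#'
#' Applies [classify_housekeeping()] and [classify_tissue_specific()]
#' and resolves each gene to a single class: `housekeeping`,
#' `tissue_specific` (in the target cell) or `other`. The two labels are
#' mutually exclusive by construction of the rules (a housekeeping gene
#' is expressed in all tissues and therefore never a candidate).
#'
#' @inheritParams classify_tissue_specific
#' @inheritParams classify_housekeeping
#' @return A data.frame with the supporting statistics and a `class`
#'   column.
#' @export
classify_genes <- function(expr, cell_expr, rpkm_floor = 0.1, sd_max = 1,
                           ratio_log2_max = 2, frac_low = 0.1,
                           frac_high = 0.5) {
  hk <- classify_housekeeping(expr, rpkm_floor, sd_max, ratio_log2_max)
  ts <- classify_tissue_specific(expr, cell_expr, low = rpkm_floor,
                                 frac_low = frac_low, frac_high = frac_high)
  cls <- ifelse(hk$housekeeping, "housekeeping",
                ifelse(ts$tissue_specific, "tissue_specific", "other"))
  cbind(hk, ts[, c("max_rpkm", "candidate", "tissue_specific")],
        data.frame(class = cls, row.names = rownames(hk)))
}
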
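#' Combined chromatin accessibility score
#'
#' DNase and ATAC window means are each z-score transformed across loci
#' (sample standard deviation) and averaged, giving a single
#' accessibility score with equal weight to both assays. The score is
#' invariant to affine rescaling of either input signal.
#'
#' @param dnase,atac per-locus signal vectors of equal length (>= 2).
#' @return Per-locus accessibility scores (mean 0 by construction).
#' @export
accessibility_score <- function(dnase, atac) {
  if (length(dnase) != length(atac)) stop("input vectors differ in length")
  if (length(dnase) < 2L) stop("need at least two loci")
  z <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("degenerate input: zero variance in an accessibility signal")
    }
    (x - mean(x)) / s
  }
  (z(dnase) + z(atac)) / 2
}

#' Pearson correlation and its square
#'
#' @param x,y per-locus signal vectors (>= 3 loci, non-constant).
#' @return A list with `r` and `r2`.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("input vectors differ in length")
  if (length(x) < 3L) stop("need at least three loci")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant vector")
  }
  r <- stats::cor(x, y)
  list(r = r, r2 = r^2)
}

#' Locus-by-feature signal matrix
#'
#' One row per non-redundant locus (TSS points plus enhancer midpoints;
#' exact duplicate positions are dropped), one column per feature track,
#' each value the 2-kb window mean of the normalized, input-subtracted
#' track at the locus. When both `DNase` and `ATAC` columns are present
#' an `accessibility` column (see [accessibility_score()]) is appended.
#'
#' @param tracks named list of `coverage_track`s (feature name -> track).
#' @param chrom,pos locus chromosomes and 1-based positions.
#' @param locus_id optional locus identifiers.
#' @param locus_type optional locus type annotation (e.g. `"TSS"` /
#'   `"enhancer"`), carried through to the output.
#' @param width window width in bp (default 2000).
#' @param dnase_col,atac_col feature names used for the accessibility
#'   score.
#' @return A data.frame: `locus_id`, `chrom`, `pos`, `locus_type`, one
#'   column per feature, and `accessibility` when computable.
#' @export
locus_signal_matrix <- function(tracks, chrom, pos, locus_id = NULL,
                                locus_type = NULL, width = 2000,
                                dnase_col = "DNase", atac_col = "ATAC") {
  if (is.null(names(tracks))) stop("'tracks' must be a named list")
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  if (is.null(locus_id)) locus_id <- paste0("locus_", seq_along(pos))
  if (is.null(locus_type)) locus_type <- rep(NA_character_, length(pos))
  keep <- !duplicated(paste(chrom, pos))
  chrom <- chrom[keep]; pos <- pos[keep]
  locus_id <- locus_id[keep]; locus_type <- locus_type[keep]
  df <- data.frame(locus_id = locus_id, chrom = chrom, pos = pos,
                   locus_type = locus_type, stringsAsFactors = FALSE)
  for (nm in names(tracks)) {
    df[[nm]] <- window_means(tracks[[nm]], chrom, pos, width)
  }
  if (all(c(dnase_col, atac_col) %in% names(df))) {
    df$accessibility <- accessibility_score(df[[dnase_col]], df[[atac_col]])
  }
  df
}

#' Select loci in the top accessibility decile
#'
#' Keeps loci whose accessibility score reaches the 90th percentile
#' (linear interpolation, ties at the threshold included).
#'
#' @param matrix a data.frame from [locus_signal_matrix()].
#' @param percentile retained top percentage (default 10).
#' @param score_col column holding the score (default `"accessibility"`).
#' @return The subset data.frame.
#' @export
select_top_accessible <- function(matrix, percentile = 10,
                                  score_col = "accessibility") {
  sc <- matrix[[score_col]]
  if (is.null(sc)) stop("no accessibility score column")
  thr <- stats::quantile(sc, 1 - percentile / 100, names = FALSE, type = 7)
  matrix[sc >= thr, , drop = FALSE]
}

#' Linear variance decomposition of a target signal
#'
#' Ordinary least squares of the response feature on the given
#' explanatory features plus an intercept. Reports the coefficient table
#' with standard errors, the single-feature (marginal) R-squared of each
#' feature, the joint multiple R-squared, and the analysis-of-variance
#' partition both as sequential sums of squares (in the supplied feature
#' order) and as each feature's marginal contribution when added last.
#'
#' @param data data.frame of per-locus window means (>= 10 rows).
#' @param response response column name (e.g. the target ChIP signal).
#' @param features character vector of explanatory column names.
#' @return An object of class `variance_decomposition`: list with
#'   `coefficients` (data.frame: estimate, se, t), `marginal_r2`,
#'   `joint_r2`, `anova_sequential`, `anova_last` (data.frames with
#'   `term`, `df`, `sum_sq`, `frac_var`), `sigma`, `n`, and the fitted
#'   `model`.
#' @export
variance_decomposition <- function(data, response, features) {
  if (nrow(data) < 10L) stop("need at least 10 loci")
  cols <- c(response, features)
  if (!all(cols %in% names(data))) stop("missing response or feature column")
  d <- data[, cols, drop = FALSE]
  X <- as.matrix(d[, features, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop("degenerate input: rank-deficient design")
  }
  fml <- stats::reformulate(features, response = response)
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients[, 1:3, drop = FALSE])
  names(co) <- c("estimate", "se", "t")
  marginal <- vapply(features, function(f) {
    summary(stats::lm(stats::reformulate(f, response = response),
                      data = d))$r.squared
  }, numeric(1))
  an <- stats::anova(fit)
  tot_ss <- sum(an[["Sum Sq"]])
  seq_tab <- data.frame(term = rownames(an), df = an$Df,
                        sum_sq = an[["Sum Sq"]],
                        frac_var = an[["Sum Sq"]] / tot_ss)
  last_ss <- vapply(features, function(f) {
    rest <- setdiff(features, f)
    red_fml <- if (length(rest)) stats::reformulate(rest,
                                                    response = response)
    else stats::reformulate("1", response = response)
    red <- stats::lm(red_fml, data = d)
    sum(stats::resid(red)^2) - sum(stats::resid(fit)^2)
  }, numeric(1))
  last_tab <- data.frame(term = features, df = 1L, sum_sq = last_ss,
                         frac_var = last_ss / tot_ss)
  structure(list(coefficients = co,
                 marginal_r2 = marginal,
                 joint_r2 = sm$r.squared,
                 anova_sequential = seq_tab,
                 anova_last = last_tab,
                 sigma = sm$sigma, n = nrow(d), model = fit),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("variance_decomposition: n = %d, joint R^2 = %.3f\n",
              x$n, x$joint_r2))
  cat("marginal R^2:\n")
  print(round(x$marginal_r2, 3))
  invisible(x)
}

#' Fraction of motif occurrences falling inside CpG islands
#'
#' Scans both strands of the genome for exact IUPAC-consensus matches
#' (overlapping matches counted; a palindromic motif is scanned on one
#' strand only, so each strandless site is counted once) and reports the
#' fraction of matches whose start coordinate lies inside a CGI,
#' together with the companion statistic: the fraction of genomic CG
#' dinucleotides inside CGIs.
#'
#' @param motif IUPAC consensus string (length >= 4).
#' @param seqs genome `DNAStringSet` or FASTA path.
#' @param cgis `GRanges` of CpG islands.
#' @return A list: `fraction`, `n_matches`, `n_in_cgi`, `cg_fraction`,
#'   `n_cg`.
#' @export
motif_scan_fraction <- function(motif, seqs, cgis) {
  if (nchar(motif) < 4L) stop("motif must be at least 4 bases")
  if (is.character(seqs)) seqs <- read_genome_fasta(seqs)
  fwd <- Biostrings::DNAString(motif)
  rev <- Biostrings::reverseComplement(fwd)
  palindromic <- as.character(fwd) == as.character(rev)
  scan_starts <- function(pat, subject) {
    BiocGenerics::start(Biostrings::matchPattern(pat, subject,
                                                 fixed = FALSE))
  }
  count_hits <- function(pat) {
    tot <- 0L; hit <- 0L
    for (ch in names(seqs)) {
      st <- scan_starts(pat, seqs[[ch]])
      if (length(st) == 0L) next
      pts <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, st))
      tot <- tot + length(st)
      hit <- hit + sum(GenomicRanges::countOverlaps(pts, cgis,
                                                    ignore.strand = TRUE) > 0)
    }
    c(tot, hit)
  }
  counts <- count_hits(fwd)
  if (!palindromic) counts <- counts + count_hits(rev)
  if (counts[1] == 0L) stop("motif not found in the genome")
  cg <- count_hits(Biostrings::DNAString("CG"))
  list(fraction = counts[2] / counts[1],
       n_matches = counts[1], n_in_cgi = counts[2],
       cg_fraction = cg[2] / cg[1], n_cg = cg[1])
}
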
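#' Pairwise peak colocalisation
#'
#' Two peaks are colocalised when they lie on the same chromosome and
#' the gap between their intervals is at most `max_gap` (1 kb by
#' default, the conventional tolerance for ChIP peak colocalisation).
#' The relation is symmetric: `a` partners `b` iff `b` partners `a`.
#'
#' @param a,b peak `GRanges`.
#' @param max_gap maximum tolerated gap in bp.
#' @return A list: `pairs` (data.frame of colocalised index pairs with
#'   their gap), `n_a_hit` / `n_b_hit` (peaks of each set with at least
#'   one partner).
#' @export
colocalise <- function(a, b, max_gap = 1000) {
  .check_granges(a)
  .check_granges(b)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(a, b, maxgap = max_gap,
                                ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  gaps <- if (length(qi)) {
    suppressWarnings(GenomicRanges::distance(a[qi], b[si],
                                             ignore.strand = TRUE))
  } else integer(0)
  list(pairs = data.frame(a_idx = qi, b_idx = si, distance = gaps),
       n_a_hit = length(unique(qi)),
       n_b_hit = length(unique(si)))
}

#' Multi-set co-occupancy (Venn decomposition) of peak sets
#'
#' Builds a graph over all peaks of all sets, connecting any two peaks
#' (regardless of set) whose gap is at most `max_gap`. Each connected
#' component is one colocalisation region and is labelled by the subset
#' of peak-set names present in it, so chains of peaks are counted once
#' (transitive closure) and every peak belongs to exactly one component.
#'
#' @param peak_sets named list (>= 2 entries) of peak `GRanges`.
#' @param max_gap maximum tolerated gap in bp.
#' @return A list: `counts` (named integer vector, one entry per
#'   observed label, names are sorted set names joined by `&`),
#'   `membership` (component id per peak, in concatenation order),
#'   `sets` (set name per peak), `n_components`.
#' @export
multi_venn <- function(peak_sets, max_gap = 1000) {
  if (length(peak_sets) < 2L || is.null(names(peak_sets))) {
    stop("need a named list of at least two peak sets")
  }
  set_of <- rep(names(peak_sets), lengths(peak_sets))
  all_gr <- do.call(c, lapply(unname(peak_sets), function(g) {
    GenomicRanges::granges(g, use.mcols = FALSE)
  }))
  n <- length(all_gr)
  if (n == 0L) {
    return(list(counts = integer(0), membership = integer(0),
                sets = character(0), n_components = 0L))
  }
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(all_gr, maxgap = max_gap,
                                ignore.strand = TRUE,
                                drop.self = TRUE, drop.redundant = TRUE))
  edges <- data.frame(from = S4Vectors::queryHits(hits),
                      to = S4Vectors::subjectHits(hits))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  memb <- igraph::components(g)$membership
  memb <- memb[as.character(seq_len(n))]
  labels <- vapply(split(set_of, memb), function(s) {
    paste(sort(unique(s)), collapse = "&")
  }, character(1))
  counts <- table(labels)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       membership = as.integer(memb),
       sets = set_of,
       n_components = length(labels))
}

#' High-confidence regions from the top decile of peak scores
#'
#' For each peak set, keeps the peaks whose enrichment score reaches the
#' set's 90th percentile (linear interpolation; ties at the threshold
#' are kept, so the most enriched tenth is never truncated by ties), and
#' merges the union across sets into a non-redundant interval set.
#'
#' @param peak_sets named list of peak `GRanges` with an `enrichment`
#'   metadata column.
#' @param percentile the retained top percentage (default 10).
#' @return A list: `regions` (merged `GRanges`), `kept` (named list of
#'   the surviving peaks per set), `thresholds` (per-set score cutoff).
#' @export
high_confidence_regions <- function(peak_sets, percentile = 10) {
  if (length(peak_sets) == 0L) stop("empty peak-set list")
  thresholds <- vapply(peak_sets, function(g) {
    sc <- GenomicRanges::mcols(g)$enrichment
    if (is.null(sc) || length(sc) == 0L) stop("peak set without scores")
    stats::quantile(sc, 1 - percentile / 100, names = FALSE, type = 7)
  }, numeric(1))
  kept <- Map(function(g, thr) g[GenomicRanges::mcols(g)$enrichment >= thr],
              peak_sets, thresholds)
  regions <- merge_intervals(do.call(c, lapply(unname(kept), function(g) {
    GenomicRanges::granges(g, use.mcols = FALSE)
  })))
  list(regions = regions, kept = kept, thresholds = thresholds)
}

#' Binomial over-representation of peaks in a region set
#'
#' Given `k` of `n` peaks falling in target regions that cover a
#' fraction `f` of the genome, reports the fold enrichment
#' `(k/n) / f` and the one-sided upper-tail binomial probability
#' `P(X >= k)`, `X ~ Binomial(n, f)`, evaluated by log-space summation
#' so that extremely small probabilities remain meaningful.
#'
#' @param k number of colocalised peaks.
#' @param n total number of peaks.
#' @param regions target regions (`GRanges`), used with `genome` to
#'   compute `f`; ignored when `f` is supplied directly.
#' @param genome a `Seqinfo` genome index (with `regions`).
#' @param f genome fraction of the target regions, in `(0, 1]`.
#' @return A list: `k`, `n`, `f`, `fold`, `p`, `log10_p`.
#' @export
overrepresentation <- function(k, n, regions = NULL, genome = NULL,
                               f = NULL) {
  if (k < 0 || n < 0 || k > n) stop("need 0 <= k <= n")
  if (is.null(f)) {
    if (is.null(regions) || is.null(genome)) {
      stop("supply either 'f' or both 'regions' and 'genome'")
    }
    if (length(regions) == 0L) stop("empty region set")
    f <- genome_fraction_covered(regions, genome)
  }
  if (f <= 0) stop("degenerate input: regions cover none of the genome")
  log_terms <- stats::dbinom(k:n, n, f, log = TRUE)
  log_p <- .logsumexp(log_terms)
  list(k = k, n = n, f = f, fold = (k / n) / f,
       p = exp(log_p), log10_p = log_p / log(10))
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Mutual-exclusivity quadrant statistic for two signals
#'
#' Computes 2-kb window means of both tracks at each locus, splits loci
#' into four quadrants by per-track thresholds (their 75th percentiles
#' over the loci by default) and summarises co-occurrence by the odds
#' ratio `(n_both * n_neither) / (n_A_only * n_B_only)`, with the
#' Haldane-Anscombe +0.5 correction when any cell is empty. Mutually
#' exclusive signals give OR well below 1; independent signals give OR
#' near 1.
#'
#' @param track_a,track_b normalized/subtracted `coverage_track`s.
#' @param chrom,pos locus chromosomes and 1-based positions (>= 4 loci).
#' @param t_a,t_b quadrant thresholds; `NULL` for the per-track 75th
#'   percentile over the loci.
#' @param width window width in bp (default 2000).
#' @return A list: `thresholds`, the four counts, `odds_ratio`,
#'   `corrected` (whether +0.5 was applied), and the per-locus `mean_a`,
#'   `mean_b`.
#' @export
mutual_exclusivity <- function(track_a, track_b, chrom, pos, t_a = NULL,
                               t_b = NULL, width = 2000) {
  if (length(pos) < 4L) stop("need at least 4 loci")
  ma <- window_means(track_a, chrom, pos, width)
  mb <- window_means(track_b, chrom, pos, width)
  if (is.null(t_a)) t_a <- stats::quantile(ma, 0.75, names = FALSE)
  if (is.null(t_b)) t_b <- stats::quantile(mb, 0.75, names = FALSE)
  hi_a <- ma > t_a
  hi_b <- mb > t_b
  n_both <- sum(hi_a & hi_b)
  n_a_only <- sum(hi_a & !hi_b)
  n_b_only <- sum(!hi_a & hi_b)
  n_neither <- sum(!hi_a & !hi_b)
  cells <- c(n_both, n_a_only, n_b_only, n_neither)
  corrected <- any(cells == 0L)
  cc <- if (corrected) cells + 0.5 else cells
  list(thresholds = c(a = t_a, b = t_b),
       n_both = n_both, n_a_only = n_a_only, n_b_only = n_b_only,
       n_neither = n_neither,
       odds_ratio = (cc[1] * cc[4]) / (cc[2] * cc[3]),
       corrected = corrected, mean_a = ma, mean_b = mb)
}

#' Odds ratio and exact test for a 2x2 contingency table
#'
#' The sample odds ratio `ad/bc` (Haldane +0.5 correction on all cells
#' when any cell is zero) together with the two-sided exact conditional
#' (hypergeometric) probability from Fisher's test.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return A list: `odds_ratio`, `p`, `corrected`.
#' @export
contingency_odds_ratio <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cells must be non-negative integers")
  }
  if (all(tab == 0)) stop("all-zero table")
  corrected <- any(tab == 0)
  ct <- if (corrected) tab + 0.5 else tab
  list(odds_ratio = (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1]),
       p = stats::fisher.test(tab)$p.value,
       corrected = corrected)
}

#' Allocate complex-representative peaks to genomic categories
#'
#' Each representative peak (or colocalisation component interval) is
#' assigned the first matching category: `CGI_TSS` (within 1 kb of a
#' CGI-associated TSS), `nonCGI_TSS` (within 1 kb of any other TSS),
#' `enhancer` (within 1 kb of an enhancer call), `other`. Proportions
#' come with Poisson standard errors `sqrt(count)/total`, reflecting
#' counting noise in the number of peaks (a binomial SE is available via
#' `se`).
#'
#' @param representatives named list of `GRanges`, one per complex
#'   representative (e.g. the CFP1-SET1A colocalisation components for
#'   SET1A complexes).
#' @param tss_records data.frame with `chrom`, `pos` and logical
#'   `is_cgi` columns (see [build_tss_records()]).
#' @param enhancers enhancer `GRanges` (may be empty).
#' @param max_gap proximity threshold in bp (default 1000).
#' @param se `"poisson"` (default) or `"binomial"`.
#' @return A data.frame with one row per representative x category:
#'   `representative`, `category`, `count`, `proportion`, `se`.
#' @export
allocate_complexes <- function(representatives, tss_records, enhancers,
                               max_gap = 1000, se = c("poisson", "binomial")) {
  se <- match.arg(se)
  if (length(representatives) == 0L ||
      any(lengths(representatives) == 0L)) {
    stop("every representative set must be non-empty")
  }
  cgi_tss <- tss_records[tss_records$is_cgi, , drop = FALSE]
  non_tss <- tss_records[!tss_records$is_cgi, , drop = FALSE]
  pts <- function(df) GenomicRanges::GRanges(df$chrom,
                                             IRanges::IRanges(df$pos, df$pos))
  lv <- c("CGI_TSS", "nonCGI_TSS", "enhancer", "other")
  out <- lapply(names(representatives), function(nm) {
    g <- representatives[[nm]]
    near_cgi_tss <- .near_any(g, pts(cgi_tss), max_gap)
    near_tss <- .near_any(g, pts(non_tss), max_gap)
    near_enh <- if (length(enhancers)) {
      d <- suppressWarnings(
        GenomicRanges::distanceToNearest(g, enhancers, ignore.strand = TRUE))
      flag <- logical(length(g))
      flag[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance <= max_gap
      flag
    } else logical(length(g))
    cat <- ifelse(near_cgi_tss, "CGI_TSS",
           ifelse(near_tss, "nonCGI_TSS",
           ifelse(near_enh, "enhancer", "other")))
    counts <- table(factor(cat, levels = lv))
    total <- length(g)
    serr <- if (se == "poisson") sqrt(as.integer(counts)) / total else {
      p <- as.integer(counts) / total
      sqrt(p * (1 - p) / total)
    }
    data.frame(representative = nm, category = lv,
               count = as.integer(counts),
               proportion = as.integer(counts) / total,
               se = serr)
  })
  do.call(rbind, out)
}
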
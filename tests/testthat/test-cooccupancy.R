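test_that("colocalisation respects the maximum-gap rule and is symmetric", {
  a <- gr0("chr1", 100, 200)
  b <- gr0("chr1", 900, 1000)
  co <- colocalise(a, b, max_gap = 1000)
  expect_equal(co$n_a_hit, 1L)
  expect_equal(co$pairs$distance, 700L)
  far <- gr0("chr1", 1700, 1800)   # gap 1500
  expect_equal(colocalise(a, far, max_gap = 1000)$n_a_hit, 0L)
  # symmetry of the pair relation
  co_ab <- colocalise(a, b)
  co_ba <- colocalise(b, a)
  expect_equal(co_ab$n_a_hit, co_ba$n_b_hit)
  expect_equal(co_ab$n_b_hit, co_ba$n_a_hit)
})

test_that("colocalisation counts match an exhaustive pairwise oracle", {
  set.seed(61)
  for (trial in 1:50) {
    a <- random_peak_df(60, chrom_len = 2e5)
    b <- random_peak_df(60, chrom_len = 2e5)
    co <- colocalise(df_to_gr(a), df_to_gr(b), max_gap = 1000)
    expect_equal(c(co$n_a_hit, co$n_b_hit), bf_coloc_counts(a, b, 1000))
  }
})

test_that("multi-set components label peaks transitively", {
  a <- gr0("chr1", 1000, 1100)
  venn <- multi_venn(list(A = a, B = a), max_gap = 1000)
  expect_equal(venn$counts, c("A&B" = 1L))

  far <- list(A = gr0("chr1", 1000, 1100), B = gr0("chr1", 50000, 50100))
  venn2 <- multi_venn(far, max_gap = 1000)
  expect_equal(venn2$counts[c("A", "B")], c(A = 1L, B = 1L))

  # chain a1 - b1 - a2 with consecutive gaps <= max_gap merges into one
  chain <- list(A = c(gr0("chr1", 0, 100), gr0("chr1", 2200, 2300)),
                B = gr0("chr1", 1100, 1200))
  venn3 <- multi_venn(chain, max_gap = 1000)
  expect_equal(venn3$counts, c("A&B" = 1L))
  expect_equal(venn3$n_components, 1L)
})

test_that("component labels match a brute-force union-find oracle", {
  set.seed(62)
  for (trial in 1:20) {
    a <- random_peak_df(40, chrom_len = 1e5, chroms = "chr1")
    b <- random_peak_df(40, chrom_len = 1e5, chroms = "chr1")
    venn <- multi_venn(list(A = df_to_gr(a), B = df_to_gr(b)),
                       max_gap = 500)
    bf <- bf_venn_counts(a, b, 500)
    expect_equal(venn$counts[order(names(venn$counts))],
                 bf[order(names(bf))])
  }
})

test_that("high-confidence selection keeps the most enriched tenth", {
  pk <- peak_set(gr("chr1", (1:100) * 1000, (1:100) * 1000 + 100),
                 enrichment = 1:100)
  hc <- high_confidence_regions(list(X = pk), percentile = 10)
  expect_equal(length(hc$kept$X), 10L)
  expect_equal(sort(GenomicRanges::mcols(hc$kept$X)$enrichment), 91:100)

  ties <- peak_set(gr("chr1", (1:20) * 1000, (1:20) * 1000 + 100),
                   enrichment = rep(7, 20))
  hc2 <- high_confidence_regions(list(X = ties), percentile = 10)
  expect_equal(length(hc2$kept$X), 20L)  # ties at the threshold survive
})

test_that("merged high-confidence regions match a per-base oracle", {
  set.seed(63)
  mk <- function() {
    df <- random_peak_df(100, chrom_len = 5e4, chroms = "chr1")
    peak_set(df_to_gr(df), enrichment = runif(100, 0, 50))
  }
  sets <- list(A = mk(), B = mk())
  hc <- high_confidence_regions(sets, percentile = 10)
  kept_df <- do.call(rbind, lapply(hc$kept, function(g) {
    data.frame(start = BiocGenerics::start(g), end = BiocGenerics::end(g))
  }))
  expect_equal(sum(BiocGenerics::width(hc$regions)),
               bf_union_length(kept_df$start, kept_df$end, 5e4))
})

test_that("fold over-representation reproduces printed-count arithmetic", {
  o <- overrepresentation(444, 1673, f = 0.0016)
  expect_equal(o$fold, (444 / 1673) / 0.0016)
  expect_equal(round(o$fold), 166)
  o2 <- overrepresentation(159, 5488, f = 0.0016)
  expect_equal(round(o2$fold, 1), 18.1)
  # k at the expectation gives fold ~ 1
  o3 <- overrepresentation(round(1000 * 0.05), 1000, f = 0.05)
  expect_equal(o3$fold, 1, tolerance = 0.01)
})

test_that("binomial upper tail matches exact enumeration and pbinom", {
  # small-n enumeration with choose()
  p_enum <- function(k, n, f) {
    sum(vapply(k:n, function(i) choose(n, i) * f^i * (1 - f)^(n - i),
               numeric(1)))
  }
  expect_equal(overrepresentation(3, 10, f = 0.1)$p, p_enum(3, 10, 0.1),
               tolerance = 1e-12)
  for (n in c(5, 12, 20)) {
    for (k in c(0, 1, n %/% 2, n)) {
      expect_equal(overrepresentation(k, n, f = 0.23)$p,
                   p_enum(k, n, 0.23), tolerance = 1e-12)
    }
  }
  # log-space sum against the library tail for n = 1000 (far-tail cases
  # where the reference itself underflows to 0 are compared in log space)
  for (k in c(1, 50, 200, 500)) {
    ours <- overrepresentation(k, 1000, f = 0.1)$p
    ref <- pbinom(k - 1, 1000, 0.1, lower.tail = FALSE)
    expect_lt(abs(ours - ref) / ref, 1e-10)
  }
  far <- overrepresentation(999, 1000, f = 0.1)
  ref_log10 <- pbinom(998, 1000, 0.1, lower.tail = FALSE,
                      log.p = TRUE) / log(10)
  expect_equal(far$log10_p, ref_log10, tolerance = 1e-10)
  # fold is invariant to uniform duplication of peaks
  expect_equal(overrepresentation(30, 200, f = 0.01)$fold,
               overrepresentation(90, 600, f = 0.01)$fold)
  expect_error(overrepresentation(5, 3, f = 0.1), "k <= n")
  expect_error(overrepresentation(1, 10, f = 0), "degenerate")
})

test_that("genome fraction feeds the enrichment when regions are given", {
  gi <- genome_index("chr1", 1e6)
  regions <- gr0("chr1", 0, 1600)
  o <- overrepresentation(444, 1673, regions, gi)
  expect_equal(o$f, 0.0016)
  expect_equal(round(o$fold), 166)
})

test_that("mutual exclusivity yields OR below 1 when co-occurrence is absent", {
  set.seed(64)
  n <- 4000
  a <- rep(0, n); b <- rep(0, n)
  loci <- seq(1000, 190000, by = 2000)
  hi_a <- seq_along(loci) %% 2 == 0
  for (i in seq_along(loci)) {
    k <- (loci[i] - 1) %/% 50 + 1
    amp <- 15 + runif(1, 0, 10)  # varied heights avoid threshold ties
    if (hi_a[i]) a[k + (-5:5)] <- amp else b[k + (-5:5)] <- amp
  }
  ta <- one_chrom_track(a, chrom_len = 200000)
  tb <- one_chrom_track(b, chrom_len = 200000)
  me <- mutual_exclusivity(ta, tb, "chr1", loci)
  expect_equal(me$n_both, 0L)
  expect_lt(me$odds_ratio, 1)
  expect_true(me$corrected)
  expect_error(mutual_exclusivity(ta, tb, "chr1", loci[1:3]), "4 loci")
})

test_that("independent signals give an odds ratio near one", {
  set.seed(65)
  nbin <- 420000  # 21-Mb chromosome
  ta <- one_chrom_track(rnorm(nbin), chrom_len = nbin * 50)
  tb <- one_chrom_track(rnorm(nbin), chrom_len = nbin * 50)
  loci <- seq(2000, nbin * 50 - 2000, by = 2000)[1:10000]
  me <- mutual_exclusivity(ta, tb, "chr1", loci)
  expect_gt(me$odds_ratio, 0.8)
  expect_lt(me$odds_ratio, 1.25)
})

test_that("contingency odds ratios match hand arithmetic and enumeration", {
  expect_equal(contingency_odds_ratio(matrix(10, 2, 2))$odds_ratio, 1)
  expect_equal(contingency_odds_ratio(matrix(c(20, 5, 5, 20), 2))$odds_ratio,
               16)
  expect_true(contingency_odds_ratio(matrix(c(5, 0, 3, 4), 2))$corrected)
  expect_error(contingency_odds_ratio(matrix(0, 2, 2)), "all-zero")

  set.seed(66)
  for (trial in 1:20) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (all(tab == 0)) next
    expect_equal(contingency_odds_ratio(tab)$p, bf_fisher_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("complex allocation partitions peaks with Poisson errors", {
  tssrec <- data.frame(chrom = "chr1",
                       pos = c(10000L, 20000L, 30000L, 40000L),
                       is_cgi = c(TRUE, TRUE, FALSE, FALSE))
  enh <- gr("chr1", 100000, 100400)
  reps <- list(X = gr("chr1",
                      c(9990, 10010, 19990, 20010, 9995, 20005, 10005,
                        29990, 100100, 500000),
                      c(9990, 10010, 19990, 20010, 9995, 20005, 10005,
                        29990, 100100, 500000) + 10))
  al <- allocate_complexes(reps, tssrec, enh)
  expect_equal(sum(al$count), 10L)
  expect_equal(sum(al$proportion), 1)
  cgi_row <- al[al$category == "CGI_TSS", ]
  expect_equal(cgi_row$count, 7L)
  expect_equal(cgi_row$se, sqrt(7) / 10)

  # all peaks at enhancers
  al2 <- allocate_complexes(list(Y = gr("chr1", 100090, 100110)),
                            tssrec[0, ], enh)
  expect_equal(al2[al2$category == "enhancer", "proportion"], 1)
  expect_error(allocate_complexes(list(Z = GenomicRanges::GRanges()),
                                  tssrec, enh), "non-empty")
})
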
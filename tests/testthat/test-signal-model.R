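test_that("accessibility scores average the two z-transformed signals", {
  set.seed(71)
  x <- runif(200, 0, 50)
  sc <- accessibility_score(x, x)
  expect_equal(sc, (x - mean(x)) / sd(x))

  y <- runif(200, 0, 5)
  sc2 <- accessibility_score(x, y)
  expect_equal(mean(sc2), 0, tolerance = 1e-12)
  expect_lte(sd(sc2), 1 + 1e-12)

  # two independent standardized signals: sd of the mean ~ sqrt(1/2)
  a <- rnorm(20000); b <- rnorm(20000)
  expect_equal(sd(accessibility_score(a, b)), sqrt(1 / 2), tolerance = 0.02)

  # affine invariance of either input
  expect_equal(accessibility_score(3 * x + 7, y), sc2, tolerance = 1e-12)
  expect_error(accessibility_score(rep(1, 10), y[1:10]), "zero variance")
})

test_that("pearson_r2 matches closed forms and the null", {
  x <- 1:50
  expect_equal(pearson_r2(x, 2 * x + 3), list(r = 1, r2 = 1))
  expect_equal(pearson_r2(x, -x)$r, -1)
  expect_equal(pearson_r2(x, -x)$r2, 1)
  set.seed(72)
  expect_lt(abs(pearson_r2(rnorm(10000), rnorm(10000))$r), 0.05)
  expect_error(pearson_r2(rep(1, 10), rnorm(10)), "constant")
})

test_that("top-accessibility selection keeps the top decile with ties", {
  df <- data.frame(accessibility = 1:100)
  expect_equal(nrow(select_top_accessible(df)), 10L)
  df_ties <- data.frame(accessibility = rep(4, 30))
  expect_equal(nrow(select_top_accessible(df_ties)), 30L)
})

test_that("variance decomposition recovers exact and null relations", {
  set.seed(73)
  n <- 200
  d <- data.frame(SET1A = runif(n, 0, 10), H3K4me3 = runif(n, 0, 10),
                  CpG = runif(n, 0, 10))
  d$CFP1 <- 2 * d$SET1A
  vd <- suppressWarnings(  # a perfect fit is intended here
    variance_decomposition(d, "CFP1", c("CpG", "H3K4me3", "SET1A")))
  expect_equal(vd$joint_r2, 1)
  expect_equal(unname(vd$marginal_r2["SET1A"]), 1)
  expect_equal(vd$coefficients["SET1A", "estimate"], 2)

  d$noise <- rnorm(n)
  null_d <- data.frame(y = rnorm(10000), a = rnorm(10000), b = rnorm(10000),
                       c = rnorm(10000))
  vd0 <- variance_decomposition(null_d, "y", c("a", "b", "c"))
  expect_lt(vd0$joint_r2, 0.01)

  # rank-deficient design is rejected
  d$dup <- d$SET1A
  expect_error(variance_decomposition(d, "CFP1", c("SET1A", "dup")),
               "rank-deficient")
})

test_that("variance decomposition matches the generating model", {
  set.seed(74)
  n <- 5000
  a <- 0.7; b <- -1.2; cc <- 2.0; sigma <- 1.5
  d <- data.frame(f1 = rnorm(n, 0, 2), f2 = rnorm(n, 5, 1),
                  f3 = runif(n, 0, 4))
  d$y <- a * d$f1 + b * d$f2 + cc * d$f3 + rnorm(n, 0, sigma)
  vd <- variance_decomposition(d, "y", c("f1", "f2", "f3"))
  est <- vd$coefficients[c("f1", "f2", "f3"), ]
  expect_true(all(abs(est$estimate - c(a, b, cc)) < 3 * est$se))
  fitted_true <- a * d$f1 + b * d$f2 + cc * d$f3
  r2_analytic <- 1 - var(d$y - fitted_true) / var(d$y)
  expect_equal(vd$joint_r2, r2_analytic, tolerance = 0.03)
  # sequential sums of squares account for all variance
  expect_equal(sum(vd$anova_sequential$frac_var), 1)
})

test_that("OLS agrees with hand-rolled normal equations", {
  set.seed(75)
  n <- 300
  d <- data.frame(f1 = rnorm(n), f2 = runif(n), f3 = rnorm(n, 2))
  d$y <- 1 + 0.5 * d$f1 - 2 * d$f2 + 0.3 * d$f3 + rnorm(n, 0, 0.7)
  vd <- variance_decomposition(d, "y", c("f1", "f2", "f3"))
  X <- cbind(1, as.matrix(d[, c("f1", "f2", "f3")]))
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(vd$coefficients$estimate), as.numeric(beta),
               tolerance = 1e-8)
})

test_that("joint R-squared never drops when a feature is added", {
  set.seed(76)
  n <- 500
  d <- data.frame(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  d$y <- d$f1 + 0.2 * d$f2 + rnorm(n)
  v1 <- variance_decomposition(d, "y", "f1")
  v2 <- variance_decomposition(d, "y", c("f1", "f2"))
  v3 <- variance_decomposition(d, "y", c("f1", "f2", "f3"))
  expect_gte(v2$joint_r2, v1$joint_r2)
  expect_gte(v3$joint_r2, v2$joint_r2)
  expect_gte(v3$joint_r2, max(v3$marginal_r2))
})

test_that("motif scanning matches a position-by-position oracle", {
  set.seed(77)
  s <- paste(sample(c("A", "C", "G", "T"), 100000, replace = TRUE),
             collapse = "")
  seqs <- Biostrings::DNAStringSet(c(chr1 = s))
  cgis <- gr("chr1", c(10000, 50000), c(12000, 55000))

  res <- motif_scan_fraction("ACGG", seqs, cgis)
  chars <- strsplit(s, "")[[1]]
  starts_of <- function(pat) {
    p <- strsplit(pat, "")[[1]]
    idx <- seq_len(length(chars) - length(p) + 1)
    hits <- rep(TRUE, length(idx))
    for (j in seq_along(p)) hits <- hits & chars[idx + j - 1] == p[j]
    idx[hits]
  }
  st <- c(starts_of("ACGG"), starts_of("CCGT"))  # forward + reverse strand
  in_cgi <- (st >= 10000 & st <= 12000) | (st >= 50000 & st <= 55000)
  expect_equal(res$n_matches, length(st))
  expect_equal(res$fraction, mean(in_cgi))

  # palindromic motif counted once per strandless position
  pal <- motif_scan_fraction("ACGT", seqs, cgis)
  expect_equal(pal$n_matches, length(starts_of("ACGT")))

  # companion statistic: genomic CG fraction inside CGIs
  st_cg <- starts_of("CG")
  expect_equal(pal$n_cg, length(st_cg))
  expect_equal(pal$cg_fraction,
               mean((st_cg >= 10000 & st_cg <= 12000) |
                      (st_cg >= 50000 & st_cg <= 55000)))
})

test_that("planted motifs inside CGIs give fraction one; absent motifs error", {
  s <- paste0(strrep("A", 1000), "TTACGTTGA", strrep("A", 1000),
              "TTACGTTGA", strrep("A", 500))
  seqs <- Biostrings::DNAStringSet(c(chr1 = s))
  cgis <- gr("chr1", c(995, 2000), c(1015, 2025))
  res <- motif_scan_fraction("TTACGTTGA", seqs, cgis)
  expect_equal(res$fraction, 1)
  expect_error(motif_scan_fraction("GGGCCCGGGCCC", seqs, cgis), "not found")
})

test_that("locus matrices drop duplicate positions and score accessibility", {
  set.seed(78)
  tr1 <- one_chrom_track(runif(400), chrom_len = 20000)
  tr2 <- one_chrom_track(runif(400), chrom_len = 20000)
  pos <- c(5000L, 9000L, 9000L, 15000L)
  m <- locus_signal_matrix(list(DNase = tr1, ATAC = tr2), "chr1", pos)
  expect_equal(nrow(m), 3L)
  expect_true("accessibility" %in% names(m))
  expect_equal(m$DNase, window_means(tr1, "chr1", unique(pos)))
})
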
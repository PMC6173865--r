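test_that("1x normalization fixes the genome-wide mean at exactly 1", {
  t1 <- one_chrom_track(c(2, 2, 2, 2))
  expect_equal(unlist(normalize_1x(t1)$values, use.names = FALSE),
               c(1, 1, 1, 1))
  t2 <- one_chrom_track(c(0, 4))
  expect_equal(unlist(normalize_1x(t2)$values, use.names = FALSE), c(0, 2))

  set.seed(11)
  t3 <- one_chrom_track(runif(500, 0, 10))
  expect_lt(abs(mean(unlist(normalize_1x(t3)$values)) - 1), 1e-12)

  expect_error(normalize_1x(one_chrom_track(rep(0, 10))), "degenerate")
})

test_that("1x normalization is invariant to global rescaling", {
  set.seed(12)
  v <- runif(300, 0, 5)
  a <- normalize_1x(one_chrom_track(v))
  b <- normalize_1x(one_chrom_track(7.3 * v))
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("input subtraction preserves negatives and checks the grid", {
  chip <- one_chrom_track(c(3, 1, 0, 2))
  inp <- one_chrom_track(c(5, 1, 0, 0))
  d <- subtract_input(chip, inp)
  expect_equal(unlist(d$values, use.names = FALSE), c(-2, 0, 0, 2))
  expect_equal(unlist(subtract_input(chip, chip)$values, use.names = FALSE),
               rep(0, 4))
  zero <- one_chrom_track(rep(0, 4))
  expect_equal(subtract_input(chip, zero)$values, chip$values)
  other_grid <- coverage_track(list(chr1 = rep(0, 2)),
                               genome_index("chr1", 200), 100)
  expect_error(subtract_input(chip, other_grid), "incompatible")
})

test_that("window means average bins with midpoints in the window", {
  const <- one_chrom_track(rep(3.5, 100))
  expect_equal(window_mean(const, "chr1", 2500), 3.5)

  v <- rep(0, 100); v[30] <- 40  # bin 30 midpoint at 1475 (0-based)
  tr <- one_chrom_track(v)
  expect_equal(window_mean(tr, "chr1", 1500, width = 2000), 1.0)

  # truncation: a 2-kb window centred at 500 on a 1-kb chromosome
  short <- one_chrom_track(1:20, chrom_len = 1000)
  expect_equal(window_mean(short, "chr1", 500, width = 2000), mean(1:20))
  expect_error(window_mean(short, "chr1", 5000, width = 2000))
})

test_that("CpG density follows the percent-of-positions convention", {
  seq5 <- paste0(paste(rep("CGAAAAAAAA", 5), collapse = ""))  # 5 CGs, 50 bp
  seqs <- Biostrings::DNAStringSet(c(chr1 = seq5))
  tr <- cpg_density_track(seqs, bin_size = 50)
  expect_equal(tr$values$chr1, 10)

  seqs_a <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 50)))
  expect_equal(cpg_density_track(seqs_a, 50)$values$chr1, 0)

  seqs_cg <- Biostrings::DNAStringSet(c(chr1 = strrep("CG", 25)))
  expect_equal(cpg_density_track(seqs_cg, 50)$values$chr1, 50)
})

test_that("CpG bin counts sum to a brute-force scan of the sequence", {
  set.seed(13)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
             collapse = "")
  tr <- cpg_density_track(Biostrings::DNAStringSet(c(chr1 = s)), 50)
  chars <- strsplit(s, "")[[1]]
  bf <- sum(chars[-5000] == "C" & chars[-1] == "G")
  expect_equal(sum(tr$values$chr1) * 50 / 100, bf)
  expect_true(all(tr$values$chr1 >= 0 & tr$values$chr1 <= 100))
})

test_that("ambiguous bases never contribute CpG counts", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste0("CNGNCG", strrep("A", 44))))
  expect_equal(cpg_density_track(seqs, 50)$values$chr1, 2)  # only one CG
})

test_that("signal matrices have the stated shape and match window means", {
  set.seed(14)
  tr <- one_chrom_track(runif(400), chrom_len = 20000)
  pos <- c(5000L, 9000L, 15000L)
  sm <- build_signal_matrix(tr, "chr1", pos, flank = 3000)
  expect_equal(dim(sm$values), c(3L, 120L))
  expect_false(anyNA(sm$values))
  expect_equal(rowMeans(sm$values),
               window_means(tr, "chr1", pos, width = 6000),
               tolerance = 1e-9)

  const <- one_chrom_track(rep(2, 400), chrom_len = 20000)
  smc <- build_signal_matrix(const, "chr1", pos, flank = 3000)
  expect_true(all(smc$values == 2))

  # truncated window is NA-padded, and NA cells are excluded from means
  sme <- build_signal_matrix(tr, "chr1", 1000L, flank = 3000)
  expect_true(anyNA(sme$values))
  expect_equal(mean(sme$values[1, ], na.rm = TRUE),
               window_mean(tr, "chr1", 1000L, width = 6000))

  expect_error(build_signal_matrix(tr, "chr1", pos, flank = 3025),
               "multiple")
})

test_that("signal matrix rows are ordered by the sort key", {
  tr <- one_chrom_track(rep(1, 400), chrom_len = 20000)
  pos <- c(5000L, 9000L, 15000L)
  sm <- build_signal_matrix(tr, "chr1", pos, flank = 1000,
                            sort_by = c(2, 9, 5))
  expect_equal(sm$pos, c(9000L, 15000L, 5000L))
})

test_that("threshold_log clips below the floor before the log2 transform", {
  expect_equal(threshold_log(0), 0)
  expect_equal(threshold_log(-5), 0)
  expect_equal(threshold_log(7), 3)
  expect_equal(threshold_log(-5, floor = 1), 1)
})

test_that("bedGraph tracks round-trip through write and read", {
  set.seed(15)
  gi <- genome_index(c("chr1", "chr2"), c(1030, 500))
  tr <- coverage_track(list(chr1 = round(runif(21, -2, 10), 4),
                            chr2 = round(runif(10, 0, 3), 4)), gi, 50)
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  tr2 <- read_bedgraph_track(f, gi, 50)
  expect_equal(tr2$values, tr$values, tolerance = 1e-9)
})
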
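test_that("the generator is a pure function of config and seed", {
  cfg <- sim_config()
  s1 <- simulate_genome(cfg, seed = 5)
  s2 <- simulate_genome(cfg, seed = 5)
  expect_identical(as.character(s1$seqs), as.character(s2$seqs))
  expect_identical(s1$genes, s2$genes)
  t1 <- simulate_tracks(s1, seed = 6)
  t2 <- simulate_tracks(s2, seed = 6)
  expect_identical(t1$raw$CFP1$values, t2$raw$CFP1$values)
  e1 <- simulate_expression(s1, seed = 7)
  e2 <- simulate_expression(s2, seed = 7)
  expect_identical(e1$tissues, e2$tissues)
})

test_that("written synthetic files are byte-identical across reruns", {
  cfg <- sim_config()
  d1 <- file.path(tempdir(), "sim-a")
  d2 <- file.path(tempdir(), "sim-b")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_epigenome(cfg, seed = 9, outdir = d1, cell_types = "ERY")
  simulate_epigenome(cfg, seed = 9, outdir = d2, cell_types = "ERY")
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  md1 <- unname(tools::md5sum(file.path(d1, f1)))
  md2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(md1, md2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted CGIs are CpG-dense relative to background", {
  fx <- synthetic_fixture()
  sim <- fx$obj$sim
  cpg <- cpg_density_track(sim$seqs, 50, sim$genome)
  cgi_mid <- floor((BiocGenerics::start(sim$cgis) +
                      BiocGenerics::end(sim$cgis)) / 2)
  inside <- window_means(cpg, as.character(GenomicRanges::seqnames(sim$cgis)),
                         cgi_mid, width = 400)
  genome_mean <- mean(unlist(cpg$values, use.names = FALSE))
  expect_gt(mean(inside) - genome_mean, 5)
  # every island exceeds the 10%-of-positions definition in its core
  expect_gt(min(inside), 10)
})

test_that("CGI promoter labels are recovered exactly from the annotation", {
  fx <- synthetic_fixture()
  sim <- fx$obj$sim
  flag <- classify_cgi_tss(sim$genes$chrom, sim$genes$tss, sim$cgis)
  expect_identical(flag, sim$genes$is_cgi)
})

test_that("expression matrices reproduce the planted gene classes", {
  sim <- simulate_genome(sim_config(), seed = 81)
  ex <- simulate_expression(sim, seed = 82)
  hk <- classify_housekeeping(ex$tissues)
  expect_identical(unname(hk$housekeeping),
                   sim$genes$class == "housekeeping")
  for (cell in c("ERY", "EBV")) {
    ts <- classify_tissue_specific(ex$tissues, rowMeans(ex$cells[[cell]]))
    expect_identical(unname(ts$tissue_specific),
                     sim$genes$class == paste0("ts_", cell))
  }
  # permuting tissue columns changes no label
  perm <- ex$tissues[, sample(ncol(ex$tissues))]
  expect_identical(classify_housekeeping(perm)$housekeeping,
                   hk$housekeeping)
})

test_that("emitted files parse with the package readers", {
  fx <- synthetic_fixture()
  dir <- fx$dir
  genome <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(genome_size(genome), 2e6)
  seqs <- read_genome_fasta(file.path(dir, "genome.fa"))
  expect_equal(unname(Biostrings::width(seqs)),
               unname(as.integer(GenomeInfoDb::seqlengths(genome))))
  ann <- read_gtf_annotation(file.path(dir, "genes.gtf"), genome)
  expect_equal(nrow(ann$tss), nrow(fx$obj$sim$genes))
  expect_equal(sort(ann$tss$pos), sort(fx$obj$sim$genes$tss))
  cgis <- read_bed(file.path(dir, "cgis.bed"), genome)
  expect_equal(length(cgis), length(fx$obj$sim$cgis))
  tr <- read_bedgraph_track(file.path(dir, "tracks", "ERY", "CFP1.bedGraph"),
                            genome, 50)
  expect_equal(tr$values, fx$obj$tracks$ERY$raw$CFP1$values,
               tolerance = 1e-9)
  pk <- read_narrowpeak(file.path(dir, "peaks", "ERY", "SET1A.narrowPeak"),
                        genome)
  expect_equal(length(pk), length(fx$obj$tracks$ERY$peaks$SET1A))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$genes), nrow(fx$obj$sim$genes))
})

test_that("planted enhancers are recovered from the emitted tracks", {
  fx <- synthetic_fixture()
  sim <- fx$obj$sim
  sub <- normalize_subtract_tracks(fx$obj$tracks$ERY$raw)
  tss <- data.frame(chrom = sim$genes$chrom, pos = sim$genes$tss)
  calls <- call_enhancers(sub$ATAC, sub$PolII, tss)
  planted <- sim$enhancers[sim$enhancers$cell == "ERY", ]
  pg <- gr(planted$chrom, planted$center - 150, planted$center + 150)
  co <- colocalise(calls, pg, max_gap = 500)
  precision <- co$n_a_hit / length(calls)
  recall <- co$n_b_hit / nrow(planted)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})

test_that("planted mutual exclusivity shows up as a low odds ratio", {
  fx <- synthetic_fixture()
  sim <- fx$obj$sim
  sub <- normalize_subtract_tracks(fx$obj$tracks$ERY$raw)
  me <- mutual_exclusivity(sub$CFP1, sub$H3K27me3,
                           sim$genes$chrom, sim$genes$tss)
  expect_lt(me$odds_ratio, 0.2)
})

test_that("infeasible layouts are rejected at configuration time", {
  expect_error(sim_config(chrom_length = 5e5), "infeasible")
  expect_error(sim_config(n_hk = 400), "exceed")
})
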
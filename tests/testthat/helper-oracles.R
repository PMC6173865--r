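# Independent brute-force oracles and small fixture builders used across
# the test files. The oracles deliberately avoid the package's own code
# paths (per-base masks, O(n^2) pair scans, exhaustive enumeration).

gr <- function(chrom, start1, end1) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1),
                         seqinfo = GenomeInfoDb::Seqinfo(
                           c("chr1", "chr2", "chr3")))
}

# 0-based half-open interval helper matching on-disk conventions
gr0 <- function(chrom, start0, end0) gr(chrom, start0 + 1L, end0)

one_chrom_track <- function(values, bin_size = 50,
                            chrom_len = length(values) * bin_size) {
  coverage_track(list(chr1 = values),
                 genome_index("chr1", chrom_len), bin_size)
}

# per-base boolean mask union length (single chromosome, 1-based closed)
bf_union_length <- function(start1, end1, chrom_len) {
  mask <- logical(chrom_len)
  for (i in seq_along(start1)) mask[start1[i]:end1[i]] <- TRUE
  sum(mask)
}

# gap between 1-based closed intervals; 0 when overlapping/book-ended
bf_gap <- function(s1, e1, s2, e2) {
  pmax(pmax(s2 - e1, s1 - e2) - 1L, 0L)
}

# O(|A|*|B|) colocalisation hit counts on plain data.frames
bf_coloc_counts <- function(a, b, max_gap) {
  hit_a <- logical(nrow(a))
  hit_b <- logical(nrow(b))
  for (i in seq_len(nrow(a))) {
    same <- b$chrom == a$chrom[i]
    if (!any(same)) next
    g <- bf_gap(a$start[i], a$end[i], b$start[same], b$end[same])
    if (any(g <= max_gap)) hit_a[i] <- TRUE
    hit_b[same] <- hit_b[same] | g <= max_gap
  }
  c(sum(hit_a), sum(hit_b))
}

# brute-force connected-component labels over the union of two peak sets
bf_venn_counts <- function(a, b, max_gap) {
  all_df <- rbind(cbind(a, set = "A"), cbind(b, set = "B"))
  n <- nrow(all_df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (all_df$chrom[i] == all_df$chrom[j] &&
          bf_gap(all_df$start[i], all_df$end[i],
                 all_df$start[j], all_df$end[j]) <= max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- vapply(split(all_df$set, roots), function(s) {
    paste(sort(unique(s)), collapse = "&")
  }, character(1))
  tab <- table(labels)
  stats::setNames(as.integer(tab), names(tab))
}

random_peak_df <- function(n, chrom_len = 1e6, chroms = c("chr1", "chr2"),
                           width_range = c(100, 500)) {
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  s <- sample.int(chrom_len - max(w) - 1L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + w - 1L)
}

df_to_gr <- function(df) gr(df$chrom, df$start, df$end)

# two-sided exact conditional p for a 2x2 table by hypergeometric
# enumeration (sum of all tables with the observed margins whose
# probability does not exceed the observed table's)
bf_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0L, k - n2); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n2, k - x) / choose(m + n2, k)
  }, numeric(1))
  obs <- tab[1, 1] - lo + 1L
  sum(probs[probs <= probs[obs] * (1 + 1e-7)])
}

# session-cached synthetic fixture shared by pipeline-level tests
.fixture_env <- new.env(parent = emptyenv())

synthetic_fixture <- function() {
  if (!exists("fx", envir = .fixture_env)) {
    dir <- file.path(tempdir(), "trxg-fixture")
    obj <- simulate_epigenome(sim_config(), seed = 42, outdir = dir,
                              cell_types = "ERY")
    assign("fx", list(dir = dir, obj = obj), envir = .fixture_env)
  }
  get("fx", envir = .fixture_env)
}

fixture_pipeline_config <- function(outdir) {
  fx <- synthetic_fixture()
  analysis_config(
    genome_fasta = file.path(fx$dir, "genome.fa"),
    chrom_sizes = file.path(fx$dir, "chrom.sizes"),
    gtf = file.path(fx$dir, "genes.gtf"),
    cgis_bed = file.path(fx$dir, "cgis.bed"),
    tracks_dir = file.path(fx$dir, "tracks", "ERY"),
    peaks_dir = file.path(fx$dir, "peaks", "ERY"),
    expr_tissues = file.path(fx$dir, "expr", "tissues.tsv"),
    expr_cell = file.path(fx$dir, "expr", "ERY.tsv"),
    outdir = outdir)
}
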
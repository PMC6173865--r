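#' Configuration for the synthetic epigenome
#'
#' Defines the study conditions emulated by the generator: a 2-Mb genome
#' on two chromosomes carrying planted CpG islands, genes with CGI and
#' non-CGI promoters split into housekeeping / tissue-specific / silent
#' Polycomb-marked / other classes, cell-type-specific enhancers placed
#' well away from TSSs, a 16-tissue RPKM matrix built to satisfy or
#' violate the gene-class rules by construction, and coverage tracks in
#' which the target signal (CFP1) is a planted linear function of CpG
#' density, H3K4me3 and SET1A plus half-normal noise, with H3K27me3
#' bumps confined to silent promoters (planted mutual exclusivity).
#'
#' All amplitudes are in normalized, input-subtracted signal units: the
#' generator back-transforms to raw coverage so that 1x normalization
#' followed by input subtraction recovers the planted signal up to a
#' constant offset. Enhancer ATAC/Pol II amplitudes default to three
#' times the calling thresholds (30 and 15) over background noise with
#' standard deviation 1.
#'
#' @param chrom_length length of each chromosome in bp.
#' @param n_chrom number of chromosomes.
#' @param bin_size track bin width in bp.
#' @param genes_per_chrom genes per chromosome.
#' @param gene_spacing TSS-to-TSS spacing in bp.
#' @param gene_zone_start first TSS anchor on each chromosome.
#' @param n_hk,n_ts_ery,n_ts_ebv,n_silent gene-class counts (the
#'   remainder are class `other`).
#' @param enh_per_cell enhancers per chromosome per cell type.
#' @param enh_spacing,enh_zone_start enhancer anchor layout in bp.
#' @param free_cgis_per_chrom CpG islands without an associated gene.
#' @param free_cgi_spacing,free_cgi_start free-CGI anchor layout in bp.
#' @param tissue_count reference tissues in the expression panel.
#' @param coefficients named vector `c(cpg=, h3k4me3=, set1a=)` of the
#'   planted linear model for the target signal.
#' @param eps_sd scale of the half-normal model noise (per bin).
#' @param noise_sd scale of the half-normal background coverage noise.
#' @param bump_sd,acc_bump_sd,k27_bump_sd Gaussian bump widths (bp) for
#'   TSS marks, accessibility/Pol II signals, and the broad H3K27me3
#'   mark.
#' @param amps named list of amplitude ranges (two-element `c(lo, hi)`)
#'   or fixed scalars per signal; see defaults.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_length = 1e6, n_chrom = 2, bin_size = 50,
                       genes_per_chrom = 150, gene_spacing = 3000,
                       gene_zone_start = 10000,
                       n_hk = 90, n_ts_ery = 30, n_ts_ebv = 30,
                       n_silent = 90,
                       enh_per_cell = 25, enh_spacing = 4000,
                       enh_zone_start = 462000,
                       free_cgis_per_chrom = 20, free_cgi_spacing = 5000,
                       free_cgi_start = 700000,
                       tissue_count = 16,
                       coefficients = c(cpg = 0.05, h3k4me3 = 0.15,
                                        set1a = 0.2),
                       eps_sd = 0.5, noise_sd = 1,
                       bump_sd = 150, acc_bump_sd = 100, k27_bump_sd = 300,
                       amps = list()) {
  default_amps <- list(
    h3k4me3 = c(15, 30), set1a = c(10, 30), set1a_enh = c(5, 15),
    hcf1 = c(10, 30), rbbp5_tss = c(10, 25), rbbp5_enh = c(8, 20),
    menin = c(10, 30), utx = c(8, 20),
    h3k4me1_enh = c(10, 25), h3k4me1_tss = c(2, 5),
    h3k27me3 = c(8, 15),
    atac_tss = c(12, 40), atac_enh = 30,
    dnase_enh = c(15, 35), polII_tss = c(10, 25), polII_enh = 15)
  default_amps[names(amps)] <- amps
  cfg <- list(chrom_length = chrom_length, n_chrom = n_chrom,
              bin_size = bin_size,
              genes_per_chrom = genes_per_chrom,
              gene_spacing = gene_spacing,
              gene_zone_start = gene_zone_start,
              n_hk = n_hk, n_ts_ery = n_ts_ery, n_ts_ebv = n_ts_ebv,
              n_silent = n_silent,
              enh_per_cell = enh_per_cell, enh_spacing = enh_spacing,
              enh_zone_start = enh_zone_start,
              free_cgis_per_chrom = free_cgis_per_chrom,
              free_cgi_spacing = free_cgi_spacing,
              free_cgi_start = free_cgi_start,
              tissue_count = tissue_count,
              coefficients = coefficients,
              eps_sd = eps_sd, noise_sd = noise_sd,
              bump_sd = bump_sd, acc_bump_sd = acc_bump_sd,
              k27_bump_sd = k27_bump_sd,
              amps = default_amps)
  n_genes <- n_chrom * genes_per_chrom
  if (n_hk + n_ts_ery + n_ts_ebv + n_silent > n_genes) {
    stop("gene-class counts exceed the number of genes")
  }
  gene_zone_end <- gene_zone_start + (genes_per_chrom - 1) * gene_spacing
  enh_zone_end <- enh_zone_start + (2 * enh_per_cell - 1) * enh_spacing
  cgi_zone_end <- free_cgi_start + (free_cgis_per_chrom - 1) *
    free_cgi_spacing
  if (gene_zone_end + 3000 > enh_zone_start ||
      enh_zone_end + 2000 > free_cgi_start ||
      cgi_zone_end + 2000 > chrom_length) {
    stop("infeasible placement: zones do not fit the chromosome")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate the genome: sequence, CpG islands and gene annotation
#'
#' Produces a background sequence with roughly 1% CG dinucleotide starts,
#' planted CGIs of 500-1500 bp with at least 16% CG starts (comfortably
#' above the 10%-of-positions definition of a high-CpG island), and
#' genes whose TSSs are either inside a planted CGI (CGI promoters,
#' half of the genes) or more than 1 kb from every CGI. Deterministic
#' given the seed.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return A list of class `synthetic_genome`: `genome` (`Seqinfo`),
#'   `seqs` (`DNAStringSet`), `genes` (data.frame with planted classes),
#'   `cgis` (`GRanges`), `enhancers` (data.frame with `cell` labels),
#'   `free_cgis` (data.frame), `config`, `seed`.
#' @export
simulate_genome <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  genome <- genome_index(chroms, rep(cfg$chrom_length, cfg$n_chrom))

  n_genes <- cfg$n_chrom * cfg$genes_per_chrom
  classes <- sample(c(rep("housekeeping", cfg$n_hk),
                      rep("ts_ERY", cfg$n_ts_ery),
                      rep("ts_EBV", cfg$n_ts_ebv),
                      rep("silent_pcg", cfg$n_silent),
                      rep("other", n_genes - cfg$n_hk - cfg$n_ts_ery -
                            cfg$n_ts_ebv - cfg$n_silent)))
  cgi_flag <- sample(rep_len(c(TRUE, FALSE), n_genes))
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    transcript_id = sprintf("g%03d.t1", seq_len(n_genes)),
    chrom = rep(chroms, each = cfg$genes_per_chrom),
    tss = rep(cfg$gene_zone_start +
                (seq_len(cfg$genes_per_chrom) - 1) * cfg$gene_spacing,
              cfg$n_chrom) + sample(-400:400, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    class = classes, is_cgi = cgi_flag,
    stringsAsFactors = FALSE)
  body_len <- sample(1000:2500, n_genes, replace = TRUE)
  genes$start <- ifelse(genes$strand == "+", genes$tss,
                        genes$tss - body_len + 1L)
  genes$end <- ifelse(genes$strand == "+", genes$tss + body_len - 1L,
                      genes$tss)

  # promoter CGIs (centred on the TSS, small jitter) + gene-free CGIs
  pg <- genes[genes$is_cgi, ]
  p_len <- sample(500:1500, nrow(pg), replace = TRUE)
  p_start <- pg$tss - p_len %/% 2 + sample(-200:200, nrow(pg), replace = TRUE)
  free <- data.frame(
    chrom = rep(chroms, each = cfg$free_cgis_per_chrom),
    center = rep(cfg$free_cgi_start +
                   (seq_len(cfg$free_cgis_per_chrom) - 1) *
                     cfg$free_cgi_spacing, cfg$n_chrom))
  f_len <- sample(500:1500, nrow(free), replace = TRUE)
  cgis <- BiocGenerics::sort(GenomicRanges::GRanges(
    c(pg$chrom, free$chrom),
    IRanges::IRanges(c(p_start, free$center - f_len %/% 2),
                     width = c(p_len, f_len))))

  # enhancer anchors alternate between the two cell types
  n_enh <- 2 * cfg$enh_per_cell
  enh <- data.frame(
    chrom = rep(chroms, each = n_enh),
    center = rep(cfg$enh_zone_start + (seq_len(n_enh) - 1) *
                   cfg$enh_spacing, cfg$n_chrom) +
      sample(-200:200, cfg$n_chrom * n_enh, replace = TRUE),
    cell = rep(rep(c("ERY", "EBV"), cfg$enh_per_cell), cfg$n_chrom),
    stringsAsFactors = FALSE)

  seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    .simulate_chrom_seq(cfg, ch, cgis)
  }, character(1)))
  names(seqs) <- chroms

  structure(list(genome = genome, seqs = seqs, genes = genes, cgis = cgis,
                 enhancers = enh, free_cgis = free, config = cfg,
                 seed = seed),
            class = "synthetic_genome")
}

# one chromosome of sequence: CpG-suppressed background with planted
# CpG-rich island segments
.simulate_chrom_seq <- function(cfg, chrom, cgis) {
  L <- cfg$chrom_length
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, L, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3))
  # thin CG starts from the iid rate (0.2 * 0.2) down to ~1%
  cg <- which(s[-L] == "C" & s[-1] == "G")
  drop <- cg[stats::runif(length(cg)) > 0.01 / 0.04]
  s[drop + 1L] <- "A"
  on_chrom <- cgis[as.character(GenomicRanges::seqnames(cgis)) == chrom]
  for (i in seq_along(on_chrom)) {
    a <- GenomicRanges::start(on_chrom)[i]
    b <- GenomicRanges::end(on_chrom)[i]
    len <- b - a + 1L
    seg <- sample(bases, len, replace = TRUE,
                  prob = c(0.15, 0.35, 0.35, 0.15))
    slots <- seq(1L, len - 1L, by = 2L)
    plant <- sample(slots, min(length(slots), round(0.16 * len)))
    seg[plant] <- "C"
    seg[plant + 1L] <- "G"
    s[a:b] <- seg
  }
  paste(s, collapse = "")
}

# add Gaussian bumps (amplitude at the centre) to per-chromosome bin
# vectors; values is a named list, centres are 1-based positions
.add_bumps <- function(values, bin_size, chrom, center, amp, sd_bp) {
  for (i in seq_along(center)) {
    v <- values[[chrom[i]]]
    c0 <- center[i] - 0.5
    k <- .bins_in_window(c0 - 4 * sd_bp, c0 + 4 * sd_bp, bin_size)
    lo <- max(k$lo, 1L); hi <- min(k$hi, length(v))
    if (hi < lo) next
    mids <- (lo:hi - 1) * bin_size + bin_size / 2
    values[[chrom[i]]][lo:hi] <- v[lo:hi] +
      amp[i] * exp(-((mids - c0)^2) / (2 * sd_bp^2))
  }
  values
}

.zero_track_values <- function(genome, bin_size) {
  nb <- .n_bins(genome, bin_size)
  lapply(nb, function(n) numeric(n))
}

.runif_amp <- function(n, range) {
  if (length(range) == 1L) rep(range, n) else stats::runif(n, range[1],
                                                           range[2])
}

#' Simulate coverage tracks and peak sets for one cell type
#'
#' Builds the thirteen signal tracks (CFP1, SET1A, HCF1, RBBP5, Menin,
#' UTX, H3K4me3, H3K4me1, H3K27me3, ATAC, DNase, PolII, input) as raw
#' coverage: planted clean signal in normalized units, back-transformed
#' with a random library-depth factor plus half-normal background noise,
#' so that [normalize_1x()] + [subtract_input()] recovers the planted
#' signal up to a constant offset. The CFP1 track is the planted linear
#' function of CpG density, H3K4me3 and SET1A plus half-normal model
#' noise; H3K27me3 bumps appear only at silent Polycomb-marked TSSs.
#' Peak files are emitted for the six TrxG subunits with enrichment =
#' planted amplitude and FDR drawn below 0.01.
#'
#' @param sim a `synthetic_genome` from [simulate_genome()].
#' @param seed integer RNG seed.
#' @param cell_type `"ERY"` or `"EBV"`; selects the active
#'   tissue-specific genes and the planted enhancer subset.
#' @return A list of class `synthetic_tracks`: `raw` (named list of raw
#'   `coverage_track`s), `peaks` (named list of peak `GRanges` for the
#'   six subunits), `truth` (planted coefficients, bump tables, active
#'   gene ids, cell enhancers, per-track depth factors and clean means),
#'   `cell_type`, `seed`.
#' @export
simulate_tracks <- function(sim, seed = 1, cell_type = c("ERY", "EBV")) {
  cell_type <- match.arg(cell_type)
  set.seed(seed)
  cfg <- sim$config
  bs <- cfg$bin_size
  genome <- sim$genome
  genes <- sim$genes
  amps <- cfg$amps

  active <- genes[genes$class == "housekeeping" |
                    genes$class == paste0("ts_", cell_type), ]
  hk <- genes[genes$class == "housekeeping", ]
  ts_cell <- genes[genes$class == paste0("ts_", cell_type), ]
  silent <- genes[genes$class == "silent_pcg", ]
  enh <- sim$enhancers[sim$enhancers$cell == cell_type, ]
  free <- sim$free_cgis

  zero <- function() .zero_track_values(genome, bs)
  bump_df <- function(chrom, center, amp) {
    data.frame(chrom = chrom, center = center, amp = amp,
               stringsAsFactors = FALSE)
  }

  # planted bump tables (amplitudes in normalized-subtracted units)
  b_k4 <- bump_df(active$chrom, active$tss,
                  .runif_amp(nrow(active), amps$h3k4me3))
  enh_s1 <- enh[seq_len(min(10L, nrow(enh))), ]
  b_s1 <- rbind(bump_df(active$chrom, active$tss,
                        .runif_amp(nrow(active), amps$set1a)),
                bump_df(enh_s1$chrom, enh_s1$center,
                        .runif_amp(nrow(enh_s1), amps$set1a_enh)))
  b_hcf1 <- bump_df(hk$chrom, hk$tss, .runif_amp(nrow(hk), amps$hcf1))
  b_rbbp5 <- rbind(bump_df(active$chrom, active$tss,
                           .runif_amp(nrow(active), amps$rbbp5_tss)),
                   bump_df(enh$chrom, enh$center,
                           .runif_amp(nrow(enh), amps$rbbp5_enh)))
  menin_hk <- hk[sample(nrow(hk), round(2 / 3 * nrow(hk))), ]
  menin_free <- free[sample(nrow(free), min(10L, nrow(free))), ]
  b_menin <- rbind(bump_df(menin_hk$chrom, menin_hk$tss,
                           .runif_amp(nrow(menin_hk), amps$menin)),
                   bump_df(menin_free$chrom, menin_free$center,
                           .runif_amp(nrow(menin_free), amps$menin)))
  utx_free <- free[sample(nrow(free), min(10L, nrow(free))), ]
  b_utx <- rbind(bump_df(enh$chrom, enh$center,
                         .runif_amp(nrow(enh), amps$utx)),
                 bump_df(ts_cell$chrom, ts_cell$tss,
                         .runif_amp(nrow(ts_cell), amps$utx)),
                 bump_df(utx_free$chrom, utx_free$center,
                         .runif_amp(nrow(utx_free), amps$utx)))
  b_k27 <- bump_df(silent$chrom, silent$tss,
                   .runif_amp(nrow(silent), amps$h3k27me3))
  atac_tss_amp <- .runif_amp(nrow(active), amps$atac_tss)
  b_atac <- rbind(bump_df(active$chrom, active$tss, atac_tss_amp),
                  bump_df(enh$chrom, enh$center,
                          .runif_amp(nrow(enh), amps$atac_enh)))
  b_dnase <- rbind(bump_df(active$chrom, active$tss,
                           atac_tss_amp * stats::runif(nrow(active), 0.6,
                                                       1.0)),
                   bump_df(enh$chrom, enh$center,
                           .runif_amp(nrow(enh), amps$dnase_enh)))
  b_pol <- rbind(bump_df(active$chrom, active$tss,
                         .runif_amp(nrow(active), amps$polII_tss)),
                 bump_df(enh$chrom, enh$center,
                         .runif_amp(nrow(enh), amps$polII_enh)))

  mk_clean <- function(b, sd_bp) {
    .add_bumps(zero(), bs, b$chrom, b$center, b$amp, sd_bp)
  }
  clean <- list(
    SET1A = mk_clean(b_s1, cfg$bump_sd),
    HCF1 = mk_clean(b_hcf1, cfg$bump_sd),
    RBBP5 = mk_clean(b_rbbp5, cfg$bump_sd),
    Menin = mk_clean(b_menin, cfg$bump_sd),
    UTX = mk_clean(b_utx, cfg$bump_sd),
    H3K4me3 = mk_clean(b_k4, cfg$bump_sd),
    H3K27me3 = mk_clean(b_k27, cfg$k27_bump_sd),
    ATAC = mk_clean(b_atac, cfg$acc_bump_sd),
    DNase = mk_clean(b_dnase, cfg$acc_bump_sd),
    PolII = mk_clean(b_pol, cfg$acc_bump_sd))
  k4me1 <- zero()
  k4me1 <- .add_bumps(k4me1, bs, enh$chrom, enh$center - 500L,
                      .runif_amp(nrow(enh), amps$h3k4me1_enh), cfg$bump_sd)
  k4me1 <- .add_bumps(k4me1, bs, enh$chrom, enh$center + 500L,
                      .runif_amp(nrow(enh), amps$h3k4me1_enh), cfg$bump_sd)
  clean$H3K4me1 <- .add_bumps(k4me1, bs, active$chrom, active$tss,
                              .runif_amp(nrow(active), amps$h3k4me1_tss),
                              cfg$bump_sd)

  cpg <- cpg_density_track(sim$seqs, bs, genome)
  co <- cfg$coefficients
  clean$CFP1 <- Map(function(cp, k4, s1) {
    co[["cpg"]] * cp + co[["h3k4me3"]] * k4 + co[["set1a"]] * s1 +
      abs(stats::rnorm(length(cp), 0, cfg$eps_sd))
  }, cpg$values, clean$H3K4me3, clean$SET1A)
  clean$input <- zero()

  # back-transform: raw = depth * (K * clean + 1 + |N(0, noise_sd)|)
  # with K = (1 + mu) / (1 - mean(clean)); then 1x normalization and
  # input subtraction return clean - mean(clean) + noise
  mu <- cfg$noise_sd * sqrt(2 / pi)
  depth <- stats::setNames(stats::runif(length(clean), 0.5, 2),
                           names(clean))
  clean_means <- vapply(clean, function(v) {
    mean(unlist(v, use.names = FALSE))
  }, numeric(1))
  if (any(clean_means >= 0.95)) {
    stop("configuration error: planted signal mass too dense for the genome")
  }
  raw <- Map(function(v, m, d) {
    K <- (1 + mu) / (1 - m)
    vals <- lapply(v, function(x) {
      d * (K * x + 1 + abs(stats::rnorm(length(x), 0, cfg$noise_sd)))
    })
    coverage_track(vals, genome, bs)
  }, clean, clean_means, as.list(depth[names(clean)]))

  # peak sets for the six TrxG subunits; CFP1 peaks sit where the
  # planted linear model puts signal (active TSSs, SET1A+ enhancers,
  # and a sample of gene-free CGIs bound through CpG density alone)
  cfp1_free <- free[sample(nrow(free), min(15L, nrow(free))), ]
  cfp1_centers <- rbind(
    data.frame(chrom = active$chrom, center = active$tss),
    data.frame(chrom = enh_s1$chrom, center = enh_s1$center),
    data.frame(chrom = cfp1_free$chrom, center = cfp1_free$center))
  cfp1_amp <- vapply(seq_len(nrow(cfp1_centers)), function(i) {
    v <- clean$CFP1[[cfp1_centers$chrom[i]]]
    v[min(length(v), (cfp1_centers$center[i] - 1L) %/% bs + 1L)]
  }, numeric(1))
  b_cfp1 <- bump_df(cfp1_centers$chrom, cfp1_centers$center, cfp1_amp)

  mk_peaks <- function(b) {
    gr <- GenomicRanges::GRanges(b$chrom,
                                 IRanges::IRanges(pmax(b$center - 200L, 1L),
                                                  b$center + 200L))
    peak_set(gr, summit = b$center, enrichment = b$amp,
             fdr = stats::runif(nrow(b), 0, 0.01))
  }
  peaks <- list(CFP1 = mk_peaks(b_cfp1), SET1A = mk_peaks(b_s1),
                HCF1 = mk_peaks(b_hcf1), RBBP5 = mk_peaks(b_rbbp5),
                Menin = mk_peaks(b_menin), UTX = mk_peaks(b_utx))

  truth <- list(coefficients = co, eps_sd = cfg$eps_sd,
                bumps = list(CFP1 = b_cfp1, SET1A = b_s1, HCF1 = b_hcf1,
                             RBBP5 = b_rbbp5, Menin = b_menin, UTX = b_utx,
                             H3K4me3 = b_k4, H3K27me3 = b_k27,
                             ATAC = b_atac, DNase = b_dnase, PolII = b_pol),
                active_genes = active$gene_id,
                enhancers = enh, depth = depth, clean_means = clean_means)
  structure(list(raw = raw, peaks = peaks, truth = truth,
                 cell_type = cell_type, seed = seed),
            class = "synthetic_tracks")
}

#' Normalize and input-subtract a set of raw tracks
#'
#' Convenience wrapper applying [normalize_1x()] to every track and
#' subtracting the normalized input track from each signal track.
#'
#' @param raw named list of raw `coverage_track`s including one named
#'   `input`.
#' @param input_name name of the input track.
#' @return Named list of normalized, input-subtracted signal tracks
#'   (the input itself is dropped).
#' @export
normalize_subtract_tracks <- function(raw, input_name = "input") {
  if (!input_name %in% names(raw)) stop("no input track")
  norm <- lapply(raw, normalize_1x)
  inp <- norm[[input_name]]
  sig <- norm[names(norm) != input_name]
  lapply(sig, subtract_input, input = inp)
}

#' Simulate the 16-tissue and cell-type RPKM matrices
#'
#' Expression values are built so that every planted housekeeping gene
#' satisfies all three housekeeping clauses, every planted
#' tissue-specific gene satisfies the candidate and half-maximum clauses
#' in its own cell type only, and every other gene provably violates at
#' least one clause of each rule (silent genes are candidates whose cell
#' expression stays below half-maximum; `other` genes are bimodal across
#' tissues, which breaks the log-variance clause while staying above the
#' 10%-of-maximum low-expression cutoff).
#'
#' @param sim a `synthetic_genome`.
#' @param seed integer RNG seed.
#' @return A list of class `synthetic_expression`: `tissues` (genes x 16
#'   RPKM matrix), `cells` (list of genes x 2 replicate matrices for
#'   `ERY` and `EBV`), `truth` (planted per-gene class / cell labels).
#' @export
simulate_expression <- function(sim, seed = 1) {
  set.seed(seed)
  genes <- sim$genes
  nt <- sim$config$tissue_count
  n <- nrow(genes)
  expr <- matrix(0, n, nt,
                 dimnames = list(genes$gene_id,
                                 sprintf("tissue_%02d", seq_len(nt))))
  cell_e <- matrix(0, n, 2, dimnames = list(genes$gene_id,
                                            c("rep1", "rep2")))
  cell_b <- cell_e

  i_hk <- which(genes$class == "housekeeping")
  if (length(i_hk)) {
    b <- 2^stats::runif(length(i_hk), 1, 5)
    expr[i_hk, ] <- b * 2^stats::runif(length(i_hk) * nt, -0.8, 0.8)
    cell_e[i_hk, ] <- b * 2^stats::runif(length(i_hk) * 2, -0.5, 0.5)
    cell_b[i_hk, ] <- b * 2^stats::runif(length(i_hk) * 2, -0.5, 0.5)
  }
  for (cell in c("ERY", "EBV")) {
    i_ts <- which(genes$class == paste0("ts_", cell))
    if (!length(i_ts)) next
    M <- stats::runif(length(i_ts), 20, 60)
    home <- sample(nt, length(i_ts), replace = TRUE)
    for (j in seq_along(i_ts)) {
      row <- stats::runif(nt, 0.2, 0.09 * M[j])
      row[home[j]] <- M[j]
      expr[i_ts[j], ] <- row
    }
    own <- matrix(stats::runif(length(i_ts) * 2, 0.6, 0.95), ncol = 2) * M
    off <- matrix(stats::runif(length(i_ts) * 2, 0.2, 1), ncol = 2)
    if (cell == "ERY") {
      cell_e[i_ts, ] <- own; cell_b[i_ts, ] <- off
    } else {
      cell_b[i_ts, ] <- own; cell_e[i_ts, ] <- off
    }
  }
  i_sil <- which(genes$class == "silent_pcg")
  if (length(i_sil)) {
    expr[i_sil, ] <- stats::runif(length(i_sil) * nt, 0.01, 0.08)
    mx <- apply(expr[i_sil, , drop = FALSE], 1L, max)
    cell_e[i_sil, ] <- matrix(stats::runif(length(i_sil) * 2, 0.1, 0.4),
                              ncol = 2) * mx
    cell_b[i_sil, ] <- matrix(stats::runif(length(i_sil) * 2, 0.1, 0.4),
                              ncol = 2) * mx
  }
  i_oth <- which(genes$class == "other")
  if (length(i_oth)) {
    M <- stats::runif(length(i_oth), 15, 30)
    for (j in seq_along(i_oth)) {
      vals <- c(stats::runif(nt / 2, 0.85, 1), stats::runif(nt / 2, 0.11,
                                                            0.15)) * M[j]
      expr[i_oth[j], ] <- vals[sample(nt)]
    }
    cell_e[i_oth, ] <- stats::runif(length(i_oth) * 2, 1, 10)
    cell_b[i_oth, ] <- stats::runif(length(i_oth) * 2, 1, 10)
  }
  truth <- data.frame(gene_id = genes$gene_id, class = genes$class,
                      stringsAsFactors = FALSE)
  structure(list(tissues = expr,
                 cells = list(ERY = cell_e, EBV = cell_b),
                 truth = truth),
            class = "synthetic_expression")
}
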
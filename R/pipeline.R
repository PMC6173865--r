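#' Analysis configuration
#'
#' Collects every input path and every numeric constant of the analysis
#' in one declarative object, so that no stage hard-codes a threshold.
#' Defaults are the study's standard values: ATAC > 10 within 1 kb for
#' accessible TSSs, ATAC > 10 with Pol II > 5 beyond 2 kb from TSSs for
#' enhancers, 1-kb CGI and colocalisation distances, 50-bp bins, 2-kb
#' signal windows, top decile for high-confidence peaks and
#' accessibility, and the RPKM rules for gene classes (floor 0.1,
#' log2 SD < 1, ratio < 4, half-maximum, 10%-of-maximum).
#'
#' @param genome_fasta,chrom_sizes,gtf,cgis_bed annotation input paths.
#' @param tracks_dir directory of `<signal>.bedGraph` raw coverage
#'   tracks, one of them named `input.bedGraph`.
#' @param peaks_dir directory of `<subunit>.narrowPeak` peak files.
#' @param expr_tissues,expr_cell RPKM matrix TSV paths (reference panel
#'   and target cell type).
#' @param outdir output directory for the report and stage tables.
#' @param target name of the target signal/peak set (default `"CFP1"`).
#' @param complex_subunits subunit peak sets forming the core complex
#'   whose joint colocalisation is reported.
#' @param model_features explanatory features of the variance
#'   decomposition (`"CpG"` refers to the computed CpG-density track).
#' @param exclusivity_mark repressive mark tested for mutual
#'   exclusivity with the target (default `"H3K27me3"`).
#' @param atac_tss,atac_enh,polII_enh,tss_cgi_dist,coloc_gap,enh_tss_dist,window,bin,flank,top_percentile
#'   numeric thresholds (see Description).
#' @param rpkm_floor,hk_sd,hk_ratio_log2,ts_frac,ts_low_frac gene-class
#'   rule parameters.
#' @param seed integer recorded for provenance (the pipeline itself is
#'   deterministic).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(genome_fasta, chrom_sizes, gtf, cgis_bed,
                            tracks_dir, peaks_dir, expr_tissues,
                            expr_cell, outdir = NULL,
                            target = "CFP1",
                            complex_subunits = c("CFP1", "SET1A", "HCF1",
                                                 "RBBP5"),
                            model_features = c("CpG", "H3K4me3", "SET1A"),
                            exclusivity_mark = "H3K27me3",
                            atac_tss = 10, atac_enh = 10, polII_enh = 5,
                            tss_cgi_dist = 1000, coloc_gap = 1000,
                            enh_tss_dist = 2000, window = 2000, bin = 50,
                            flank = 3000, top_percentile = 10,
                            rpkm_floor = 0.1, hk_sd = 1,
                            hk_ratio_log2 = 2, ts_frac = 0.5,
                            ts_low_frac = 0.1, seed = 1) {
  cfg <- as.list(environment())
  num <- c("atac_tss", "atac_enh", "polII_enh", "tss_cgi_dist",
           "coloc_gap", "enh_tss_dist", "window", "bin", "flank",
           "top_percentile", "rpkm_floor", "hk_sd", "hk_ratio_log2",
           "ts_frac", "ts_low_frac")
  if (any(unlist(cfg[num]) <= 0)) stop("all thresholds must be positive")
  structure(cfg, class = "analysis_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the end-to-end occupancy analysis
#'
#' Executes the full downstream pipeline on the configured inputs:
#' track normalization and input subtraction; CpG-density profiling;
#' gene and TSS classification; accessible-TSS and enhancer calling;
#' peak colocalisation, multi-set co-occupancy and binomial enrichment
#' of target peaks in enhancers; mutual-exclusivity quadrants of the
#' target versus the repressive mark at TSSs; high-confidence TrxG
#' regions and complex allocation; the locus-by-feature signal matrix;
#' and feature correlations plus the linear variance decomposition in
#' the top accessibility decile. Identical inputs and configuration
#' give byte-identical reports.
#'
#' @param config an [analysis_config()].
#' @return A list of class `pipeline_report` with one element per stage
#'   (`tracks`, `cpg`, `gene_classes`, `features`, `cooccupancy`,
#'   `exclusivity`, `trxg`, `locus_matrix`, `signal_model`) plus
#'   `provenance`. When `config$outdir` is set, `report.json` and stage
#'   TSV tables are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cfg <- config

  genome <- .stage("inputs", read_chrom_sizes(cfg$chrom_sizes))
  seqs <- .stage("inputs", read_genome_fasta(cfg$genome_fasta))
  ann <- .stage("inputs", read_gtf_annotation(cfg$gtf, genome))
  cgis <- .stage("inputs", read_bed(cfg$cgis_bed, genome))
  track_files <- sort(list.files(cfg$tracks_dir, "\\.bedGraph$",
                                 full.names = TRUE))
  peak_files <- sort(list.files(cfg$peaks_dir, "\\.narrowPeak$",
                                full.names = TRUE))
  if (length(track_files) == 0L) stop("no bedGraph tracks found")
  if (length(peak_files) == 0L) stop("no peak files found")
  raw <- .stage("inputs", lapply(
    stats::setNames(track_files,
                    sub("\\.bedGraph$", "", basename(track_files))),
    read_bedgraph_track, genome = genome, bin_size = cfg$bin))
  peaks <- .stage("inputs", lapply(
    stats::setNames(peak_files,
                    sub("\\.narrowPeak$", "", basename(peak_files))),
    read_narrowpeak, genome = genome))
  expr <- .stage("inputs", read_rpkm_matrix(cfg$expr_tissues))
  cell_expr <- .stage("inputs", read_rpkm_matrix(cfg$expr_cell))

  # stage 1: 1x normalization and input subtraction
  scale_factors <- vapply(raw, function(t) 1 / mean(.all_bins(t)),
                          numeric(1))
  tracks <- .stage("normalize", normalize_subtract_tracks(raw))
  st_tracks <- list(n_tracks = length(tracks),
                    bin_size = cfg$bin,
                    scale_factors = as.list(scale_factors))

  # stage 2: CpG density
  cpg <- .stage("cpg_density", cpg_density_track(seqs, cfg$bin, genome))
  tracks$CpG <- cpg
  st_cpg <- list(mean_percent = mean(.all_bins(cpg)),
                 cg_fraction_in_cgis = .cg_fraction(seqs, cgis))

  # stage 3: gene classes and TSS records
  st_classes <- .stage("classify", {
    common <- intersect(rownames(expr), rownames(cell_expr))
    gc <- classify_genes(expr[common, , drop = FALSE],
                         rowMeans(cell_expr[common, , drop = FALSE]),
                         rpkm_floor = cfg$rpkm_floor, sd_max = cfg$hk_sd,
                         ratio_log2_max = cfg$hk_ratio_log2,
                         frac_low = cfg$ts_low_frac,
                         frac_high = cfg$ts_frac)
    tssrec <- build_tss_records(ann$tss, cgis, tracks$ATAC, gc,
                                cgi_dist = cfg$tss_cgi_dist,
                                atac_threshold = cfg$atac_tss,
                                atac_dist = cfg$tss_cgi_dist)
    target_peaks <- peaks[[cfg$target]]
    summit_cat <- classify_summit(
      as.character(GenomicRanges::seqnames(target_peaks)),
      GenomicRanges::mcols(target_peaks)$summit,
      tssrec, ann$genes, cgis,
      tss_dist = cfg$tss_cgi_dist, cgi_dist = cfg$tss_cgi_dist)
    tss_pts <- GenomicRanges::GRanges(tssrec$chrom,
                                      IRanges::IRanges(tssrec$pos,
                                                       tssrec$pos))
    has_peak <- .near_any(tss_pts, target_peaks, cfg$tss_cgi_dist)
    bias_tab <- table(factor(has_peak, c(TRUE, FALSE)),
                      factor(tssrec$is_cgi, c(TRUE, FALSE)))
    bias <- contingency_odds_ratio(bias_tab)
    list(gene_classes = gc, tss_records = tssrec,
         summit_categories = as.list(table(summit_cat)),
         class_counts = as.list(table(gc$class)),
         cgi_tss_count = sum(tssrec$is_cgi),
         accessible_tss_count = sum(tssrec$is_accessible),
         cgi_bias = list(odds_ratio = bias$odds_ratio, p = bias$p))
  })

  # stage 4: accessible TSSs and enhancer calls
  st_features <- .stage("features", {
    enh <- call_enhancers(tracks$ATAC, tracks$PolII,
                          st_classes$tss_records,
                          atac_min = cfg$atac_enh,
                          polII_min = cfg$polII_enh,
                          tss_dist = cfg$enh_tss_dist)
    list(enhancers = enh,
         n_enhancers = length(enh),
         enhancer_genome_fraction =
           genome_fraction_covered(enh, genome),
         accessible_tss_count = st_classes$accessible_tss_count)
  })
  enhancers <- st_features$enhancers

  # stage 5: colocalisation, co-occupancy and enrichment
  st_cooc <- .stage("cooccupancy", {
    target_peaks <- peaks[[cfg$target]]
    others <- setdiff(names(peaks), cfg$target)
    pairwise <- lapply(stats::setNames(others, others), function(nm) {
      co <- colocalise(target_peaks, peaks[[nm]], cfg$coloc_gap)
      list(n_target = length(target_peaks), n_other = length(peaks[[nm]]),
           n_target_hit = co$n_a_hit, n_other_hit = co$n_b_hit)
    })
    venn <- multi_venn(peaks[intersect(cfg$complex_subunits,
                                       names(peaks))], cfg$coloc_gap)
    k <- if (length(enhancers)) {
      colocalise(target_peaks, enhancers, cfg$coloc_gap)$n_a_hit
    } else 0L
    ovr <- if (length(enhancers) && k > 0) {
      o <- overrepresentation(k, length(target_peaks), enhancers, genome)
      list(k = o$k, n = o$n, f = o$f, fold = o$fold, p = o$p,
           log10_p = o$log10_p)
    } else list(k = k, n = length(target_peaks), f = NA, fold = NA,
                p = NA, log10_p = NA)
    list(pairwise = pairwise, venn_counts = as.list(venn$counts),
         n_components = venn$n_components, enhancer_overrep = ovr)
  })

  # stage 6: mutual exclusivity at TSSs
  st_excl <- .stage("exclusivity", {
    tssrec <- st_classes$tss_records
    me <- mutual_exclusivity(tracks[[cfg$target]],
                             tracks[[cfg$exclusivity_mark]],
                             tssrec$chrom, tssrec$pos,
                             width = cfg$window)
    me[c("thresholds", "n_both", "n_a_only", "n_b_only", "n_neither",
         "odds_ratio", "corrected")]
  })

  # stage 7: high-confidence TrxG regions and complex allocation
  st_trxg <- .stage("trxg", {
    hc <- high_confidence_regions(peaks, cfg$top_percentile)
    target_peaks <- peaks[[cfg$target]]
    partner <- setdiff(cfg$complex_subunits, cfg$target)[1]
    co <- colocalise(target_peaks, peaks[[partner]], cfg$coloc_gap)
    reps <- list(peaks[[cfg$target]][unique(co$pairs$a_idx)])
    names(reps) <- paste0(cfg$target, "_", partner)
    for (nm in setdiff(names(peaks), cfg$complex_subunits)) {
      reps[[nm]] <- peaks[[nm]]
    }
    alloc <- allocate_complexes(reps, st_classes$tss_records, enhancers,
                                max_gap = cfg$coloc_gap)
    list(n_high_confidence_regions = length(hc$regions),
         thresholds = as.list(hc$thresholds), allocation = alloc)
  })

  # stage 8: locus-by-feature signal matrix
  st_matrix <- .stage("locus_matrix", {
    tssrec <- st_classes$tss_records
    loci_chrom <- c(tssrec$chrom,
                    as.character(GenomicRanges::seqnames(enhancers)))
    loci_pos <- c(tssrec$pos, GenomicRanges::mcols(enhancers)$midpoint)
    loci_type <- c(rep("TSS", nrow(tssrec)),
                   rep("enhancer", length(enhancers)))
    locus_signal_matrix(tracks, loci_chrom, loci_pos,
                        locus_type = loci_type, width = cfg$window)
  })

  # stage 9: correlations and variance decomposition
  st_model <- .stage("signal_model", {
    feats <- setdiff(names(tracks), cfg$target)
    cors <- lapply(stats::setNames(feats, feats), function(f) {
      pearson_r2(st_matrix[[f]], st_matrix[[cfg$target]])
    })
    top <- select_top_accessible(st_matrix, cfg$top_percentile)
    vd <- variance_decomposition(top, cfg$target, cfg$model_features)
    list(n_loci = nrow(st_matrix), n_top = nrow(top),
         correlations = cors,
         coefficients = cbind(term = rownames(vd$coefficients),
                              vd$coefficients),
         marginal_r2 = as.list(vd$marginal_r2),
         joint_r2 = vd$joint_r2,
         anova_sequential = vd$anova_sequential,
         anova_last = vd$anova_last)
  })

  inputs <- c(cfg$genome_fasta, cfg$chrom_sizes, cfg$gtf, cfg$cgis_bed,
              track_files, peak_files, cfg$expr_tissues, cfg$expr_cell)
  prov_cfg <- cfg[setdiff(names(cfg), "outdir")]
  provenance <- list(
    package_version = as.character(utils::packageVersion("trxgtools")),
    input_md5 = as.list(tools::md5sum(inputs)),
    config = prov_cfg[!vapply(prov_cfg, is.null, logical(1))])

  report <- structure(
    list(tracks = st_tracks, cpg = st_cpg,
         gene_classes = st_classes[c("class_counts", "summit_categories",
                                     "cgi_tss_count",
                                     "accessible_tss_count", "cgi_bias")],
         features = st_features[c("n_enhancers",
                                  "enhancer_genome_fraction",
                                  "accessible_tss_count")],
         cooccupancy = st_cooc, exclusivity = st_excl,
         trxg = st_trxg[c("n_high_confidence_regions", "thresholds",
                          "allocation")],
         locus_matrix = list(n_loci = nrow(st_matrix),
                             features = setdiff(names(st_matrix),
                                                c("locus_id", "chrom",
                                                  "pos", "locus_type"))),
         signal_model = st_model,
         provenance = provenance),
    class = "pipeline_report")

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    o <- function(...) file.path(cfg$outdir, ...)
    gc_tab <- st_classes$gene_classes
    utils::write.table(cbind(gene_id = rownames(gc_tab), gc_tab),
                       o("gene_classes.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(st_classes$tss_records, o("tss_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_enhancers(enhancers, o("enhancers.bed"), o("enhancers.tsv"))
    utils::write.table(st_matrix, o("locus_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(st_trxg$allocation, o("allocation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, o("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report with stages:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  invisible(x)
}

# fraction of genomic CG dinucleotide starts falling inside regions
.cg_fraction <- function(seqs, regions) {
  tot <- 0L; hit <- 0L
  for (ch in names(seqs)) {
    st <- BiocGenerics::start(Biostrings::matchPattern("CG", seqs[[ch]]))
    if (length(st) == 0L) next
    tot <- tot + length(st)
    pts <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, st))
    hit <- hit + sum(GenomicRanges::countOverlaps(
      pts, regions, ignore.strand = TRUE) > 0)
  }
  if (tot == 0L) return(NA_real_)
  hit / tot
}
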
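#' Write a gene table as GTF
#'
#' Emits `gene` and `transcript` records (1-based inclusive GTF
#' coordinates) with `gene_id`/`transcript_id` attributes.
#'
#' @param genes data.frame with `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand` columns.
#' @param file output path.
#' @export
write_gtf <- function(genes, file) {
  attr_gene <- sprintf('gene_id "%s";', genes$gene_id)
  attr_tx <- sprintf('gene_id "%s"; transcript_id "%s";',
                     genes$gene_id, genes$transcript_id)
  rows <- rbind(
    data.frame(chrom = genes$chrom, source = "synthetic", type = "gene",
               start = genes$start, end = genes$end, score = ".",
               strand = genes$strand, frame = ".", attrs = attr_gene),
    data.frame(chrom = genes$chrom, source = "synthetic",
               type = "transcript", start = genes$start, end = genes$end,
               score = ".", strand = genes$strand, frame = ".",
               attrs = attr_tx))
  rows <- rows[order(rows$chrom, rows$start, rows$type), ]
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Generate and write the full synthetic epigenome
#'
#' Runs [simulate_genome()], [simulate_tracks()] (per cell type) and
#' [simulate_expression()] with seeds derived from `seed`, and, when
#' `outdir` is given, writes every output in its standard on-disk
#' format: `genome.fa`, `chrom.sizes`, `genes.gtf`, `cgis.bed`,
#' `tracks/<cell>/<signal>.bedGraph`, `peaks/<cell>/<subunit>.narrowPeak`,
#' `expr/tissues.tsv`, `expr/<cell>.tsv` and `truth.json`. Outputs are a
#' pure function of `(config, seed)`; rerunning with the same arguments
#' reproduces every file byte for byte.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed (track and expression seeds are derived
#'   by small offsets).
#' @param outdir output directory, or `NULL` to skip writing.
#' @param cell_types cell types to simulate tracks for.
#' @return A list of class `synthetic_epigenome`: `sim`, `tracks` (per
#'   cell type), `expression`, `paths` (when written).
#' @export
simulate_epigenome <- function(config = sim_config(), seed = 1,
                               outdir = NULL,
                               cell_types = c("ERY", "EBV")) {
  sim <- simulate_genome(config, seed)
  tracks <- lapply(stats::setNames(seq_along(cell_types), cell_types),
                   function(i) {
                     simulate_tracks(sim, seed + i, cell_types[i])
                   })
  expr <- simulate_expression(sim, seed + 10L)
  paths <- NULL
  if (!is.null(outdir)) {
    paths <- write_synthetic_epigenome(sim, tracks, expr, outdir)
  }
  structure(list(sim = sim, tracks = tracks, expression = expr,
                 paths = paths, seed = seed),
            class = "synthetic_epigenome")
}

#' @rdname simulate_epigenome
#' @param sim a `synthetic_genome`.
#' @param tracks named list of `synthetic_tracks` (one per cell type).
#' @param expr a `synthetic_expression`.
#' @export
write_synthetic_epigenome <- function(sim, tracks, expr, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  Biostrings::writeXStringSet(sim$seqs, p("genome.fa"))
  write_chrom_sizes(sim$genome, p("chrom.sizes"))
  write_gtf(sim$genes, p("genes.gtf"))
  write_bed(sim$cgis, p("cgis.bed"))
  for (cell in names(tracks)) {
    td <- p("tracks", cell); pd <- p("peaks", cell)
    dir.create(td, recursive = TRUE, showWarnings = FALSE)
    dir.create(pd, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tracks[[cell]]$raw)) {
      write_bedgraph(tracks[[cell]]$raw[[nm]],
                     file.path(td, paste0(nm, ".bedGraph")))
    }
    for (nm in names(tracks[[cell]]$peaks)) {
      write_narrowpeak(tracks[[cell]]$peaks[[nm]],
                       file.path(pd, paste0(nm, ".narrowPeak")))
    }
  }
  dir.create(p("expr"), showWarnings = FALSE)
  write_rpkm_matrix(expr$tissues, p("expr", "tissues.tsv"))
  for (cell in names(expr$cells)) {
    write_rpkm_matrix(expr$cells[[cell]],
                      p("expr", paste0(cell, ".tsv")))
  }
  truth <- list(
    genes = sim$genes,
    enhancers = sim$enhancers,
    free_cgis = sim$free_cgis,
    coefficients = as.list(sim$config$coefficients),
    seed = sim$seed,
    cell_types = names(tracks))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(root = outdir, genome = p("genome.fa"),
       chrom_sizes = p("chrom.sizes"), gtf = p("genes.gtf"),
       cgis = p("cgis.bed"), truth = p("truth.json"))
}
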
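# trxgtools

Downstream analysis of chromatin occupancy for CpG-island-centric
studies of Trithorax-group (TrxG) complexes — the kind of study that
asks where a CxxC-domain reader such as CFP1 binds in the genome, how
its occupancy relates to CpG islands (CGIs), active promoters and
enhancers, and which chromatin features quantitatively explain its
ChIP signal.

The package takes the standard products of a ChIP-seq/ATAC-seq/DNase-seq
experiment — binned coverage tracks (bedGraph), peak calls
(narrowPeak), gene annotation (GTF), CGI annotation (BED), a genome
FASTA and RPKM expression matrices (TSV) — and implements the whole
downstream layer:

* **Signal tracks** — scaling every track to 1x genome-wide coverage
  (mean bin value exactly 1), input subtraction with negatives
  preserved, CpG-density tracks in percent-of-positions units (5 CpGs
  in a 50-bp window = 10%), 2-kb locus averaging, and heatmap-style
  signal matrices around TSSs/CGIs.
* **Gene and TSS classes** — housekeeping genes (RPKM ≥ 0.1 in all
  tissues, sd of log2 RPKM < 1, all ratios to the mean < 4),
  tissue-specific genes (candidate if all RPKM ≤ 0.1 or more than half
  of tissues ≤ 10% of the maximum; called when the target cell reaches
  half-maximum), CGI status of TSSs (distance < 1 kb) and the
  six-way summit classification (CGI TSS → CGI genic → CGI intergenic →
  TSS → genic → intergenic).
* **Feature calls** — accessible TSSs (any ATAC bin > 10 within 1 kb)
  and putative enhancers (bins with ATAC > 10 *and* Pol II > 5, more
  than 2 kb from every TSS, merged into regions).
* **Co-occupancy statistics** — peak colocalisation with a 1-kb maximum
  gap, transitive multi-set Venn decomposition, top-decile
  high-confidence regions, binomial genomic-overlap enrichment
  computed in log space
  (fold = (k/n)/f, p = P(X ≥ k), X ~ Bin(n, f)), mutual-exclusivity
  quadrant odds ratios, exact 2×2 contingency tests, and allocation of
  complex-representative peaks to CGI TSS / non-CGI TSS / enhancer /
  other with Poisson standard errors √k/n.
* **Signal model** — a combined chromatin-accessibility score (mean of
  the DNase and ATAC z-scores), per-feature Pearson R², and an OLS
  variance decomposition CFP1 ~ CpG + H3K4me3 + SET1A on loci in the
  top accessibility decile, with marginal and sequential ANOVA
  partitions.
* **Synthetic epigenome** — a seed-deterministic generator that plants
  CGIs, gene classes, enhancers, subunit peak sets and a linear CFP1
  model with known coefficients, so every stage can be validated
  end-to-end with no external data.

## Worked example

Simulate a 2-Mb epigenome with planted ground truth, then run the full
pipeline on the emitted files:

```r
library(trxgtools)

dir <- file.path(tempdir(), "demo")
simulate_epigenome(sim_config(), seed = 7, outdir = dir,
                   cell_types = "ERY")

cfg <- analysis_config(
  genome_fasta = file.path(dir, "genome.fa"),
  chrom_sizes  = file.path(dir, "chrom.sizes"),
  gtf          = file.path(dir, "genes.gtf"),
  cgis_bed     = file.path(dir, "cgis.bed"),
  tracks_dir   = file.path(dir, "tracks", "ERY"),
  peaks_dir    = file.path(dir, "peaks", "ERY"),
  expr_tissues = file.path(dir, "expr", "tissues.tsv"),
  expr_cell    = file.path(dir, "expr", "ERY.tsv"),
  outdir       = file.path(tempdir(), "demo-out"))
rep <- run_pipeline(cfg)

rep$gene_classes$class_counts
#> $housekeeping [1] 90   $other [1] 180   $tissue_specific [1] 30
rep$features$accessible_tss_count   # 120  (the planted active genes)
rep$features$n_enhancers            # 50   (the planted ERY enhancers)
rep$exclusivity$odds_ratio          # 0.0132  (CFP1 vs H3K27me3 at TSSs)
rep$signal_model$coefficients
#>                 term    estimate      se      t
#> (Intercept)           -0.169      0.0234  -7.2
#> CpG                    0.0494     0.0038  12.9
#> H3K4me3                0.1516     0.0150  10.1
#> SET1A                  0.2113     0.0139  15.2
```

The recovered coefficients sit within two standard errors of the
planted values (0.05, 0.15, 0.20): the linear model that generated the
CFP1 track is identified from the normalized, input-subtracted data in
the top accessibility decile. The gene-class counts (90 housekeeping,
30 tissue-specific) and the 120 accessible TSSs and 50 enhancer calls
reproduce the planted truth exactly, and the odds ratio ≪ 1 reflects
the planted mutual exclusivity between the target signal and the
Polycomb mark.

Every quantity in the report is also available as a standalone
function (`normalize_1x()`, `classify_housekeeping()`,
`call_enhancers()`, `multi_venn()`, `overrepresentation()`,
`mutual_exclusivity()`, `variance_decomposition()`, ...); see the
vignette for the methods behind each stage.

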
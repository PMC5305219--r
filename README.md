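# chromakin

An R package for integrating ChIP-seq and RNA-seq time courses of
Activin/NODAL–SMAD2 signalling: it links ligand-induced SMAD2 chromatin
binding to the transcriptional kinetics of its target genes, and to the
chromatin state (Pol II occupancy, histone acetylation, nucleosome
depletion) at the binding sites. It is aimed at regulatory-genomics analysts
who want the whole analysis chain — bespoke differential-expression
filtering, rule-based kinetic classification, consensus peak construction
and footprint quantification, differential Pol II calling, metaprofiles,
acetylation-state stratification and directed motif analysis — as tested,
reusable functions rather than one-off scripts, validated end to end on
synthetic data with planted ground truth.

## The models at the core

* **Differential expression.** Median-of-ratios size factors
  $s_j = \mathrm{median}_i\, k_{ij}/(\prod_j k_{ij})^{1/m}$; a 40th-percentile
  low-expression filter; a Wald test on the difference of log2 normalized
  means with pooled method-of-moments variance and a $t_{n_A+n_B-2}$
  reference; targets at FDR < 0.05 and |log2FC| ≥ 0.7 vs the SB-431542
  baseline, minus low-count (< 30 reads) and untreated-only genes.
* **Kinetics.** Four printed rules over the (1 hr, 8 hr, untreated) log2FC
  triple classify targets as induced sustained, transient induced, delayed
  or repressed (precedence-resolved); "baseline off" = < 30 reads in the
  inhibited state; direct vs indirect via translation-inhibitor fold
  changes. One-phase decay $y = (y_0 - p)e^{-kt} + p$ gives mRNA half-lives
  $\ln 2 / k$.
* **SMAD2 binding.** Peaks (fold enrichment ≥ 3, repeat-filtered) merged
  into consensus loci on ≥ 1 shared nucleotide; counts of +100-bp-shifted
  reads scaled to 40 M mapped reads; each locus assigned to the nearest
  regulated gene within 100 kb of TSS/TTS; the per-gene **SMAD2 footprint**
  is the sum of normalized counts over its associated loci.
* **Pol II.** Normalization factors from high-signal/low-variance 1-kb bins,
  SB-geometric-mean-harmonized across comparisons; sliding-window NB Wald
  tests vs the inhibited state; a gene is Pol II-differential when
  differential bases over the gene ± 2 kb reach an overlap ratio ≥ 0.09 of
  the gene length.
* **Chromatin state.** Strand-aware metaprofiles (Savitzky–Golay smoothed);
  ± 2.5-kb locus acetylation signals clustered and stratified three ways
  (overall low/high, baseline low/high, induced vs not at log2FC ≥ 0.7 in
  both marks); Welch t comparisons of SMAD2 binding between classes.
* **Motifs.** Directed IUPAC scans on both strands with summit-relative
  positions, tri-nucleotide-preserving (Eulerian-walk) shuffle backgrounds,
  and a 100-bp-window chi-square for FOXH1-type elements.
* **Integration.** High-confidence targets = (RNA ∩ Pol II) plus genes in
  one list rescued by a replicate-conserved SMAD2 peak within 100 kb.

See `vignettes/chromakin-methods.Rmd` for assumptions, parameter defaults
and the reasoning behind every open design choice.

## Worked example

A complete synthetic study (four conditions × two replicates, ~5-Mb default
genome; scaled down here) run through every stage:

```r
library(chromakin)

cfg <- sim_config(seed = 42, noise_free = TRUE,
                  chrom_lengths = c(chr1 = 8e5, chr2 = 6e5),
                  n_genes = 400, n_per_category = 8, n_baseline_off = 4,
                  n_de_only = 3, n_polii_only = 3, n_background_loci = 15,
                  n_lowfold_peaks = 5, n_repeat_peaks = 4, n_fragments = 6e4,
                  n_enhancer_bg = 100, n_matched_bg = 100)
bundle <- simulate_study(cfg)
res <- run_all(bundle)

table(res$kinetics$category, res$kinetics$baseline)
#>                     off on
#>   delayed             0  8
#>   induced_sustained   4 11
#>   repressed           0  8
#>   transient_induced   0  8
```

39 regulated genes are recovered and classified; the four genes induced from
a silent baseline (< 30 reads under SB-431542) are flagged `off`. SMAD2
binding is quantified per gene:

```r
head(res$footprints[res$footprints$n_peaks > 0,
     c("gene_id", "n_peaks", "footprint_SB", "footprint_Activin8h",
       "log2fc_Activin8h")], 4)
#>   gene_id n_peaks footprint_SB footprint_Activin8h log2fc_Activin8h
#> 1   g0002       1     16666.67            414673.6         4.636897
#> 2   g0028       1     16666.67            346672.4         4.378494
#> 3   g0030       1     16666.67            455340.9         4.771868
#> 4   g0046       2     26666.67            575342.9         4.431287
```

Footprints are sums of normalized (40 M-scaled) read counts over the
consensus peaks assigned to each gene: near-background under signal
inhibition, strongly induced at 8 hr. Integration recovers the planted truth
exactly in the zero-dispersion limit:

```r
length(res$polii_set); nrow(res$high_confidence)
#> [1] 39
#> [1] 42
setequal(res$high_confidence$gene_id, bundle$truth$high_confidence$gene_id)
#> [1] TRUE
```

(42 = 36 genes on both evidence lists plus 3 RNA-only and 3 Pol II-only
genes rescued by replicate-conserved peaks.) The embedded FOXH1-type motif
is found in 60% of summit sequences, 87-fold enriched over the
tri-nucleotide shuffle background, with 97% of hits within ± 50 bp of the
summit:

```r
subset(res$motifs$enrichment, motif == "FOXH1")
#>   motif                        set   n    fraction     fold
#> 1 FOXH1                     target 144 0.604166667  1.00000
#> 2 FOXH1                   shuffled 144 0.006944444 87.00000
#> 3 FOXH1 enhancer_summits_synthetic 100 0.000000000       NA
#> 4 FOXH1 distance_matched_synthetic 100 0.020000000 30.20833
round(res$motifs$positional$central_fraction, 3)
#> [1] 0.966
```

The same pipeline is available from the command line:

```sh
exec/chromakin simulate --seed 1 --out bundle_dir
exec/chromakin run-all  --seed 1 --out results_dir
```

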
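# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

tiny_config <- function(seed = 7, ...) {
  sim_config(seed = seed, chrom_lengths = c(chr1 = 8e5, chr2 = 6e5),
             n_genes = 400, n_per_category = 8, n_baseline_off = 4,
             n_de_only = 3, n_polii_only = 3, n_background_loci = 15,
             n_lowfold_peaks = 5, n_repeat_peaks = 4, n_fragments = 6e4,
             n_enhancer_bg = 100, n_matched_bg = 100, ...)
}

# noise-free tiny bundle + full pipeline results (most expensive fixture)
nf_run <- function() {
  if (is.null(.fixture_env$nf)) {
    b <- simulate_study(tiny_config(noise_free = TRUE))
    .fixture_env$nf <- list(bundle = b, res = run_all(b))
  }
  .fixture_env$nf
}

# noisy tiny bundle (no pipeline run attached)
noisy_bundle <- function() {
  if (is.null(.fixture_env$noisy)) {
    .fixture_env$noisy <- simulate_study(tiny_config())
  }
  .fixture_env$noisy
}

# hand-built gene models: data.frame + exons attribute, matching the package
# conventions (0-based half-open; tss/tts strand-aware)
mk_genes <- function(df, exons = NULL) {
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df$tts <- ifelse(df$strand == "+", df$end - 1, df$start)
  if (is.null(exons)) {
    exons <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                        start = df$start, end = df$end, strand = df$strand,
                        stringsAsFactors = FALSE)
  }
  df$exon_kb <- vapply(df$gene_id, function(g) {
    e <- exons[exons$gene_id == g, ]
    sum(e$end - e$start) / 1000
  }, numeric(1))
  attr(df, "exons") <- exons
  df
}

mk_peaks <- function(chrom, start, end, summit = NULL, fe = 10,
                     condition = "Activin8h") {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             name = sprintf("p%d", seq_len(n)), score = 0L, strand = ".",
             fold_enrichment = rep_len(fe, n), pvalue = -1, qvalue = 0.01,
             summit = if (is.null(summit)) floor((start + end) / 2) else summit,
             condition = rep_len(condition, n), stringsAsFactors = FALSE)
}

# constant-depth coverage track
mk_const_track <- function(value, len = 1e4, chrom = "chr1",
                           sample_id = "s1", n_fragments = 1000) {
  structure(list(cov = stats::setNames(list(S4Vectors::Rle(value, len)), chrom),
                 chrom_lengths = stats::setNames(len, chrom),
                 n_fragments = n_fragments, sample_id = sample_id),
            class = "cov_track")
}

mk_track_from_values <- function(values, chrom = "chr1", sample_id = "s1") {
  structure(list(cov = stats::setNames(list(S4Vectors::Rle(values)), chrom),
                 chrom_lengths = stats::setNames(length(values), chrom),
                 n_fragments = sum(values) / 200, sample_id = sample_id),
            class = "cov_track")
}
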
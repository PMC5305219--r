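# Differential expression: median-of-ratios normalization, the 40th-percentile
# expression filter, a simplified NB-family Wald test of each stimulated
# condition against the SB-431542 baseline, and the bespoke target filters
# (FDR < 0.05, |log2FC| >= 0.7, < 30 total reads, Untreated-only exclusion).

row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  (rowSums(m^2) - rowSums(m)^2 / n) / (n - 1)
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: for each sample, the median over genes of the
#' ratio of its count to the gene's geometric mean across samples. Genes with
#' a zero count in any sample are excluded from the median.
#'
#' @param counts gene-by-sample count matrix
#' @return named positive numeric vector, one factor per sample
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2L) ck_stop("size factors need >= 2 samples")
  ok <- rowSums(counts == 0) == 0L
  if (!any(ok)) {
    ck_stop("no gene with nonzero counts in every sample",
            class = "chromakin_normalization_error")
  }
  lg <- log(counts[ok, , drop = FALSE])
  gm <- rowMeans(lg)
  apply(exp(sweep(lg, 1, gm)), 2, median)
}

#' Remove lowly expressed genes
#'
#' Drops genes whose mean count across all samples falls below the given
#' percentile (default 40th) of the per-gene-mean distribution. The percentile
#' uses linear interpolation (R quantile type 7); genes exactly at the
#' threshold are retained.
#'
#' @param counts count matrix
#' @param percentile quantile cutoff in `[0, 1)`
#' @return character vector of retained gene ids; the threshold is attached as
#'   `attr(, "threshold")`
#' @export
filter_low_expression <- function(counts, percentile = 0.4) {
  if (nrow(counts) == 0L) ck_stop("empty count matrix")
  mu <- rowMeans(counts)
  thr <- as.numeric(quantile(mu, percentile, type = 7))
  keep <- rownames(counts)[mu >= thr]
  attr(keep, "threshold") <- thr
  keep
}

#' Simplified negative-binomial differential test (one condition vs reference)
#'
#' Wald-type test on the difference of log2 normalized means between two
#' groups. The variance of the statistic is the method-of-moments
#' (within-group) variance of the log2 normalized counts pooled across the two
#' groups, referred to a t distribution with nA + nB - 2 degrees of freedom.
#' This keeps type-I error at the nominal level with two replicates per group,
#' which a per-gene plug-in NB dispersion cannot (see the methods vignette).
#' Genes with zero counts in both groups return (log2fc = 0, p = 1).
#'
#' @param counts raw count matrix
#' @param sample_sheet sample sheet restricted or not to RNA samples
#' @param condition treatment condition to test
#' @param reference baseline condition (default "SB")
#' @param sf size factors for all columns of `counts` (computed if NULL)
#' @param pseudocount added to normalized counts before log2
#' @return data.frame: gene_id, mean_ref, mean_trt (normalized means),
#'   log2fc, pvalue
#' @export
nb_differential <- function(counts, sample_sheet, condition, reference = "SB",
                            sf = NULL, pseudocount = 0.5) {
  ss <- sample_sheet[sample_sheet$assay == "RNA", , drop = FALSE]
  A <- ss$sample_id[ss$condition == reference]
  B <- ss$sample_id[ss$condition == condition]
  if (length(A) < 2L || length(B) < 2L) {
    ck_stop("need >= 2 replicates per group (%s: %d, %s: %d)",
            reference, length(A), condition, length(B))
  }
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(names(sf))) names(sf) <- colnames(counts)
  q <- sweep(counts, 2, sf[colnames(counts)], "/")
  w <- log2_wald(q[, A, drop = FALSE], q[, B, drop = FALSE], pseudocount)
  res <- data.frame(gene_id = rownames(counts),
                    mean_ref = rowMeans(q[, A, drop = FALSE]),
                    mean_trt = rowMeans(q[, B, drop = FALSE]),
                    log2fc = w$log2fc,
                    pvalue = w$pvalue, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' @importFrom stats pt
NULL

#' Full differential-expression stage
#'
#' Applies the low-expression filter, then tests each non-reference condition
#' against SB-431542 and BH-adjusts p-values across retained genes within each
#' comparison.
#'
#' @inheritParams nb_differential
#' @param conditions conditions to test (default all non-reference ones)
#' @param percentile low-expression percentile filter
#' @return wide data.frame, one row per retained gene, with per-condition
#'   mean_, log2fc_, pvalue_ and fdr_ columns
#' @export
run_de <- function(counts, sample_sheet, conditions = NULL, reference = "SB",
                   percentile = 0.4, pseudocount = 0.5) {
  ss <- sample_sheet[sample_sheet$assay == "RNA", , drop = FALSE]
  counts <- counts[, ss$sample_id, drop = FALSE]
  conditions <- conditions %||% setdiff(intersect(ck_conditions, ss$condition),
                                        reference)
  keep <- filter_low_expression(counts, percentile)
  kept <- counts[keep, , drop = FALSE]
  sf <- size_factors(counts)  # factors from the full matrix, per DESeq usage
  out <- data.frame(gene_id = keep, stringsAsFactors = FALSE)
  q <- sweep(kept, 2, sf[colnames(kept)], "/")
  refcols <- ss$sample_id[ss$condition == reference]
  out[[paste0("mean_", reference)]] <- rowMeans(q[, refcols, drop = FALSE])
  for (cond in conditions) {
    r <- nb_differential(kept, ss, cond, reference, sf = sf,
                         pseudocount = pseudocount)
    out[[paste0("mean_", cond)]] <- r$mean_trt
    out[[paste0("log2fc_", cond)]] <- r$log2fc
    out[[paste0("pvalue_", cond)]] <- r$pvalue
    out[[paste0("fdr_", cond)]] <- p.adjust(r$pvalue, "BH")
  }
  attr(out, "reference") <- reference
  attr(out, "conditions") <- conditions
  out
}

#' Select differentially regulated target genes
#'
#' Keeps genes significant (fdr < `fdr` and |log2FC| >= `lfc`) in at least one
#' stimulated-vs-SB comparison, then removes genes with fewer than `min_reads`
#' raw reads in total and genes whose only passing comparison is Untreated.
#' Reason codes (priority: low_total_reads > untreated_only >
#' no_significant_comparison) are recorded for every gene; the three rules are
#' order-independent in the genes they retain.
#'
#' @param de output of [run_de()]
#' @param counts raw count matrix (for the read-sum rule)
#' @param fdr,lfc significance thresholds
#' @param min_reads raw-read floor summed over samples
#' @param min_reads_scope "sum" (default: total over all samples) or
#'   "per_condition" (every condition must individually reach `min_reads`)
#' @param stimulated the comparisons that count as real stimulation
#' @return `de` with passes_filters + reason columns; regulated subset in
#'   `attr(, "regulated")`
#' @export
apply_target_filters <- function(de, counts, fdr = 0.05, lfc = 0.7,
                                 min_reads = 30, min_reads_scope = "sum",
                                 stimulated = c("Activin1h", "Activin8h"),
                                 sample_sheet = NULL) {
  min_reads_scope <- match.arg(min_reads_scope, c("sum", "per_condition"))
  conds <- attr(de, "conditions")
  pass <- sapply(conds, function(cond) {
    de[[paste0("fdr_", cond)]] < fdr & abs(de[[paste0("log2fc_", cond)]]) >= lfc
  })
  colnames(pass) <- conds
  stim_pass <- rowSums(pass[, intersect(conds, stimulated), drop = FALSE]) > 0
  any_pass <- rowSums(pass) > 0
  k <- counts[de$gene_id, , drop = FALSE]
  enough <- if (min_reads_scope == "sum") {
    rowSums(k) >= min_reads
  } else {
    # alternative reading: keep the gene if any single condition reaches the floor
    if (is.null(sample_sheet)) ck_stop("per_condition scope needs a sample sheet")
    ss <- sample_sheet[match(colnames(k), sample_sheet$sample_id), ]
    percond <- sapply(unique(ss$condition), function(cc)
      rowSums(k[, ss$condition == cc, drop = FALSE]))
    apply(percond, 1, max) >= min_reads
  }
  reason <- rep("pass", nrow(de))
  fail <- !(stim_pass & enough)
  reason[fail] <- "no_significant_comparison"
  reason[fail & any_pass & !stim_pass] <- "untreated_only"
  reason[fail & any_pass & !enough] <- "low_total_reads"
  de$passes_filters <- stim_pass & enough
  de$reason <- reason
  attr(de, "regulated") <- de$gene_id[de$passes_filters]
  de
}

#' Fragments per kilobase of exon per million mapped fragments
#'
#' @param counts count matrix
#' @param gene_models gene-model table (uses `exon_kb`)
#' @param totals per-sample library sizes; defaults to column sums
#' @return FPKM matrix over the genes present in both inputs
#' @export
fpkm <- function(counts, gene_models, totals = colSums(counts)) {
  genes <- intersect(rownames(counts), gene_models$gene_id)
  gm <- gene_models[match(genes, gene_models$gene_id), ]
  if (any(gm$exon_kb <= 0)) {
    ck_stop("gene %s has exon_kb <= 0", gm$gene_id[gm$exon_kb <= 0][1L],
            class = "chromakin_validation_error")
  }
  sweep(counts[genes, , drop = FALSE] / gm$exon_kb, 2, totals / 1e6, "/")
}
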
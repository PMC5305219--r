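# Differential Pol II occupancy: DiffReps-style normalization factors from
# high-signal/low-variance bins, SB geometric-mean harmonization across
# comparisons, windowed differential testing vs SB-431542, and gene-level
# calls via the overlap-ratio statistic (>= 0.09).

# Wald test on difference of log2 normalized means; shared with rnaseq_de.
# qA, qB: normalized count matrices (rows = features). Returns l2fc + p.
log2_wald <- function(qA, qB, pseudocount = 0.5) {
  nA <- ncol(qA); nB <- ncol(qB)
  lqA <- log2(qA + pseudocount); lqB <- log2(qB + pseudocount)
  mA <- rowMeans(lqA); mB <- rowMeans(lqB)
  vA <- row_vars(lqA); vB <- row_vars(lqB)
  pooled <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  se <- sqrt(pooled * (1 / nA + 1 / nB))
  diff <- mB - mA
  tt <- ifelse(is.finite(se) & se > 0, diff / se, 0)
  p <- 2 * pt(-abs(tt), df = nA + nB - 2)
  # zero-dispersion limit: identical replicates but distinct group means are
  # infinitely strong evidence; identical everything is none
  exact <- !is.finite(se) | se < 1e-12
  p[exact & abs(diff) > 1e-9] <- 0
  p[exact & abs(diff) <= 1e-9] <- 1
  zero <- rowSums(qA) + rowSums(qB) == 0
  p[zero] <- 1
  list(log2fc = ifelse(zero, 0, diff), pvalue = p)
}

# Window-level NB Wald test: model-based variance (Poisson floor plus pooled
# method-of-moments excess dispersion) with a t reference at nA+nB df. The
# empirical-variance t(nA+nB-2) used for genes has no power over ~1e5 windows
# (its p-value floor exceeds the BH threshold), while a plain normal reference
# is anticonservative under between-replicate overdispersion; this reference
# keeps pre-BH type-I under 5% on Poisson and mildly overdispersed nulls and
# detects a 3-fold block at 30x depth (see the methods vignette).
nb_window_test <- function(qA, qB, pseudocount = 0.5) {
  nA <- ncol(qA); nB <- ncol(qB)
  muA <- rowMeans(qA); muB <- rowMeans(qB)
  vA <- row_vars(qA); vB <- row_vars(qB)
  pooled <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  mu0 <- (nA * muA + nB * muB) / (nA + nB)
  alpha <- pmax((pooled - mu0) / mu0^2, 0)
  alpha[!is.finite(alpha)] <- 0
  VA <- muA / nA + alpha * muA^2 / nA
  VB <- muB / nB + alpha * muB^2 / nB
  lnfc <- log((muB + pseudocount) / (muA + pseudocount))
  vln <- VA / (muA + pseudocount)^2 + VB / (muB + pseudocount)^2
  z <- ifelse(vln > 0, lnfc / sqrt(vln), 0)
  p <- 2 * pt(-abs(z), df = nA + nB)
  p[muA + muB == 0] <- 1
  list(log2fc = lnfc / log(2), pvalue = p)
}

# fragment-equivalent counts of a coverage track in fixed bins, via cumsums
binned_counts <- function(track, bin = 1000, fraglen = 200) {
  parts <- lapply(names(track$cov), function(chr) {
    v <- as.numeric(track$cov[[chr]])
    len <- length(v)
    nb <- len %/% bin
    if (nb == 0L) return(NULL)
    cs <- c(0, cumsum(v))
    idx <- seq(0L, nb * bin, by = bin)
    data.frame(chrom = chr, start = idx[-length(idx)],
               count = diff(cs[idx + 1L]) / fraglen)
  })
  do.call(rbind, parts)
}

#' ChIP normalization factors from high-signal, low-variance bins
#'
#' Total mapped reads are unreliable for ChIP libraries because enrichment
#' efficiency varies; instead, factors are computed from 1-kb bins whose mean
#' depth across samples exceeds the `signal_quantile` (90th) percentile and
#' whose coefficient of variation across samples is below the median CV of
#' that high-signal subset, then median-of-ratios over those bins.
#'
#' @param tracks named list of `cov_track` objects (same IP)
#' @param bin bin width (bp)
#' @param fraglen fragment length used for count conversion
#' @param signal_quantile high-signal quantile threshold
#' @param min_bins minimum selected bins required
#' @return named positive factors (size-factor-like: divide counts by them)
#' @export
normalization_factors <- function(tracks, bin = 1000, fraglen = 200,
                                  signal_quantile = 0.9, min_bins = 10L) {
  if (length(tracks) < 2L) ck_stop("need >= 2 samples")
  m <- binned_matrix(tracks, bin = bin, fraglen = fraglen)
  factors_from_binmat(m, signal_quantile, min_bins)
}

binned_matrix <- function(tracks, bin = 1000, fraglen = 200) {
  bc <- lapply(tracks, binned_counts, bin = bin, fraglen = fraglen)
  m <- do.call(cbind, lapply(bc, `[[`, "count"))
  colnames(m) <- names(tracks)
  m
}

factors_from_binmat <- function(m, signal_quantile = 0.9, min_bins = 10L) {
  mu <- rowMeans(m)
  high <- mu > quantile(mu, signal_quantile, type = 7)
  cv <- apply(m[high, , drop = FALSE], 1, sd) / rowMeans(m[high, , drop = FALSE])
  # <= so the zero-variance limit (all CVs 0) still selects bins
  sel <- m[high, , drop = FALSE][cv <= median(cv), , drop = FALSE]
  if (nrow(sel) < min_bins) {
    ck_stop("only %d high-signal/low-variance bins (need >= %d)",
            nrow(sel), min_bins, class = "chromakin_normalization_error")
  }
  size_factors(sel)
}

#' Harmonize SB-431542 geometric means across comparisons
#'
#' Each comparison's factors are divided by the ratio of its SB geometric mean
#' to the reference (first) comparison's, so the SB geometric mean of every
#' comparison of the same IP is identical while within-comparison ratios are
#' preserved exactly.
#'
#' @param factors_list list of named factor vectors, one per comparison
#' @param sb_samples list (parallel) of the SB sample names in each comparison
#' @return list of adjusted factor vectors
#' @export
harmonize_sb_geomean <- function(factors_list, sb_samples) {
  stopifnot(length(factors_list) == length(sb_samples))
  gm <- mapply(function(f, sb) geomean(f[sb]), factors_list, sb_samples)
  ref <- gm[[1L]]
  mapply(function(f, g) f / (g / ref), factors_list, gm, SIMPLIFY = FALSE)
}

#' Call differential-occupancy windows against SB-431542
#'
#' Sliding 1-kb windows (100-bp step) are counted in every sample, normalized
#' by the supplied factors, tested with the shared log2-mean Wald test, and
#' BH-adjusted across all windows; significant windows of the same direction
#' that overlap are merged into differential regions.
#'
#' @param trt_tracks,sb_tracks named lists of `cov_track` replicates
#' @param factors named normalization factors covering all samples
#' @param window,step window geometry in bp
#' @param q_threshold BH-adjusted significance cutoff
#' @param fraglen fragment length for count conversion
#' @return data.frame chrom, start, end, direction ("up"/"down"), n_windows,
#'   min_q
#' @export
call_differential_windows <- function(trt_tracks, sb_tracks, factors,
                                      window = 1000, step = 100,
                                      q_threshold = 0.05, fraglen = 200) {
  stopifnot(length(trt_tracks) >= 2L, length(sb_tracks) >= 2L)
  chroms <- names(sb_tracks[[1L]]$cov)
  win_tab <- list(); qA_parts <- list(); qB_parts <- list()
  for (chr in chroms) {
    len <- sb_tracks[[1L]]$chrom_lengths[[chr]]
    starts <- seq(0, len - window, by = step)
    cnt <- function(track) {
      cs <- c(0, cumsum(as.numeric(track$cov[[chr]])))
      (cs[starts + window + 1L] - cs[starts + 1L]) / fraglen
    }
    qA_parts[[chr]] <- sapply(sb_tracks, cnt)
    qB_parts[[chr]] <- sapply(trt_tracks, cnt)
    win_tab[[chr]] <- data.frame(chrom = chr, start = starts,
                                 end = starts + window)
  }
  wins <- do.call(rbind, win_tab)
  qA <- do.call(rbind, qA_parts); qB <- do.call(rbind, qB_parts)
  qA <- sweep(qA, 2, factors[names(sb_tracks)], "/")
  qB <- sweep(qB, 2, factors[names(trt_tracks)], "/")
  res <- nb_window_test(qA, qB)
  qval <- p.adjust(res$pvalue, "BH")
  sig <- which(qval < q_threshold)
  if (!length(sig)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), n_windows = integer(),
                      min_q = numeric(), stringsAsFactors = FALSE))
  }
  sw <- wins[sig, , drop = FALSE]
  sw$direction <- ifelse(res$log2fc[sig] > 0, "up", "down")
  sw$q <- qval[sig]
  parts <- lapply(split(sw, paste(sw$chrom, sw$direction)), function(x) {
    ir <- as_ir(x$start, x$end)
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)
    ov <- IRanges::findOverlaps(ir, merged)
    grp <- S4Vectors::subjectHits(ov)
    data.frame(chrom = x$chrom[1L], start = IRanges::start(merged) - 1,
               end = as.numeric(IRanges::end(merged)),
               direction = x$direction[1L],
               n_windows = as.integer(tabulate(grp, length(merged))),
               min_q = as.numeric(tapply(x$q, grp, min)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential bases overlapping a gene, as an overlap ratio
#'
#' The numerator counts differential-region bases overlapping the gene with a
#' 2-kb flank allowance on each side; the denominator is the unflanked gene
#' interval length (so the ratio can exceed 1). A gene passes at ratio >=
#' `threshold` (0.09 published).
#'
#' @param regions differential regions ([call_differential_windows()] output)
#' @param genes gene-model table
#' @param flank flank allowance (bp)
#' @param threshold pass threshold
#' @return data.frame gene_id, diff_bases, overlap_ratio, passes
#' @export
gene_overlap_ratio <- function(regions, genes, flank = 2000, threshold = 0.09) {
  if (any(genes$end <= genes$start)) {
    ck_stop("zero-length gene", class = "chromakin_validation_error")
  }
  out <- data.frame(gene_id = genes$gene_id, diff_bases = 0,
                    stringsAsFactors = FALSE)
  for (chr in unique(genes$chrom)) {
    gi_ <- which(genes$chrom == chr)
    rr <- regions[regions$chrom == chr, , drop = FALSE]
    if (nrow(rr) == 0L) next
    rir <- IRanges::reduce(as_ir(rr$start, rr$end))
    gext <- as_ir(pmax(genes$start[gi_] - flank, 0), genes$end[gi_] + flank)
    ov <- IRanges::findOverlaps(gext, rir)
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(gext[S4Vectors::queryHits(ov)],
                                            rir[S4Vectors::subjectHits(ov)]))
    covered <- tapply(w, S4Vectors::queryHits(ov), sum)
    out$diff_bases[gi_[as.integer(names(covered))]] <- as.numeric(covered)
  }
  out$overlap_ratio <- out$diff_bases / (genes$end - genes$start)
  out$passes <- out$overlap_ratio >= threshold
  out
}

#' Gene-level differential Pol II calls across comparisons
#'
#' A gene is differential when its overlap ratio reaches the threshold in at
#' least one comparison; the per-comparison maximum is reported.
#'
#' @param regions_list named list of region tables, one per comparison
#' @inheritParams gene_overlap_ratio
#' @param exclude gene ids to drop (declarative stand-in for the published
#'   manual microRNA/false-positive filtering)
#' @return data.frame gene_id, per-comparison ratio_ columns, max_ratio,
#'   passes
#' @export
polii_gene_calls <- function(regions_list, genes, flank = 2000,
                             threshold = 0.09, exclude = character()) {
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  ratios <- sapply(names(regions_list), function(nm) {
    gene_overlap_ratio(regions_list[[nm]], genes, flank, threshold)$overlap_ratio
  })
  if (is.null(dim(ratios))) ratios <- matrix(ratios, nrow = nrow(genes))
  colnames(ratios) <- names(regions_list)
  for (nm in names(regions_list)) out[[paste0("ratio_", nm)]] <- ratios[, nm]
  out$max_ratio <- apply(ratios, 1, max)
  out$passes <- out$max_ratio >= threshold & !out$gene_id %in% exclude
  out
}

#' Gene-level Pol II log2 fold change vs SB-431542
#'
#' Factor-adjusted fragment counts over the entire genomic extent of each gene
#' (+/- `flank`), averaged across replicates per condition, log2 vs the SB
#' mean with a pseudocount. Genes with no signal in any sample return NA.
#'
#' @param tracks named list of `cov_track` per sample
#' @param genes gene models
#' @param factors harmonized normalization factors
#' @param sample_sheet sample sheet covering the tracks
#' @param flank bp added on each side (2 kb published)
#' @param fraglen fragment length
#' @param pseudocount for the log2 ratio
#' @return data.frame gene_id + mean_/log2fc_ per condition
#' @export
gene_level_log2fc <- function(tracks, genes, factors, sample_sheet,
                              flank = 2000, fraglen = 200, pseudocount = 0.5) {
  ss <- sample_sheet[match(names(tracks), sample_sheet$sample_id), ]
  regions <- data.frame(chrom = genes$chrom, start = genes$start - flank,
                        end = genes$end + flank)
  counts <- vapply(names(tracks), function(smp) {
    region_sums(tracks[[smp]], regions) / fraglen / factors[[smp]]
  }, numeric(nrow(genes)))
  if (nrow(genes) == 1L) counts <- matrix(counts, nrow = 1,
                                          dimnames = list(NULL, names(tracks)))
  conds <- intersect(ck_conditions, unique(ss$condition))
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  percond <- vapply(conds, function(cc)
    rowMeans(counts[, ss$condition == cc, drop = FALSE]),
    numeric(nrow(genes)))
  if (nrow(genes) == 1L) percond <- matrix(percond, nrow = 1,
                                           dimnames = list(NULL, conds))
  for (cc in conds) out[[paste0("mean_", cc)]] <- percond[, cc]
  empty <- rowSums(counts) == 0
  for (cc in setdiff(conds, "SB")) {
    l2 <- log2((percond[, cc] + pseudocount) / (percond[, "SB"] + pseudocount))
    l2[empty] <- NA_real_
    out[[paste0("log2fc_", cc)]] <- l2
  }
  out
}
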
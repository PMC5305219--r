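# Histone-acetylation state at SMAD2 binding sites: per-locus signal
# quantification (+/- 2.5 kb), hierarchical clustering, the three published
# stratification schemes, and SMAD2-binding comparisons between classes.

#' Summed normalized signal per locus per sample
#'
#' Factor-adjusted read-depth sum over a +/- `window` span around each locus
#' centre (5001 bp at the 2.5-kb default). `factor` is multiplicative (pass
#' the reciprocal of a size-factor-like normalization factor). Windows
#' clipped by chromosome ends are truncated with a warning.
#'
#' @param tracks named list of `cov_track` per sample
#' @param loci data.frame(locus_id, chrom, pos)
#' @param window half-window (bp)
#' @param factors named multiplicative factors per sample (default 1)
#' @return matrix loci x samples
#' @export
locus_signal <- function(tracks, loci, window = 2500, factors = NULL) {
  factors <- factors %||% stats::setNames(rep(1, length(tracks)), names(tracks))
  out <- matrix(0, nrow(loci), length(tracks),
                dimnames = list(loci$locus_id, names(tracks)))
  lens <- tracks[[1L]]$chrom_lengths[loci$chrom]
  if (any(loci$pos - window < 0 | loci$pos + window + 1 > lens)) {
    ck_log("warning", "some locus windows clipped by chromosome ends")
  }
  regions <- data.frame(chrom = loci$chrom, start = loci$pos - window,
                        end = loci$pos + window + 1)
  for (smp in names(tracks)) {
    out[, smp] <- region_sums(tracks[[smp]], regions) * factors[[smp]]
  }
  out
}

#' Hierarchically cluster loci on their signal matrix
#'
#' Agglomerative clustering with euclidean distance and average linkage
#' (configurable), cut into `k` flat clusters; clusters are relabelled by
#' increasing mean signal so labels are stable under input permutation.
#'
#' @param signal loci x samples matrix
#' @param k number of flat clusters
#' @param method linkage method
#' @return list: hclust tree, cluster (named integer, 1 = lowest mean),
#'   means (per-cluster mean signal)
#' @export
hcluster_loci <- function(signal, k = 2L, method = "average") {
  if (nrow(signal) < 2L) {
    cl <- stats::setNames(rep(1L, nrow(signal)), rownames(signal))
    return(list(tree = NULL, cluster = cl, means = mean(signal)))
  }
  tree <- hclust(dist(signal, method = "euclidean"), method = method)
  k <- min(k, nrow(signal))
  raw <- cutree(tree, k = k)
  means <- tapply(rowMeans(signal), raw, mean)
  relabel <- rank(means, ties.method = "first")
  cl <- stats::setNames(as.integer(relabel[as.character(raw)]), rownames(signal))
  list(tree = tree, cluster = cl, means = sort(as.numeric(means)))
}

#' Overall acetylation classes from two clustered marks
#'
#' With each mark cut into low/high clusters, "low" is the intersection of the
#' low clusters of both marks and "high" the intersection of the high
#' clusters; loci disagreeing between marks stay unlabelled.
#'
#' @param k9,k27 outputs of [hcluster_loci()] for H3K9Ac and H3K27Ac
#' @return data.frame locus_id, scheme = "overall", label (low/high/NA)
#' @export
classify_overall <- function(k9, k27) {
  ids <- intersect(names(k9$cluster), names(k27$cluster))
  lab <- rep(NA_character_, length(ids))
  lab[k9$cluster[ids] == 1L & k27$cluster[ids] == 1L] <- "low"
  lab[k9$cluster[ids] == max(k9$cluster) &
        k27$cluster[ids] == max(k27$cluster)] <- "high"
  if (all(is.na(lab))) ck_log("warning", "overall scheme: empty intersection")
  data.frame(locus_id = ids, scheme = "overall", label = lab,
             stringsAsFactors = FALSE)
}

#' Baseline (SB-431542) acetylation classes
#'
#' Per mark, loci are ranked by SB signal; the `n_select` most and least
#' enriched are taken and the cross-mark intersections labelled high_baseline
#' / low_baseline. Rank-based, hence invariant to monotone transforms of the
#' signals. With fewer than `2 * n_select` loci the selection is scaled down
#' proportionally with a warning.
#'
#' @param sb_k9,sb_k27 named SB-sample signal vectors for the two marks
#' @param n_select published selection size (100 per tail)
#' @return data.frame locus_id, scheme = "sb_baseline", label
#' @export
classify_sb_baseline <- function(sb_k9, sb_k27, n_select = 100L) {
  ids <- intersect(names(sb_k9), names(sb_k27))
  n <- length(ids)
  if (n < 2L * n_select) {
    n_select <- max(1L, n %/% 2L)
    ck_log("warning", "fewer than 2*n_select loci; using ", n_select,
           " per tail")
  }
  tails <- function(x) {
    r <- rank(x[ids], ties.method = "first")
    list(low = ids[r <= n_select], high = ids[r > n - n_select])
  }
  t9 <- tails(sb_k9); t27 <- tails(sb_k27)
  lab <- rep(NA_character_, n)
  lab[ids %in% intersect(t9$low, t27$low)] <- "low_baseline"
  lab[ids %in% intersect(t9$high, t27$high)] <- "high_baseline"
  data.frame(locus_id = ids, scheme = "sb_baseline", label = lab,
             stringsAsFactors = FALSE)
}

#' Split low-baseline loci by acetylation induction
#'
#' Among loci lowly acetylated in both marks at baseline, a locus is
#' high_increase when its 8 hr Activin vs SB log2FC reaches `cutoff` (0.7,
#' boundary inclusive) in **both** marks, else no_increase.
#'
#' @param l2fc_k9,l2fc_k27 named 8 hr log2FC vectors
#' @param low_ids the low-baseline locus set
#' @param cutoff published log2FC cutoff
#' @return data.frame locus_id, scheme = "induction_split", label
#' @export
classify_induction_split <- function(l2fc_k9, l2fc_k27, low_ids,
                                     cutoff = 0.7) {
  lab <- ifelse(l2fc_k9[low_ids] >= cutoff & l2fc_k27[low_ids] >= cutoff,
                "high_increase", "no_increase")
  data.frame(locus_id = low_ids, scheme = "induction_split",
             label = unname(lab), stringsAsFactors = FALSE)
}

#' Compare SMAD2 binding between acetylation classes
#'
#' Per class: mean and t-based 95% confidence interval of the normalized SMAD2
#' counts; between the two classes a Welch unpaired t-test, flagged
#' significant at p < 0.01 (the published significance level).
#'
#' @param smad2 named vector of normalized SMAD2 counts per locus
#' @param classes data.frame(locus_id, label) with exactly two non-NA labels
#' @param conf_level CI level
#' @param alpha significance level
#' @return list: per_class data.frame (label, n, mean, ci_lo, ci_hi), pvalue,
#'   significant
#' @export
compare_smad2_by_class <- function(smad2, classes, conf_level = 0.95,
                                   alpha = 0.01) {
  cls <- classes[!is.na(classes$label), , drop = FALSE]
  labs <- sort(unique(cls$label))
  per <- do.call(rbind, lapply(labs, function(l) {
    x <- smad2[cls$locus_id[cls$label == l]]
    n <- length(x)
    if (n < 2L) {
      ck_log("warning", "class '", l, "' has < 2 members")
      return(data.frame(label = l, n = n, mean = if (n) mean(x) else NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    }
    m <- mean(x); half <- qt(1 - (1 - conf_level) / 2, n - 1L) * sd(x) / sqrt(n)
    data.frame(label = l, n = n, mean = m, ci_lo = m - half, ci_hi = m + half)
  }))
  pv <- NA_real_
  if (length(labs) == 2L && all(per$n >= 2L)) {
    pv <- t.test(smad2[cls$locus_id[cls$label == labs[1L]]],
                 smad2[cls$locus_id[cls$label == labs[2L]]])$p.value
  }
  list(per_class = per, pvalue = pv,
       significant = !is.na(pv) && pv < alpha)
}

#' Pearson correlation of two signal vectors on the log2 scale
#'
#' @param x,y equal-length signal (or log2FC) vectors, length >= 3
#' @param log transform with log2(x + pseudocount) first
#' @param pseudocount offset before log2
#' @return Pearson r (NA when either vector has zero variance)
#' @export
correlate_marks <- function(x, y, log = TRUE, pseudocount = 0.5) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (log) { x <- log2(x + pseudocount); y <- log2(y + pseudocount) }
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}
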
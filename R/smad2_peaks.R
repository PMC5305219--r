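# SMAD2 peak processing: fold-enrichment and repeat filtering, consensus peak
# construction across conditions (>= 1 shared nucleotide), annotation,
# depth-normalized quantification (scaled to 40e6 mapped reads), peak-to-gene
# association within 100 kb of a TSS/TTS, and the per-gene SMAD2 footprint.

#' Filter MACS-style peaks
#'
#' Removes peaks with fold enrichment below `min_fold` (< 3.0 published) and
#' peaks overlapping annotated repeats over at least `max_repeat_frac` of
#' their length.
#'
#' @param peaks peak table ([read_peaks()] format)
#' @param repeats repeat annotation (BED-style interval table), or NULL
#' @param min_fold minimum MACS fold enrichment retained
#' @param max_repeat_frac repeat-overlap fraction at which a peak is dropped
#' @return retained peaks with a `repeat_frac` column
#' @export
filter_peaks <- function(peaks, repeats = NULL, min_fold = 3.0,
                         max_repeat_frac = 0.5) {
  peaks$repeat_frac <- 0
  if (!is.null(repeats) && nrow(repeats) > 0L && nrow(peaks) > 0L) {
    for (chr in unique(peaks$chrom)) {
      pi <- which(peaks$chrom == chr)
      rr <- repeats[repeats$chrom == chr, , drop = FALSE]
      if (nrow(rr) == 0L) next
      pr <- as_ir(peaks$start[pi], peaks$end[pi])
      rr_ir <- IRanges::reduce(as_ir(rr$start, rr$end))
      ov <- IRanges::findOverlaps(pr, rr_ir)
      if (length(ov) == 0L) next
      w <- IRanges::width(IRanges::pintersect(
        pr[S4Vectors::queryHits(ov)], rr_ir[S4Vectors::subjectHits(ov)]))
      covered <- tapply(w, S4Vectors::queryHits(ov), sum)
      idx <- as.integer(names(covered))
      peaks$repeat_frac[pi[idx]] <-
        as.numeric(covered) / (peaks$end[pi[idx]] - peaks$start[pi[idx]])
    }
  }
  peaks[peaks$fold_enrichment >= min_fold &
          peaks$repeat_frac < max_repeat_frac, , drop = FALSE]
}

#' Build consensus SMAD2 peaks across conditions
#'
#' Merges peaks (from any condition) that share at least a single nucleotide,
#' taking the transitive closure of pairwise overlap. Touching half-open
#' intervals share no base and are *not* merged. The consensus summit is the
#' arithmetic mean of the member summits, rounded.
#'
#' @param peaks filtered peak table with a `condition` column
#' @return data.frame of consensus peaks (consensus_id, chrom, start, end,
#'   avg_summit, n_members, conditions); member assignments in
#'   `attr(, "members")`
#' @export
build_consensus <- function(peaks) {
  if (nrow(peaks) == 0L) {
    out <- data.frame(consensus_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      avg_summit = numeric(), n_members = integer(),
                      conditions = character(), stringsAsFactors = FALSE)
    attr(out, "members") <- cbind(peaks, consensus_id = character(0))
    return(out)
  }
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  parts <- lapply(unique(peaks$chrom), function(chr) {
    p <- peaks[peaks$chrom == chr, , drop = FALSE]
    ir <- as_ir(p$start, p$end)
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)
    ov <- IRanges::findOverlaps(ir, merged)
    grp <- S4Vectors::subjectHits(ov)  # each peak hits exactly one component
    cons <- data.frame(chrom = chr,
                       start = IRanges::start(merged) - 1,
                       end = as.numeric(IRanges::end(merged)),
                       stringsAsFactors = FALSE)
    cons$avg_summit <- round(as.numeric(tapply(p$summit, grp, mean)))
    cons$n_members <- as.integer(tabulate(grp, nbins = length(merged)))
    cons$conditions <- as.character(tapply(p$condition, grp, function(x)
      paste(sort(unique(x)), collapse = ",")))
    list(cons = cons, members = cbind(p, group = grp, chrom_key = chr))
  })
  cons <- do.call(rbind, lapply(parts, `[[`, "cons"))
  cons$consensus_id <- sprintf("cp_%05d", seq_len(nrow(cons)))
  cons <- cons[, c("consensus_id", "chrom", "start", "end", "avg_summit",
                   "n_members", "conditions")]
  rownames(cons) <- NULL
  members <- do.call(rbind, lapply(parts, `[[`, "members"))
  # components are enumerated in start order per chrom, matching cons row order
  key <- paste(members$chrom_key, members$group)
  members$consensus_id <- cons$consensus_id[match(key, unique(key))]
  members$group <- NULL
  members$chrom_key <- NULL
  rownames(members) <- NULL
  attr(cons, "members") <- members
  cons
}

#' Annotate a consensus peak by its summit location
#'
#' Precedence: TSS (summit within +/- `tss_window` of any TSS) > exonic >
#' intronic > intergenic, with intergenic peaks split into upstream/downstream
#' relative to the nearest gene's orientation.
#'
#' @param consensus consensus peak table
#' @param genes gene-model table (with exons attribute)
#' @param tss_window the published +/- 500 bp TSS window
#' @return character vector of annotations, one per consensus peak
#' @export
annotate_peaks <- function(consensus, genes, tss_window = 500) {
  if (nrow(genes) == 0L) ck_stop("empty gene set",
                                 class = "chromakin_annotation_error")
  exons <- attr(genes, "exons")
  vapply(seq_len(nrow(consensus)), function(i) {
    chr <- consensus$chrom[i]; s <- consensus$avg_summit[i]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0L) return("upstream_intergenic")
    if (any(abs(s - g$tss) <= tss_window)) return("TSS")
    ex <- exons[exons$chrom == chr, , drop = FALSE]
    if (any(s >= ex$start & s < ex$end)) return("exonic")
    if (any(s >= g$start & s < g$end)) return("intronic")
    d <- pmax(g$start - s, s - (g$end - 1), 0)
    ng <- g[which.min(d), ]
    st <- effective_strand(ng$strand, warn = FALSE)
    before <- s < ng$start
    upstream <- (st == "+" && before) || (st == "-" && !before)
    if (upstream) "upstream_intergenic" else "downstream_intergenic"
  }, character(1))
}

#' Depth-normalized read counts over consensus peaks
#'
#' Reads are shifted +100 bp toward their 3' end (half the 200-bp fragment
#' size) and the count of shifted positions inside each consensus interval is
#' scaled so every sample has 40e6 mapped reads.
#'
#' @param reads named list (per sample) of data.frames
#'   (chrom, pos, strand) holding 0-based read 5' positions
#' @param consensus consensus peak table
#' @param totals named vector of total mapped reads per sample
#' @param shift 3'-ward read shift in bp
#' @param scale_to target library size (40e6 published)
#' @return matrix, consensus peaks x samples
#' @export
normalized_peak_counts <- function(reads, consensus, totals, shift = 100,
                                   scale_to = 4e7) {
  if (any(totals <= 0)) ck_stop("total mapped reads must be positive")
  out <- matrix(0, nrow(consensus), length(reads),
                dimnames = list(consensus$consensus_id, names(reads)))
  for (smp in names(reads)) {
    r <- reads[[smp]]
    spos <- r$pos + ifelse(effective_strand(r$strand, warn = FALSE) == "+",
                           shift, -shift)
    for (chr in unique(consensus$chrom)) {
      ci <- which(consensus$chrom == chr)
      p <- sort(spos[r$chrom == chr])
      if (!length(p)) next
      n_in <- findInterval(consensus$end[ci] - 1, p) -
        findInterval(consensus$start[ci] - 1, p)
      out[ci, smp] <- n_in
    }
    out[, smp] <- out[, smp] * scale_to / totals[[smp]]
  }
  out
}

# distance from a summit to a gene: 0 inside the gene body, else the smaller
# of the distances to the TSS and the TTS
summit_gene_distance <- function(summit, gene) {
  if (summit >= gene$start && summit < gene$end) return(0)
  min(abs(summit - gene$tss), abs(summit - gene$tts))
}

#' Associate consensus peaks with regulated genes
#'
#' Each peak is assigned to the regulated gene minimizing the summit distance
#' (0 inside the gene body, else min distance to TSS/TTS); peaks farther than
#' `max_distance` from every regulated gene stay unassigned. Ties go to the
#' lexicographically first gene id (documented, deterministic).
#'
#' @param consensus consensus peaks
#' @param genes gene models restricted to the regulated set
#' @param max_distance the published 100-kb cutoff
#' @return data.frame consensus_id, gene_id (NA if unassigned), distance
#' @export
associate_peaks <- function(consensus, genes, max_distance = 1e5) {
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  res <- data.frame(consensus_id = consensus$consensus_id,
                    gene_id = NA_character_, distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (chr in unique(consensus$chrom)) {
    ci <- which(consensus$chrom == chr)
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0L) next
    s <- consensus$avg_summit[ci]
    inside <- outer(s, g$start, ">=") & outer(s, g$end, "<")
    d <- pmin(abs(outer(s, g$tss, "-")), abs(outer(s, g$tts, "-")))
    d[inside] <- 0
    best <- max.col(-d, ties.method = "first")
    bestd <- d[cbind(seq_along(ci), best)]
    ok <- bestd <= max_distance
    res$gene_id[ci[ok]] <- g$gene_id[best[ok]]
    res$distance[ci[ok]] <- bestd[ok]
  }
  res
}

#' Per-gene SMAD2 footprint
#'
#' The footprint of a gene in a condition is the sum, over all consensus peaks
#' associated with the gene, of the replicate-averaged normalized read counts.
#' Genes with no associated peak get footprint 0 and log2FC NA.
#'
#' @param association output of [associate_peaks()]
#' @param norm_counts matrix from [normalized_peak_counts()]
#' @param sample_sheet sample sheet covering the SMAD2 samples in
#'   `norm_counts`
#' @param gene_ids genes to report (default: all assigned genes)
#' @param pseudocount for the log2 ratio vs SB
#' @return data.frame with per-condition footprint_ and log2fc_ columns
#' @export
smad2_footprint <- function(association, norm_counts, sample_sheet,
                            gene_ids = NULL, pseudocount = 0.5) {
  ss <- sample_sheet[match(colnames(norm_counts), sample_sheet$sample_id), ]
  conds <- intersect(ck_conditions, unique(ss$condition))
  percond <- sapply(conds, function(cc) {
    cols <- which(ss$condition == cc)
    rowMeans(norm_counts[, cols, drop = FALSE])
  })
  if (nrow(norm_counts) == 1L) percond <- matrix(percond, nrow = 1,
                                                 dimnames = list(rownames(norm_counts), conds))
  gene_ids <- gene_ids %||% sort(unique(stats::na.omit(association$gene_id)))
  out <- data.frame(gene_id = as.character(gene_ids),
                    n_peaks = integer(length(gene_ids)),
                    stringsAsFactors = FALSE)
  if (length(gene_ids) == 0L) {
    for (cc in conds) out[[paste0("footprint_", cc)]] <- numeric(0)
    for (cc in setdiff(conds, "SB")) out[[paste0("log2fc_", cc)]] <- numeric(0)
    return(out)
  }
  fp <- matrix(0, length(gene_ids), length(conds),
               dimnames = list(gene_ids, conds))
  assigned <- association[!is.na(association$gene_id) &
                            association$gene_id %in% gene_ids, , drop = FALSE]
  if (nrow(assigned)) {
    agg <- rowsum(percond[assigned$consensus_id, , drop = FALSE],
                  assigned$gene_id)
    fp[rownames(agg), ] <- agg
    tab <- table(assigned$gene_id)
    out$n_peaks <- as.integer(tab[out$gene_id])
    out$n_peaks[is.na(out$n_peaks)] <- 0L
  }
  for (cc in conds) out[[paste0("footprint_", cc)]] <- fp[, cc]
  for (cc in setdiff(conds, "SB")) {
    l2 <- log2((fp[, cc] + pseudocount) / (fp[, "SB"] + pseudocount))
    l2[out$n_peaks == 0L] <- NA_real_
    out[[paste0("log2fc_", cc)]] <- l2
  }
  out
}

#' Peak density over a modeled gene coordinate
#'
#' Summits of associated peaks are mapped to a shared coordinate system in
#' which every gene body runs from 0 to `model_kb` kb (linearly rescaled)
#' while upstream/downstream distances are preserved; minus-strand genes are
#' flipped so coordinates run 5' to 3'. Density is a 1-kb-bin histogram over
#' +/- `window` around the modeled gene.
#'
#' @param consensus consensus peaks
#' @param genes regulated gene models
#' @param association output of [associate_peaks()]
#' @param window flanking window (bp)
#' @param binsize histogram bin (bp)
#' @param model_kb modeled gene-body length (kb)
#' @return data.frame bin_start, bin_mid, count, density
#' @export
peak_density_profile <- function(consensus, genes, association,
                                 window = 1e5, binsize = 1e3, model_kb = 20) {
  body_len <- model_kb * 1000
  m <- match(association$gene_id, genes$gene_id)
  coords <- vapply(seq_len(nrow(association)), function(i) {
    if (is.na(m[i])) return(NA_real_)
    g <- genes[m[i], ]
    s <- consensus$avg_summit[match(association$consensus_id[i],
                                    consensus$consensus_id)]
    st <- effective_strand(g$strand, warn = FALSE)
    if (s >= g$start && s < g$end) {
      frac <- (s - g$start) / (g$end - g$start)
      if (st == "-") frac <- 1 - frac
      return(frac * body_len)
    }
    d5 <- s - g$tss; d3 <- s - g$tts
    if (st == "-") { d5 <- -d5; d3 <- -d3 }
    if (d5 < 0) d5 else body_len + d3
  }, numeric(1))
  coords <- coords[!is.na(coords)]
  breaks <- seq(-window, body_len + window, by = binsize)
  coords <- coords[coords >= -window & coords < body_len + window]
  if (length(coords) == 0L) {
    return(data.frame(bin_start = head(breaks, -1L),
                      bin_mid = head(breaks, -1L) + binsize / 2,
                      count = 0L, density = 0))
  }
  h <- graphics::hist(coords, breaks = breaks, right = FALSE, plot = FALSE)
  data.frame(bin_start = head(breaks, -1L), bin_mid = h$mids,
             count = h$counts, density = h$density)
}
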
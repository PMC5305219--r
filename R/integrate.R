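# High-confidence target definition: intersection of the RNA-seq and Pol II
# differential gene lists, with rescue of single-evidence genes that carry a
# replicate-conserved SMAD2 peak within 100 kb of their TSS/TTS.

# replicate-conserved peak positions: midpoints of >= 1-bp overlaps between
# the replicate-1 and replicate-2 calls of the same condition
conserved_peak_positions <- function(rep_peaks_by_condition) {
  parts <- lapply(rep_peaks_by_condition, function(pair) {
    p1 <- pair[[1L]]; p2 <- pair[[2L]]
    res <- list()
    for (chr in intersect(unique(p1$chrom), unique(p2$chrom))) {
      a <- p1[p1$chrom == chr, , drop = FALSE]
      b <- p2[p2$chrom == chr, , drop = FALSE]
      ov <- IRanges::findOverlaps(as_ir(a$start, a$end), as_ir(b$start, b$end))
      if (!length(ov)) next
      s <- pmax(a$start[S4Vectors::queryHits(ov)],
                b$start[S4Vectors::subjectHits(ov)])
      e <- pmin(a$end[S4Vectors::queryHits(ov)],
                b$end[S4Vectors::subjectHits(ov)])
      res[[chr]] <- data.frame(chrom = chr, pos = round((s + e) / 2))
    }
    do.call(rbind, res)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) data.frame(chrom = character(), pos = numeric()) else out
}

#' Build the high-confidence target gene set
#'
#' Core genes are in both the RNA differential list and the Pol II
#' differential list; genes in exactly one list are rescued when a SMAD2 peak
#' conserved between the two biological replicates (>= 1-bp overlap) lies
#' within `max_distance` of their TSS or TTS (0 inside the gene body).
#'
#' @param de_genes character vector of RNA-differential gene ids
#' @param polii_genes character vector of Pol II-differential gene ids
#' @param genes full gene-model table
#' @param rep_peaks_by_condition named list; each element a list of the two
#'   replicate peak tables of one condition (already filtered)
#' @param max_distance published 100-kb cutoff
#' @return data.frame gene_id, evidence (comma-joined codes)
#' @export
build_high_confidence <- function(de_genes, polii_genes, genes,
                                  rep_peaks_by_condition, max_distance = 1e5) {
  core <- intersect(de_genes, polii_genes)
  single <- union(setdiff(de_genes, polii_genes),
                  setdiff(polii_genes, de_genes))
  cons <- conserved_peak_positions(rep_peaks_by_condition)
  rescued <- character(0)
  if (length(single) && nrow(cons)) {
    gm <- genes[match(single, genes$gene_id), , drop = FALSE]
    near <- vapply(seq_len(nrow(gm)), function(i) {
      p <- cons[cons$chrom == gm$chrom[i], , drop = FALSE]
      if (nrow(p) == 0L) return(FALSE)
      d <- ifelse(p$pos >= gm$start[i] & p$pos < gm$end[i], 0,
                  pmin(abs(p$pos - gm$tss[i]), abs(p$pos - gm$tts[i])))
      any(d <= max_distance)
    }, logical(1))
    rescued <- single[near]
  }
  ids <- sort(union(core, rescued))
  evidence <- vapply(ids, function(g) {
    ev <- c(if (g %in% de_genes) "rna_de",
            if (g %in% polii_genes) "polii_diff",
            if (g %in% rescued) "rescued_by_replicated_peak")
    paste(ev, collapse = ",")
  }, character(1))
  data.frame(gene_id = ids, evidence = unname(evidence),
             stringsAsFactors = FALSE)
}

#' Master per-gene summary of the integrated analysis
#'
#' One row per high-confidence gene: kinetic call, SMAD2 footprint log2FCs,
#' Pol II log2FCs and associated peak annotations; absent values are NA.
#' Rows are ordered by gene_id so reruns are byte-identical.
#'
#' @param hc output of [build_high_confidence()]
#' @param kinetics kinetic-call table (may omit genes)
#' @param footprints SMAD2 footprint table
#' @param polii_lfc gene-level Pol II log2FC table (Ser5P)
#' @param association peak-gene association with annotation column
#' @return data.frame, one row per high-confidence gene
#' @export
summarize_targets <- function(hc, kinetics, footprints, polii_lfc,
                              association) {
  out <- hc[order(hc$gene_id), , drop = FALSE]
  mk <- match(out$gene_id, kinetics$gene_id)
  out$category <- kinetics$category[mk]
  out$baseline <- kinetics$baseline[mk]
  out$directness <- kinetics$directness[mk]
  mf <- match(out$gene_id, footprints$gene_id)
  for (col in grep("^(footprint|log2fc)_", names(footprints), value = TRUE)) {
    out[[paste0("smad2_", col)]] <- footprints[[col]][mf]
  }
  out$n_peaks <- footprints$n_peaks[mf]
  mp <- match(out$gene_id, polii_lfc$gene_id)
  for (col in grep("^log2fc_", names(polii_lfc), value = TRUE)) {
    out[[paste0("polii_", col)]] <- polii_lfc[[col]][mp]
  }
  ann <- association[!is.na(association$gene_id), , drop = FALSE]
  if (nrow(ann) && "annotation" %in% names(ann)) {
    agg <- tapply(ann$annotation, ann$gene_id, function(x)
      paste(sort(unique(x)), collapse = ","))
    out$peak_annotations <- as.character(agg[out$gene_id])
  }
  rownames(out) <- NULL
  out
}
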
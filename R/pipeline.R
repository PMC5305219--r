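# End-to-end orchestration of the analysis stages on a study bundle, with
# optional per-stage TSV/BED outputs. Every stage is deterministic given the
# bundle (the only RNG use, shuffle backgrounds, is derived from the bundle's
# seed).

samples_of <- function(sheet, assay, condition = NULL) {
  keep <- sheet$assay == assay
  if (!is.null(condition)) keep <- keep & sheet$condition %in% condition
  sheet$sample_id[keep]
}

wtsv <- function(x, dir, name) {
  if (!is.null(dir)) {
    data.table::fwrite(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       na = "NA")
  }
  invisible(x)
}

#' Run the full integrative pipeline on a study bundle
#'
#' Stages: differential expression and target filtering; kinetic
#' classification; SMAD2 peak filtering, consensus construction, annotation,
#' quantification, gene association and footprints; Pol II normalization,
#' differential windows and gene calls (Ser5P and Ser2P); acetylation-state
#' stratification; directed motif analysis; high-confidence integration.
#'
#' @param bundle a `study_bundle` from [simulate_study()]
#' @param out_dir optional directory for per-stage text outputs
#' @param motifs named IUPAC patterns (default: the shipped pattern file)
#' @param window,step differential-window geometry (bp)
#' @return list with every stage's result tables
#' @export
run_all <- function(bundle, out_dir = NULL, motifs = NULL,
                    window = 1000, step = 100) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  sheet <- bundle$sample_sheet
  genes <- bundle$genes
  seed <- bundle$config$seed

  ## -- RNA differential expression ----------------------------------------
  ck_log("info", "stage de")
  de <- run_de(bundle$counts, sheet)
  de <- apply_target_filters(de, bundle$counts)
  regulated <- attr(de, "regulated")
  wtsv(de, out_dir, "de_results.tsv")
  wtsv(de[de$passes_filters, , drop = FALSE], out_dir, "regulated_genes.tsv")

  ## -- kinetic classification ---------------------------------------------
  ck_log("info", "stage kinetics")
  kin <- kinetic_calls(de, bundle$counts, sheet, inhibitor = bundle$inhibitor)
  wtsv(kin, out_dir, "kinetic_calls.tsv")

  ## -- SMAD2 consensus peaks and footprints -------------------------------
  ck_log("info", "stage peaks")
  all_peaks <- do.call(rbind, bundle$peaks)
  kept <- filter_peaks(all_peaks, bundle$repeats)
  cons <- build_consensus(kept)
  cons$annotation <- annotate_peaks(cons, genes)
  reg_models <- genes[genes$gene_id %in% regulated, , drop = FALSE]
  assoc <- associate_peaks(cons, reg_models)
  assoc$annotation <- cons$annotation[match(assoc$consensus_id,
                                            cons$consensus_id)]
  smad2_ids <- samples_of(sheet, "SMAD2")
  totals <- vapply(bundle$tracks[smad2_ids], `[[`, numeric(1), "n_fragments")
  normc <- normalized_peak_counts(bundle$smad2_reads[smad2_ids], cons, totals)
  fp <- smad2_footprint(assoc, normc, sheet, gene_ids = regulated)
  dens <- peak_density_profile(cons, reg_models, assoc)
  cons$has_foxh1_motif <- NA  # filled by the motif stage below
  wtsv(assoc, out_dir, "peak_gene_association.tsv")
  wtsv(fp, out_dir, "footprints.tsv")
  wtsv(dens, out_dir, "peak_density.tsv")

  ## -- Pol II differential occupancy --------------------------------------
  ck_log("info", "stage polii")
  stim <- c("Activin1h", "Activin8h", "Untreated")
  regions <- list(); polii_factors <- list(); polii_lfc <- list()
  for (ip in c("PolII-Ser5P", "PolII-Ser2P")) {
    ids <- samples_of(sheet, ip)
    bm <- binned_matrix(bundle$tracks[ids])
    sb_ids <- samples_of(sheet, ip, "SB")
    comp_factors <- lapply(stim, function(cc) {
      cid <- c(sb_ids, samples_of(sheet, ip, cc))
      factors_from_binmat(bm[, cid, drop = FALSE])
    })
    comp_factors <- harmonize_sb_geomean(comp_factors,
                                         rep(list(sb_ids), length(stim)))
    names(comp_factors) <- stim
    for (cc in stim) {
      trt_ids <- samples_of(sheet, ip, cc)
      regions[[paste0(sub("PolII-", "", ip), "_", cc)]] <-
        call_differential_windows(bundle$tracks[trt_ids],
                                  bundle$tracks[sb_ids],
                                  comp_factors[[cc]],
                                  window = window, step = step)
    }
    fac_all <- factors_from_binmat(bm)
    polii_factors[[ip]] <- fac_all
    polii_lfc[[ip]] <- gene_level_log2fc(bundle$tracks[ids], genes, fac_all,
                                         sheet)
  }
  calls <- polii_gene_calls(regions, genes)
  polii_set <- calls$gene_id[calls$passes]
  wtsv(calls, out_dir, "polii_gene_calls.tsv")
  region_tab <- do.call(rbind, lapply(names(regions), function(nm) {
    if (nrow(regions[[nm]]) == 0L) return(NULL)
    cbind(comparison = nm, regions[[nm]])
  }))
  if (is.null(region_tab)) {
    region_tab <- data.frame(comparison = character(), chrom = character(),
                             start = numeric(), end = numeric(),
                             direction = character(), n_windows = integer(),
                             min_q = numeric())
  }
  wtsv(region_tab, out_dir, "diff_regions.tsv")
  wtsv(data.frame(sample_id = names(unlist(unname(polii_factors))),
                  factor = unlist(unname(polii_factors))),
       out_dir, "norm_factors.tsv")

  ## -- acetylation state ---------------------------------------------------
  ck_log("info", "stage acetyl")
  loci <- data.frame(locus_id = cons$consensus_id, chrom = cons$chrom,
                     pos = cons$avg_summit, stringsAsFactors = FALSE)
  ac <- list()
  for (mark in c("H3K9Ac", "H3K27Ac")) {
    ids <- samples_of(sheet, mark)
    fac <- normalization_factors(bundle$tracks[ids])
    sig <- locus_signal(bundle$tracks[ids], loci, factors = 1 / fac)
    msub <- sheet[match(ids, sheet$sample_id), ]
    cond_mean <- sapply(ck_conditions, function(cc)
      rowMeans(sig[, msub$condition == cc, drop = FALSE]))
    ac[[mark]] <- list(
      signal = sig,
      cond_mean = cond_mean,
      cluster = hcluster_loci(log2(sig + 1)),
      sb = cond_mean[, "SB"],
      l2fc8 = log2((cond_mean[, "Activin8h"] + 0.5) /
                     (cond_mean[, "SB"] + 0.5)))
  }
  overall <- classify_overall(ac$H3K9Ac$cluster, ac$H3K27Ac$cluster)
  sbbase <- classify_sb_baseline(ac$H3K9Ac$sb, ac$H3K27Ac$sb)
  low_ids <- sbbase$locus_id[!is.na(sbbase$label) &
                               sbbase$label == "low_baseline"]
  indsplit <- classify_induction_split(ac$H3K9Ac$l2fc8, ac$H3K27Ac$l2fc8,
                                       low_ids)
  classes <- rbind(overall, sbbase, indsplit)
  smad2_cond <- sheet[match(smad2_ids, sheet$sample_id), ]
  smad2_8h <- rowMeans(normc[, smad2_cond$condition == "Activin8h",
                             drop = FALSE])
  cmp <- compare_smad2_by_class(smad2_8h, indsplit)
  wtsv(classes, out_dir, "ac_classes.tsv")
  if (!is.null(out_dir)) {
    wtsv(cmp$per_class, out_dir, "class_comparison.tsv")
    sigdf <- data.frame(locus_id = loci$locus_id,
                        ac$H3K9Ac$signal, ac$H3K27Ac$signal,
                        check.names = FALSE)
    wtsv(sigdf, out_dir, "locus_signals.tsv")
  }

  ## -- metaprofiles around consensus summits ------------------------------
  ck_log("info", "stage profiles")
  anchors <- data.frame(chrom = cons$chrom, pos = cons$avg_summit,
                        strand = "+", stringsAsFactors = FALSE)
  profiles <- list()
  for (assay in c("H3", "H3K9Ac", "H3K27Ac")) {
    for (cc in c("SB", "Activin1h", "Activin8h")) {
      ids <- samples_of(sheet, assay, cc)
      tr <- Reduce(pool_tracks, bundle$tracks[ids])
      profiles[[paste0(assay, "_", cc)]] <-
        metaprofile(tr, anchors, window = 2500)
    }
  }
  if (!is.null(out_dir)) {
    pm <- data.frame(offset = profiles[[1L]]$offsets,
                     sapply(profiles, `[[`, "values"), check.names = FALSE)
    wtsv(pm, out_dir, "metaprofiles.tsv")
  }

  ## -- motifs ---------------------------------------------------------------
  ck_log("info", "stage motifs")
  if (is.null(motifs)) {
    motifs <- read_motifs(system.file("extdata", "motifs.tsv",
                                      package = "chromakin"))
  }
  targets <- bundle$sequences$targets
  shuffled <- with_seed(child_seed(seed, "shuffle"), {
    vapply(targets, trinuc_shuffle, character(1))
  })
  backgrounds <- c(list(shuffled = shuffled), bundle$sequences$backgrounds)
  primary <- motifs[[1L]]
  hits <- iupac_scan(targets, primary)
  pos <- positional_distribution(hits)
  enr <- do.call(rbind, lapply(names(motifs), function(nm) {
    cbind(motif = nm,
          background_enrichment(motifs[[nm]], targets, backgrounds))
  }))
  pres_seq <- motif_window_presence(targets, primary)
  # per consensus peak: any member summit sequence with a central-window hit
  seq_locus <- sub("_[^_]+$", "", names(pres_seq))
  member_loci <- bundle$truth$loci$locus_id %||% unique(seq_locus)
  pres_peak <- tapply(pres_seq, seq_locus, any)
  assoc_locus <- !is.na(bundle$truth$loci$gene_id[
    match(names(pres_peak), bundle$truth$loci$locus_id)])
  tab <- table(factor(assoc_locus, c(TRUE, FALSE)),
               factor(as.logical(pres_peak), c(TRUE, FALSE)))
  chisq <- chi_square_2x2(as.matrix(tab))
  wtsv(hits, out_dir, "motif_hits.tsv")
  wtsv(pos$hist, out_dir, "positional_hist.tsv")
  wtsv(enr, out_dir, "enrichment.tsv")
  if (!is.null(out_dir)) {
    wtsv(data.frame(statistic = chisq$statistic, pvalue = chisq$pvalue),
         out_dir, "foxh1_chisq.tsv")
  }

  ## -- integration ----------------------------------------------------------
  ck_log("info", "stage integrate")
  rp <- lapply(bundle$replicate_peaks, filter_peaks, repeats = bundle$repeats)
  rp_by_cond <- lapply(stim, function(cc)
    list(rp[[paste0(cc, "_rep1")]], rp[[paste0(cc, "_rep2")]]))
  names(rp_by_cond) <- stim
  hc <- build_high_confidence(regulated, polii_set, genes, rp_by_cond)
  master <- summarize_targets(hc, kin, fp, polii_lfc[["PolII-Ser5P"]], assoc)
  wtsv(hc, out_dir, "high_confidence.tsv")
  wtsv(master, out_dir, "master_table.tsv")
  if (!is.null(out_dir)) {
    write_bed(data.frame(chrom = cons$chrom, start = cons$start,
                         end = cons$end, name = cons$consensus_id,
                         score = cons$n_members, strand = "."),
              file.path(out_dir, "consensus_peaks.bed"))
    wtsv(cons, out_dir, "consensus_peaks.tsv")
  }

  list(de = de, regulated = regulated, kinetics = kin, consensus = cons,
       association = assoc, norm_counts = normc, footprints = fp,
       density = dens, regions = regions, polii_calls = calls,
       polii_set = polii_set, polii_lfc = polii_lfc,
       acetylation = list(marks = ac, classes = classes, comparison = cmp),
       profiles = profiles,
       motifs = list(hits = hits, positional = pos, enrichment = enr,
                     presence = pres_peak, chisq = chisq),
       high_confidence = hc, master = master)
}
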
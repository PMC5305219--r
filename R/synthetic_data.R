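# Synthetic study generator with planted ground truth.
#
# The generator separates a *geometry* layer (gene placement, SMAD2 binding
# loci, per-condition fold enrichments, acetylation classes, motif embedding)
# from a *measurement* layer (NB counts, fragment placement). Geometry is
# seed-deterministic and identical between noisy and noise-free runs of the
# same seed; `noise_free = TRUE` replaces the measurement layer with its
# zero-dispersion limit (counts = rounded means, fragments on deterministic
# quantile grids, unit library factors), which makes exact truth-table
# recovery by the downstream stages well-defined.

#' Build a simulation configuration
#'
#' Defaults describe the emulated study: a ~5-Mb two-chromosome genome with
#' ~2,000 genes, four conditions (SB-431542, 1 hr Activin, 8 hr Activin,
#' Untreated) with two replicates, NB gene counts with planted kinetic
#' categories, per-condition SMAD2 peak calls with planted fold enrichments,
#' ChIP coverage with planted H3 dips, acetylation flanks (~1.5 kb) and Pol II
#' TSS/TTS peaks, and 500-bp summit sequences with centrally embedded motifs.
#' Planted log2FC triples satisfy the printed classification rules with a
#' margin well above the required 0.1 log2 units.
#'
#' @param seed master RNG seed; all randomness flows from it
#' @param noise_free zero-dispersion-limit measurement layer
#' @param ... overrides for any default listed in the function body
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, noise_free = FALSE, ...) {
  cfg <- list(
    seed = as.integer(seed),
    noise_free = noise_free,
    chrom_lengths = c(chr1 = 3e6, chr2 = 2e6),
    n_genes = 2000L,
    n_replicates = 2L,
    gene_length_range = c(800, 1600),
    gap_range = c(150, 450),
    special_gap = 4500,          # clear flank around regulated/Pol II genes:
                                 # wider than flank (2 kb) + window reach so
                                 # differential regions never touch neighbours
    # RNA measurement
    baseline_mu_meanlog = log(100), baseline_mu_sdlog = 1,
    regulated_mu_range = c(200, 1000),
    baseline_off_mu = 5,
    dispersion = 0.05,
    library_factor_range = c(0.8, 1.25),
    # planted regulation
    n_per_category = 30L,
    n_baseline_off = 16L,
    n_de_only = 8L,              # DE without Pol II change
    n_polii_only = 8L,           # Pol II change without DE
    category_l2fc = list(
      induced_sustained = c(1.5, 2.5, 1.2),
      transient_induced = c(2.0, 0.8, 0.0),
      delayed           = c(0.0, 1.5, 0.8),
      repressed         = c(-0.5, -1.5, -1.0),
      baseline_off      = c(4.0, 6.0, 5.0)),
    polii_l2fc = list(up = c(Activin1h = 1.2, Activin8h = 1.8, Untreated = 1.5),
                      down = c(Activin1h = -0.8, Activin8h = -1.5,
                               Untreated = -1.2)),
    indirect_fraction = 0.3,
    # peaks
    n_background_loci = 60L,
    peaks_per_gene = 1:3,
    peak_width_range = c(300, 600),
    peak_fold_range = c(4, 20),
    n_lowfold_peaks = 20L,
    n_repeat_peaks = 15L,
    p_cond = c(Activin1h = 0.5, Activin8h = 1.0, Untreated = 0.7),
    locus_tss_offset = c(4000, 10000),  # SMAD2 sites kept distal to promoters
    locus_far_offset = c(10000, 60000),
    min_locus_gap = 6000,               # keeps acetylation flanks of distinct
                                        # loci out of each other's windows
    # coverage measurement
    frag_len = 200L,
    n_fragments = 2e5,
    h3_dip_depth = 0.6, h3_dip_sd = 150,
    ac_flank_offset = 750, ac_flank_sd = 350,
    smad2_class_mult = c(high = 1.5, low_increase = 3, low_flat = 1),
    # sequences
    seq_width = 500L,
    motif = "AATCCACA",          # FOXH1-type element
    embed_rate = 0.6, embed_spread = 25,
    n_enhancer_bg = 500L, enhancer_bg_width = 300L,
    n_matched_bg = 500L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) ck_stop("unknown config field(s): %s",
                               paste(unknown, collapse = ", "),
                               class = "chromakin_config_error")
  # YAML configs deliver named lists where the defaults are atomic vectors
  for (nm in names(over)) {
    if (is.atomic(cfg[[nm]]) && is.list(over[[nm]])) {
      over[[nm]] <- unlist(over[[nm]])
    } else if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      over[[nm]] <- lapply(over[[nm]], function(x)
        if (is.list(x)) unlist(x) else x)
    }
  }
  cfg[names(over)] <- over
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  # planted triples must satisfy their rule with margin >= 0.1 log2 units
  margin_ok <- function(triple, category) {
    l1 <- triple[1]; l8 <- triple[2]; lu <- triple[3]
    m <- switch(category,
      induced_sustained = min(l1 - 0.7, l8 - l1, lu - 0),
      transient_induced = min(l1 - 0.7, l1 - l8, l8 - 0, 0.7 - abs(lu)),
      delayed = min(0.7 - l1, l8 - 0.7, lu - 0),
      repressed = min(-0.7 - l8, 0 - lu),
      baseline_off = min(l1 - 0.7, l8 - l1, lu - 0))
    m >= 0.1
  }
  for (nm in names(cfg$category_l2fc)) {
    if (!margin_ok(cfg$category_l2fc[[nm]], nm)) {
      ck_stop("planted log2FC triple for %s violates its rule margin", nm,
              class = "chromakin_config_error")
    }
  }
  if (cfg$seq_width < nchar(cfg$motif)) {
    ck_stop("motif longer than summit sequence",
            class = "chromakin_config_error")
  }
  cfg
}

## ---- geometry layer ----

jit <- function(n, amount) round(runif(n, -amount, amount))

simulate_geometry <- function(cfg) {
  n <- cfg$n_genes
  n_cat <- cfg$n_per_category
  n_de <- 4L * n_cat + cfg$n_baseline_off + cfg$n_de_only
  n_special <- n_de + cfg$n_polii_only
  if (n_special > n) ck_stop("more regulated genes than genes",
                             class = "chromakin_config_error")

  lens <- round(runif(n, cfg$gene_length_range[1], cfg$gene_length_range[2]))
  special_idx <- sort(sample.int(n, n_special))
  special <- seq_len(n) %in% special_idx
  gaps <- round(runif(n, cfg$gap_range[1], cfg$gap_range[2]))
  gaps <- gaps + ifelse(special | c(FALSE, special[-n]), cfg$special_gap, 0)

  chroms <- names(cfg$chrom_lengths)
  chrom <- character(n); start <- numeric(n)
  ci <- 1L; pos <- 5000
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    if (pos + lens[i] + 5000 > cfg$chrom_lengths[[chroms[ci]]]) {
      ci <- ci + 1L
      if (ci > length(chroms)) {
        ck_stop("genes do not fit in the genome: reduce n_genes or enlarge it",
                class = "chromakin_config_error")
      }
      pos <- 5000 + gaps[i]
    }
    chrom[i] <- chroms[ci]; start[i] <- pos
    pos <- pos + lens[i]
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("g%04d", seq_len(n))
  genes <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                      end = start + lens, strand = strand,
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(strand == "+", genes$start, genes$end - 1)
  genes$tts <- ifelse(strand == "+", genes$end - 1, genes$start)
  # two exons per gene (a 15%-length intron)
  e1e <- genes$start + round(lens * 0.4)
  e2s <- genes$start + round(lens * 0.55)
  exons <- rbind(
    data.frame(gene_id = gene_id, chrom = chrom, start = genes$start,
               end = e1e, strand = strand, stringsAsFactors = FALSE),
    data.frame(gene_id = gene_id, chrom = chrom, start = e2s,
               end = genes$end, strand = strand, stringsAsFactors = FALSE))
  exons <- exons[order(exons$gene_id, exons$start), ]
  genes$exon_kb <- (e1e - genes$start + genes$end - e2s) / 1000
  attr(genes, "exons") <- exons[, c("gene_id", "chrom", "start", "end", "strand")]

  # role assignment among the special genes
  pool <- special_idx
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
  pool <- sample(pool)  # decouple role from genomic order
  cats <- c("induced_sustained", "transient_induced", "delayed", "repressed")
  role <- rep("none", n); category <- rep(NA_character_, n)
  for (ct in cats) {
    idx <- take(n_cat); role[idx] <- "de"; category[idx] <- ct
  }
  idx <- take(cfg$n_baseline_off)
  role[idx] <- "de_baseline_off"; category[idx] <- "induced_sustained"
  idx <- take(cfg$n_de_only)
  role[idx] <- "de_only"; category[idx] <- "induced_sustained"
  idx <- take(cfg$n_polii_only)
  role[idx] <- "polii_only"

  genes$role <- role
  genes$category <- category
  genes$de_gene <- role %in% c("de", "de_baseline_off", "de_only")
  genes$polii_gene <- role %in% c("de", "de_baseline_off", "polii_only")
  genes$baseline <- ifelse(role == "de_baseline_off", "off",
                           ifelse(genes$de_gene, "on", NA))

  # expression means
  mu <- exp(rnorm(n, cfg$baseline_mu_meanlog, cfg$baseline_mu_sdlog))
  mu[genes$de_gene | genes$polii_gene] <-
    runif(sum(genes$de_gene | genes$polii_gene),
          cfg$regulated_mu_range[1], cfg$regulated_mu_range[2])
  mu[role == "de_baseline_off"] <- cfg$baseline_off_mu
  genes$mu_sb <- mu

  # planted RNA log2FC triples
  l2 <- matrix(0, n, 3, dimnames = list(gene_id,
                                        c("Activin1h", "Activin8h", "Untreated")))
  for (i in which(genes$de_gene)) {
    key <- if (role[i] == "de_baseline_off") "baseline_off" else category[i]
    l2[i, ] <- cfg$category_l2fc[[key]]
  }
  genes$l2fc_Activin1h <- l2[, 1]; genes$l2fc_Activin8h <- l2[, 2]
  genes$l2fc_Untreated <- l2[, 3]

  # planted Pol II log2FC: occupancy follows transcriptional activity for DE
  # genes (de novo recruitment); polii_only genes change occupancy without a
  # steady-state mRNA change, de_only genes the reverse (stability decoupling)
  p2 <- matrix(0, n, 3, dimnames = dimnames(l2))
  for (i in which(genes$polii_gene)) {
    p2[i, ] <- if (genes$de_gene[i]) l2[i, ] else cfg$polii_l2fc$up
  }
  genes$polii_l2fc_Activin1h <- p2[, 1]; genes$polii_l2fc_Activin8h <- p2[, 2]
  genes$polii_l2fc_Untreated <- p2[, 3]

  # planted directness (regulated genes only)
  genes$directness <- NA_character_
  reg <- which(genes$de_gene)
  genes$directness[reg] <- ifelse(runif(length(reg)) < cfg$indirect_fraction,
                                  "indirect", "direct")

  loci <- place_loci(cfg, genes)
  list(genes = genes, loci = loci$loci, filtered = loci$filtered,
       repeats = loci$repeats)
}

# SMAD2 binding loci near regulated genes plus background, low-fold and
# repeat-embedded peaks; enforces a minimum gap so distinct loci never merge
place_loci <- function(cfg, genes) {
  targets <- genes[genes$de_gene | genes$polii_gene, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    g <- targets[i, ]
    k <- sample(cfg$peaks_per_gene, 1L)
    near <- runif(k) < 0.5
    sgn <- sample(c(-1, 1), k, TRUE)
    off <- sgn * ifelse(near,
                        runif(k, cfg$locus_tss_offset[1], cfg$locus_tss_offset[2]),
                        runif(k, cfg$locus_far_offset[1], cfg$locus_far_offset[2]))
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = g$chrom, summit = round(g$tss + off),
                 intended_gene = g$gene_id, stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, rows)
  nbg <- cfg$n_background_loci
  loci <- rbind(loci, data.frame(
    chrom = sample(names(cfg$chrom_lengths), nbg, TRUE,
                   prob = cfg$chrom_lengths / sum(cfg$chrom_lengths)),
    summit = NA, intended_gene = NA_character_, stringsAsFactors = FALSE))
  bg <- which(is.na(loci$summit))
  tss_by_chrom <- split(genes$tss, genes$chrom)
  for (i in bg) {
    for (try in 1:50) {
      s <- round(runif(1, 5000, cfg$chrom_lengths[[loci$chrom[i]]] - 5000))
      tss <- tss_by_chrom[[loci$chrom[i]]]
      if (is.null(tss) || min(abs(tss - s)) >= 1500) break
    }
    loci$summit[i] <- s
  }
  loci$summit <- pmin(pmax(loci$summit, 5000),
                      cfg$chrom_lengths[loci$chrom] - 5000)
  # drop loci closer than min_locus_gap to a retained earlier locus
  loci <- loci[order(loci$chrom, loci$summit), ]
  keep <- rep(TRUE, nrow(loci))
  lastpos <- -Inf; lastchr <- ""
  for (i in seq_len(nrow(loci))) {
    if (loci$chrom[i] == lastchr && loci$summit[i] - lastpos < cfg$min_locus_gap) {
      keep[i] <- FALSE
    } else {
      lastchr <- loci$chrom[i]; lastpos <- loci$summit[i]
    }
  }
  loci <- loci[keep, , drop = FALSE]
  w <- round(runif(nrow(loci), cfg$peak_width_range[1], cfg$peak_width_range[2]))
  loci$start <- loci$summit - round(w * runif(nrow(loci), 0.4, 0.6))
  loci$end <- loci$start + w
  loci$locus_id <- sprintf("sbs_%04d", seq_len(nrow(loci)))
  # per-condition presence and fold enrichment (never in SB)
  for (cc in names(cfg$p_cond)) {
    pres <- runif(nrow(loci)) < cfg$p_cond[[cc]]
    fe <- ifelse(pres, round(runif(nrow(loci), cfg$peak_fold_range[1],
                                   cfg$peak_fold_range[2]), 2), NA)
    loci[[paste0("present_", cc)]] <- pres
    loci[[paste0("fe_", cc)]] <- fe
  }
  none <- !loci$present_Activin1h & !loci$present_Activin8h &
    !loci$present_Untreated
  loci$present_Activin8h[none] <- TRUE
  loci$fe_Activin8h[none] <- round(runif(sum(none), cfg$peak_fold_range[1],
                                         cfg$peak_fold_range[2]), 2)
  # acetylation class per locus
  loci$ac_class <- sample(c("high", "low_increase", "low_flat"), nrow(loci),
                          replace = TRUE)
  # true gene association: nearest DE gene within 100 kb (brute force)
  de <- genes[genes$de_gene, , drop = FALSE]
  loci$gene_id <- NA_character_; loci$gene_distance <- NA_real_
  for (i in seq_len(nrow(loci))) {
    g <- de[de$chrom == loci$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    s <- loci$summit[i]
    d <- ifelse(s >= g$start & s < g$end, 0,
                pmin(abs(s - g$tss), abs(s - g$tts)))
    j <- which.min(d)
    if (d[j] <= 1e5) {
      loci$gene_id[i] <- g$gene_id[j]; loci$gene_distance[i] <- d[j]
    }
  }
  # low-fold and repeat-embedded peaks (to be filtered out), kept clear of
  # real loci
  free_spot <- function(k) {
    out <- data.frame(chrom = character(), pos = numeric())
    while (nrow(out) < k) {
      chr <- sample(names(cfg$chrom_lengths), 1L,
                    prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
      p <- round(runif(1, 5000, cfg$chrom_lengths[[chr]] - 5000))
      near <- loci$chrom == chr & abs(loci$summit - p) < cfg$min_locus_gap
      if (!any(near)) out <- rbind(out, data.frame(chrom = chr, pos = p))
    }
    out
  }
  lf <- free_spot(cfg$n_lowfold_peaks)
  rp <- free_spot(cfg$n_repeat_peaks)
  wlf <- round(runif(nrow(lf), cfg$peak_width_range[1], cfg$peak_width_range[2]))
  wrp <- round(runif(nrow(rp), cfg$peak_width_range[1], cfg$peak_width_range[2]))
  filtered <- rbind(
    data.frame(chrom = lf$chrom, summit = lf$pos, start = lf$pos - wlf %/% 2,
               end = lf$pos + (wlf + 1) %/% 2,
               fe = round(runif(nrow(lf), 1.2, 2.9), 2),
               why = "low_fold", stringsAsFactors = FALSE),
    data.frame(chrom = rp$chrom, summit = rp$pos, start = rp$pos - wrp %/% 2,
               end = rp$pos + (wrp + 1) %/% 2,
               fe = round(runif(nrow(rp), 4, 15), 2),
               why = "repeat", stringsAsFactors = FALSE))
  filtered$condition <- sample(c("Activin1h", "Activin8h", "Untreated"),
                               nrow(filtered), replace = TRUE)
  # repeat annotation: covers the repeat peaks entirely, plus decoys
  rep_bed <- data.frame(chrom = rp$chrom, start = rp$pos - wrp,
                        end = rp$pos + wrp, stringsAsFactors = FALSE)
  decoy <- free_spot(10L)
  rep_bed <- rbind(rep_bed, data.frame(chrom = decoy$chrom,
                                       start = decoy$pos - 200,
                                       end = decoy$pos + 200))
  rep_bed$name <- sprintf("rep_%02d", seq_len(nrow(rep_bed)))
  rep_bed$score <- 0L; rep_bed$strand <- "."
  list(loci = loci, filtered = filtered, repeats = rep_bed)
}

## ---- measurement layer ----

# vectorized grid positions: for feature i with n_i draws, the j-th draw sits
# at quantile (j - 0.5) / n_i of the feature's distribution
grid_q <- function(n) {
  (sequence(n) - 0.5) / rep.int(n, n)
}

#' Simulate a ChIP coverage track from spatial intensity components
#'
#' Fragments of length `frag_len` are placed with the planted intensity
#' (genome-wide uniform background, Gaussian point features, uniform region
#' features), then optional Gaussian "dips" thin fragments near their centres
#' (nucleosome depletion). Per-base depth is the fragment pileup. Component
#' weights are absolute fractions of `n_fragments` and need not sum to 1, so
#' a feature whose weight does not change between conditions yields exactly
#' the same fragments in every sample of a noise-free run.
#'
#' @param components list with up to three elements: `uniform` (scalar
#'   weight), `gaussian` (data.frame chrom, center, sd, weight), `region`
#'   (data.frame chrom, start, end, weight)
#' @param n_fragments fragment count corresponding to total weight 1
#' @param chrom_lengths named chromosome lengths
#' @param dips optional data.frame(chrom, center, sd, depth) of thinning dips
#' @param frag_len fragment length (bp)
#' @param noise_free deterministic quantile-grid placement
#' @param sample_id track label
#' @return list: track (`cov_track`), centers (data.frame chrom, pos)
#' @export
simulate_coverage <- function(components, n_fragments, chrom_lengths,
                              dips = NULL, frag_len = 200L,
                              noise_free = FALSE, sample_id = NA_character_) {
  chr_parts <- list(); pos_parts <- list()
  uw <- components$uniform %||% 0
  if (uw < 0) ck_stop("negative component weight",
                      class = "chromakin_config_error")
  if (uw > 0) {
    kc <- round(n_fragments * uw * chrom_lengths / sum(chrom_lengths))
    chr_parts$u <- rep(names(chrom_lengths), kc)
    pos_parts$u <- unlist(lapply(names(chrom_lengths), function(ch) {
      if (noise_free) grid_q(kc[[ch]]) * chrom_lengths[[ch]]
      else runif(kc[[ch]], 0, chrom_lengths[[ch]])
    }), use.names = FALSE)
  }
  ga <- components$gaussian
  if (!is.null(ga) && nrow(ga)) {
    if (any(ga$weight < 0)) ck_stop("negative component weight",
                                    class = "chromakin_config_error")
    n <- round(n_fragments * ga$weight)
    keep <- n > 0
    nk <- n[keep]
    q <- if (noise_free) stats::qnorm(grid_q(nk)) else rnorm(sum(nk))
    chr_parts$g <- rep(ga$chrom[keep], nk)
    pos_parts$g <- rep(ga$center[keep], nk) + q * rep(ga$sd[keep], nk)
  }
  rg <- components$region
  if (!is.null(rg) && nrow(rg)) {
    if (any(rg$weight < 0)) ck_stop("negative component weight",
                                    class = "chromakin_config_error")
    n <- round(n_fragments * rg$weight)
    keep <- n > 0
    nk <- n[keep]
    q <- if (noise_free) grid_q(nk) else runif(sum(nk))
    chr_parts$r <- rep(rg$chrom[keep], nk)
    pos_parts$r <- rep(rg$start[keep], nk) +
      q * rep(rg$end[keep] - rg$start[keep], nk)
  }
  cent <- data.frame(chrom = unlist(chr_parts, use.names = FALSE) %||% character(0),
                     pos = unlist(pos_parts, use.names = FALSE) %||% numeric(0),
                     stringsAsFactors = FALSE)
  cent$pos <- round(cent$pos)
  cent <- cent[cent$pos >= 0 & cent$pos < chrom_lengths[cent$chrom], ,
               drop = FALSE]
  if (!is.null(dips) && nrow(cent) > 0L && nrow(dips) > 0L) {
    keepp <- rep(1, nrow(cent))
    for (chr in unique(dips$chrom)) {
      dd <- dips[dips$chrom == chr, , drop = FALSE]
       idx <- which(cent$chrom == chr)
      if (!length(idx)) next
      ctr <- sort(dd$center)
      near <- findInterval(cent$pos[idx], ctr)
      lo <- pmax(near, 1L); hi <- pmin(near + 1L, length(ctr))
      d <- pmin(abs(cent$pos[idx] - ctr[lo]), abs(cent$pos[idx] - ctr[hi]))
      keepp[idx] <- 1 - dd$depth[1L] * exp(-d^2 / (2 * dd$sd[1L]^2))
    }
    cent <- cent[runif(nrow(cent)) < keepp, , drop = FALSE]
  }
  half <- frag_len %/% 2L
  frags <- data.frame(chrom = cent$chrom, start = cent$pos - half,
                      end = cent$pos + (frag_len - half))
  track <- cov_from_fragments(frags, chrom_lengths, sample_id = sample_id)
  track$n_fragments <- nrow(cent)
  list(track = track, centers = cent)
}

# component sets per assay; weights are condition-invariant for unchanged
# features (see simulate_coverage) so noise-free nulls are exact
chip_components <- function(assay, cond, cfg, geom) {
  g <- geom$genes; l <- geom$loci
  pres <- l[[paste0("present_", cond)]] %||% rep(FALSE, nrow(l))
  fe <- l[[paste0("fe_", cond)]]
  gauss <- function(chrom, center, sd, weight) {
    data.frame(chrom = chrom, center = center, sd = sd, weight = weight,
               stringsAsFactors = FALSE)
  }
  if (assay == "SMAD2") {
    if (cond == "SB") return(list(uniform = 0.2))
    mult <- cfg$smad2_class_mult[l$ac_class]
    w <- ifelse(pres, fe * mult, 0)
    w <- 0.8 * w / sum(w)  # per-condition scaling (SMAD2 is not window-tested)
    list(uniform = 0.2, gaussian = gauss(l$chrom, l$summit, 50, w))
  } else if (assay %in% c("PolII-Ser5P", "PolII-Ser2P")) {
    lf <- if (cond == "SB") rep(0, nrow(g)) else
      g[[paste0("polii_l2fc_", cond)]] %||% rep(0, nrow(g))
    w <- 0.9 * g$mu_sb * 2^lf / sum(g$mu_sb)
    if (assay == "PolII-Ser5P") {
      list(uniform = 0.1, gaussian = gauss(g$chrom, g$tss, 250, w))
    } else {
      list(uniform = 0.1,
           gaussian = gauss(g$chrom, g$tts, 300, 0.35 * w),
           region = data.frame(chrom = g$chrom, start = g$start, end = g$end,
                               weight = 0.65 * w, stringsAsFactors = FALSE))
    }
  } else if (assay %in% c("H3K9Ac", "H3K27Ac")) {
    amp <- ac_amplitude(l$ac_class, cond)
    s_ref <- sum(ac_amplitude(l$ac_class, "Activin8h"))  # fixed reference scale
    wl <- 0.4 * amp / s_ref
    # promoter acetylation is kept minor so SBS flanks dominate their own
    # +/- 2.5 kb windows even in a gene-dense toy genome
    list(uniform = 0.1,
         gaussian = rbind(
           gauss(g$chrom, g$tss, 300, 0.05 * g$mu_sb / sum(g$mu_sb)),
           gauss(l$chrom, l$summit - cfg$ac_flank_offset, cfg$ac_flank_sd,
                 wl / 2),
           gauss(l$chrom, l$summit + cfg$ac_flank_offset, cfg$ac_flank_sd,
                 wl / 2)))
  } else if (assay == "H3") {
    list(uniform = 1)
  } else ck_stop("no component model for assay %s", assay)
}

# relative acetylation-flank amplitude per class and condition
ac_amplitude <- function(class, cond) {
  base <- c(high = 2, low_increase = 0, low_flat = 0)[class]
  if (cond %in% c("Activin8h", "Untreated")) {
    base <- base + ifelse(class == "low_increase",
                          ifelse(cond == "Activin8h", 1, 0.9), 0)
  } else if (cond == "Activin1h") {
    base <- base + ifelse(class == "low_increase", 0.2, 0)
  }
  unname(base)
}

simulate_counts_matrix <- function(cfg, geom, sheet) {
  g <- geom$genes
  rna <- sheet[sheet$assay == "RNA", , drop = FALSE]
  lib <- if (cfg$noise_free) rep(1, nrow(rna)) else
    runif(nrow(rna), cfg$library_factor_range[1], cfg$library_factor_range[2])
  m <- sapply(seq_len(nrow(rna)), function(j) {
    cond <- rna$condition[j]
    lf <- if (cond == "SB") rep(0, nrow(g)) else g[[paste0("l2fc_", cond)]]
    mu <- g$mu_sb * 2^lf * lib[j]
    if (cfg$noise_free) round(mu) else
      rnbinom(nrow(g), mu = mu, size = 1 / cfg$dispersion)
  })
  dimnames(m) <- list(g$gene_id, rna$sample_id)
  m
}

make_sample_sheet <- function(cfg) {
  assays <- c("RNA", "SMAD2", "PolII-Ser5P", "PolII-Ser2P", "H3K9Ac",
              "H3K27Ac", "H3")
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      condition = ck_conditions, assay = assays,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("assay", "condition", "replicate")]
  grid$sample_id <- sprintf("%s_%s_r%d", gsub("PolII-", "", grid$assay),
                            grid$condition, grid$replicate)
  grid[, c("sample_id", "assay", "condition", "replicate")]
}

make_peak_tables <- function(cfg, geom) {
  l <- geom$loci
  conds <- c("Activin1h", "Activin8h", "Untreated")
  mk_row <- function(chrom, start, end, summit, fe, cond, q) {
    data.frame(chrom = chrom, start = start, end = end,
               name = NA_character_, score = 0L, strand = ".",
               fold_enrichment = fe, pvalue = -1, qvalue = q,
               summit = summit, condition = cond, stringsAsFactors = FALSE)
  }
  cond_peaks <- list(); rep_peaks <- list()
  for (cc in conds) {
    idx <- which(l[[paste0("present_", cc)]])
    if (length(idx)) {
      p <- mk_row(l$chrom[idx], l$start[idx] + jit(length(idx), 30),
                  l$end[idx] + jit(length(idx), 30),
                  l$summit[idx] + jit(length(idx), 20),
                  l[[paste0("fe_", cc)]][idx], cc,
                  signif(runif(length(idx), 1e-6, 0.04), 3))
    } else {
      p <- mk_row(character(0), numeric(0), numeric(0), numeric(0),
                  numeric(0), character(0), numeric(0))
    }
    f <- geom$filtered[geom$filtered$condition == cc, , drop = FALSE]
    if (nrow(f)) {
      p <- rbind(p, mk_row(f$chrom, f$start, f$end, f$summit, f$fe, cc,
                           signif(runif(nrow(f), 1e-6, 0.04), 3)))
    }
    p$summit <- pmax(pmin(p$summit, p$end - 1), p$start)
    p$name <- sprintf("%s_peak_%04d", cc, seq_len(nrow(p)))
    cond_peaks[[cc]] <- p
    for (r in 1:2) {
      pr <- p
      pr$start <- pr$start + jit(nrow(pr), 25)
      pr$end <- pr$end + jit(nrow(pr), 25)
      pr$summit <- pmax(pmin(pr$summit + jit(nrow(pr), 15), pr$end - 1), pr$start)
      pr$name <- sprintf("%s_r%d_peak_%04d", cc, r, seq_len(nrow(pr)))
      rep_peaks[[sprintf("%s_rep%d", cc, r)]] <- pr
    }
  }
  list(by_condition = cond_peaks, by_replicate = rep_peaks)
}

make_sequences <- function(cfg, geom) {
  l <- geom$loci
  conds <- c("Activin1h", "Activin8h", "Untreated")
  ids <- character(); chroms <- character()
  for (cc in conds) {
    idx <- which(l[[paste0("present_", cc)]])
    ids <- c(ids, sprintf("%s_%s", l$locus_id[idx], cc))
  }
  w <- cfg$seq_width
  rand_seq <- function(n, width) {
    if (n == 0L) return(character(0))
    big <- paste(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
                 collapse = "")
    substring(big, (seq_len(n) - 1L) * width + 1L, seq_len(n) * width)
  }
  seqs <- stats::setNames(rand_seq(length(ids), w), ids)
  center <- w %/% 2L
  mlen <- nchar(cfg$motif)
  motif_rc <- revcomp(cfg$motif)
  emb <- list()
  for (i in seq_along(seqs)) {
    if (runif(1) >= cfg$embed_rate) next
    off <- round(rnorm(1, 0, cfg$embed_spread))
    off <- max(min(off, w - center - mlen), -center)
    strand <- sample(c("+", "-"), 1L)
    ins <- if (strand == "+") cfg$motif else motif_rc
    s0 <- center + off  # 0-based insert position
    substr(seqs[i], s0 + 1L, s0 + mlen) <- ins
    emb[[length(emb) + 1L]] <- data.frame(
      sequence_id = names(seqs)[i], offset = off, strand = strand,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(emb)) do.call(rbind, emb) else
    data.frame(sequence_id = character(), offset = integer(),
               strand = character(), stringsAsFactors = FALSE)
  backgrounds <- list(
    enhancer_summits_synthetic =
      stats::setNames(rand_seq(cfg$n_enhancer_bg, cfg$enhancer_bg_width),
                      sprintf("enh_%04d", seq_len(cfg$n_enhancer_bg))),
    distance_matched_synthetic =
      stats::setNames(rand_seq(cfg$n_matched_bg, w),
                      sprintf("match_%04d", seq_len(cfg$n_matched_bg))))
  list(targets = seqs, backgrounds = backgrounds, truth = truth)
}

make_inhibitor_table <- function(cfg, geom) {
  g <- geom$genes[geom$genes$de_gene, , drop = FALSE]
  n <- nrow(g)
  l1 <- numeric(n); l8 <- numeric(n)
  for (i in seq_len(n)) {
    ct <- g$category[i]
    if (g$directness[i] == "direct") {
      if (ct == "repressed") { l1[i] <- -0.6; l8[i] <- -1.2 }
      else if (ct == "transient_induced") { l1[i] <- 1.6; l8[i] <- 0.6 }
      else { l1[i] <- 0.9; l8[i] <- 1.5 }
    } else {
      if (ct == "repressed") { l1[i] <- -0.1; l8[i] <- -0.3 }
      else if (ct == "transient_induced") { l1[i] <- 0.3; l8[i] <- 0.9 }
      else { l1[i] <- 0.2; l8[i] <- 0.3 }
    }
  }
  data.frame(gene_id = g$gene_id, l1h_chx = l1, l8h_chx = l8,
             l1h_eme = l1, l8h_eme = l8, stringsAsFactors = FALSE)
}

## ---- the study bundle ----

#' Simulate a complete synthetic study
#'
#' Generates gene models, RNA count matrices, per-condition and per-replicate
#' SMAD2 peak calls, repeat annotation, ChIP coverage tracks for SMAD2, Pol II
#' (Ser5P/Ser2P), H3K9Ac/H3K27Ac and H3, summit sequences with embedded
#' motifs, a translation-inhibitor log2FC table, and truth tables for every
#' planted feature. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()]
#' @return list of class `study_bundle`
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    geom <- simulate_geometry(config)
    sheet <- make_sample_sheet(config)
    counts <- simulate_counts_matrix(config, geom, sheet)
    peaks <- make_peak_tables(config, geom)
    seqs <- make_sequences(config, geom)
    inhibitor <- make_inhibitor_table(config, geom)

    chip <- sheet[sheet$assay != "RNA", , drop = FALSE]
    tracks <- list(); smad2_reads <- list()
    dip_loci <- geom$loci
    for (j in seq_len(nrow(chip))) {
      smp <- chip$sample_id[j]; assay <- chip$assay[j]; cond <- chip$condition[j]
      comp <- chip_components(assay, cond, config, geom)
      dips <- NULL
      if (assay == "H3" && cond != "SB") {
        dips <- data.frame(chrom = dip_loci$chrom, center = dip_loci$summit,
                           sd = config$h3_dip_sd, depth = config$h3_dip_depth)
      }
      sim <- simulate_coverage(comp, config$n_fragments, config$chrom_lengths,
                               dips = dips, frag_len = config$frag_len,
                               noise_free = config$noise_free, sample_id = smp)
      tracks[[smp]] <- sim$track
      if (assay == "SMAD2") {
        ctr <- sim$centers
        strand <- if (config$noise_free) {
          rep(c("+", "-"), length.out = nrow(ctr))
        } else sample(c("+", "-"), nrow(ctr), replace = TRUE)
        half <- config$frag_len %/% 2L
        smad2_reads[[smp]] <- data.frame(
          chrom = ctr$chrom,
          pos = ifelse(strand == "+", ctr$pos - half, ctr$pos + half),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
    truth <- build_truth(config, geom)
    truth$motifs <- seqs$truth
    structure(list(config = config, genes = geom$genes,
                   sample_sheet = sheet, counts = counts,
                   peaks = peaks$by_condition,
                   replicate_peaks = peaks$by_replicate,
                   repeats = geom$repeats, tracks = tracks,
                   smad2_reads = smad2_reads, sequences = seqs,
                   inhibitor = inhibitor, truth = truth),
              class = "study_bundle")
  })
}

build_truth <- function(cfg, geom) {
  g <- geom$genes; l <- geom$loci
  de_set <- g$gene_id[g$de_gene]
  polii_set <- g$gene_id[g$polii_gene]
  # replicated SMAD2 peak within 100 kb of TSS/TTS (every planted locus is
  # present in both replicates)
  summits_by_chrom <- split(l$summit, l$chrom)
  has_peak <- vapply(seq_len(nrow(g)), function(i) {
    s <- summits_by_chrom[[g$chrom[i]]]
    if (is.null(s)) return(FALSE)
    any(ifelse(s >= g$start[i] & s < g$end[i], 0,
               pmin(abs(s - g$tss[i]), abs(s - g$tts[i]))) <= 1e5)
  }, logical(1))
  core <- intersect(de_set, polii_set)
  rescue <- union(setdiff(de_set, polii_set), setdiff(polii_set, de_set))
  rescue <- rescue[rescue %in% g$gene_id[has_peak]]
  hc <- sort(union(core, rescue))
  list(genes = g,
       loci = l,
       filtered_peaks = geom$filtered,
       de_genes = sort(de_set),
       polii_genes = sort(polii_set),
       high_confidence = data.frame(
         gene_id = hc,
         evidence = ifelse(hc %in% core, "rna_de,polii_diff",
                           ifelse(hc %in% de_set, "rna_de,rescued_by_replicated_peak",
                                  "polii_diff,rescued_by_replicated_peak")),
         stringsAsFactors = FALSE),
       motifs = NULL)  # filled by simulate_study caller (sequences truth)
}

#' Write a study bundle to a directory of standard-format files
#'
#' @param bundle from [simulate_study()]
#' @param dir output directory (created)
#' @param coverage also export per-sample bedGraph tracks (large)
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir, coverage = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("peaks", "truth", "sequences")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }
  write_counts(bundle$counts, file.path(dir, "counts.tsv"))
  write_sample_sheet(bundle$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  write_gene_models(bundle$genes, file.path(dir, "genes.gtf"))
  write_bed(bundle$repeats, file.path(dir, "repeats.bed"))
  for (cc in names(bundle$peaks)) {
    write_peaks(bundle$peaks[[cc]],
                file.path(dir, "peaks", paste0("SMAD2_", cc, ".narrowPeak")))
  }
  for (nm in names(bundle$replicate_peaks)) {
    write_peaks(bundle$replicate_peaks[[nm]],
                file.path(dir, "peaks", paste0("SMAD2_", nm, ".narrowPeak")))
  }
  write_fasta(bundle$sequences$targets,
              file.path(dir, "sequences", "summits.fa"))
  for (nm in names(bundle$sequences$backgrounds)) {
    write_fasta(bundle$sequences$backgrounds[[nm]],
                file.path(dir, "sequences", paste0(nm, ".fa")))
  }
  data.table::fwrite(bundle$inhibitor, file.path(dir, "inhibitor.tsv"),
                     sep = "\t")
  for (smp in names(bundle$smad2_reads)) {
    r <- bundle$smad2_reads[[smp]]
    write_bed(data.frame(chrom = r$chrom, start = r$pos, end = r$pos + 1,
                         name = ".", score = 0L, strand = r$strand),
              file.path(dir, paste0("reads_", smp, ".bed")))
  }
  tt <- bundle$truth
  data.table::fwrite(tt$genes, file.path(dir, "truth", "genes.tsv"), sep = "\t")
  data.table::fwrite(tt$loci, file.path(dir, "truth", "loci.tsv"), sep = "\t")
  data.table::fwrite(tt$filtered_peaks,
                     file.path(dir, "truth", "filtered_peaks.tsv"), sep = "\t")
  data.table::fwrite(tt$high_confidence,
                     file.path(dir, "truth", "high_confidence.tsv"), sep = "\t")
  data.table::fwrite(bundle$sequences$truth,
                     file.path(dir, "truth", "motifs.tsv"), sep = "\t")
  writeLines(c(paste0("de_genes\t", paste(tt$de_genes, collapse = ",")),
               paste0("polii_genes\t", paste(tt$polii_genes, collapse = ","))),
             file.path(dir, "truth", "gene_sets.tsv"))
  if (coverage) {
    for (smp in names(bundle$tracks)) {
      write_coverage(bundle$tracks[[smp]],
                     file.path(dir, paste0("cov_", smp, ".bedGraph")))
    }
  }
  yaml::write_yaml(bundle$config[setdiff(names(bundle$config), "noise_free")],
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
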
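test_that("config validation enforces rule margins and feasibility", {
  expect_error(sim_config(category_l2fc = list(
    induced_sustained = c(0.75, 2.5, 1.2),  # margin over 0.7 below 0.1
    transient_induced = c(2.0, 0.8, 0.0),
    delayed = c(0.0, 1.5, 0.8),
    repressed = c(-0.5, -1.5, -1.0),
    baseline_off = c(4, 6, 5))), class = "chromakin_config_error")
  expect_error(sim_config(motif = paste(rep("A", 600), collapse = "")),
               class = "chromakin_config_error")
  expect_error(sim_config(nonsense_field = 1),
               class = "chromakin_config_error")
  expect_error(simulate_study(sim_config(chrom_lengths = c(chr1 = 5e4),
                                         n_genes = 500)),
               class = "chromakin_config_error")
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- tiny_config(seed = 99, n_genes = 120, n_fragments = 5e3,
                     n_per_category = 3, n_baseline_off = 2, n_de_only = 1,
                     n_polii_only = 1)
  b1 <- simulate_study(cfg)
  b2 <- simulate_study(cfg)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$truth$genes, b2$truth$genes)
  expect_identical(b1$sequences$targets, b2$sequences$targets)
  expect_identical(lapply(b1$tracks, function(t) t$cov),
                   lapply(b2$tracks, function(t) t$cov))
  b3 <- simulate_study(tiny_config(seed = 100, n_genes = 120,
                                   n_fragments = 5e3, n_per_category = 3,
                                   n_baseline_off = 2, n_de_only = 1,
                                   n_polii_only = 1))
  expect_false(identical(b1$counts, b3$counts))
})

test_that("a zero-regulated configuration yields empty truth and 0 targets", {
  cfg <- tiny_config(seed = 5, n_genes = 150, n_per_category = 0,
                     n_baseline_off = 0, n_de_only = 0, n_polii_only = 0,
                     n_fragments = 5e3)
  b <- simulate_study(cfg)
  expect_length(b$truth$de_genes, 0)
  expect_equal(nrow(b$truth$high_confidence), 0L)
  de <- run_de(b$counts, b$sample_sheet)
  de <- apply_target_filters(de, b$counts)
  # noisy null: BH keeps the false-positive target count at ~0
  expect_lte(length(attr(de, "regulated")), 2)
})

test_that("NB counts match the stated moments (mu = 100, alpha = 0.1)", {
  set.seed(50)
  x <- rnbinom(1e4, mu = 100, size = 1 / 0.1)
  expect_equal(mean(x), 100, tolerance = 0.02)
  expect_equal(var(x), 100 + 0.1 * 100^2, tolerance = 0.1)
  # the generator's count layer reproduces planted means per condition
  nf <- nf_run()
  tg <- nf$bundle$truth$genes
  cts <- nf$bundle$counts
  is_g <- tg$gene_id[tg$de_gene & tg$category == "induced_sustained" &
                       tg$baseline == "on"][1]
  i <- match(is_g, tg$gene_id)
  sb_cols <- grepl("SB", colnames(cts))
  a1_cols <- grepl("Activin1h", colnames(cts))
  expect_equal(mean(cts[is_g, a1_cols]) / mean(cts[is_g, sb_cols]),
               2^tg$l2fc_Activin1h[i], tolerance = 0.01)
})

test_that("uniform coverage yields the exact expected mean depth", {
  sim <- simulate_coverage(list(uniform = 1), n_fragments = 1e5,
                           chrom_lengths = c(chr1 = 1e6), noise_free = TRUE)
  v <- as.numeric(sim$track$cov$chr1)
  expect_equal(mean(v), 1e5 * 200 / 1e6, tolerance = 0.01)
  zero <- simulate_coverage(list(uniform = 0), 1e5, c(chr1 = 1e4))
  expect_equal(sum(as.numeric(zero$track$cov$chr1)), 0)
  expect_error(simulate_coverage(list(uniform = -1), 10, c(chr1 = 100)),
               class = "chromakin_config_error")
})

test_that("planted H3 dips put the depth minimum at the summit", {
  summit <- 5e4
  dips <- data.frame(chrom = "chr1", center = summit, sd = 150, depth = 0.6)
  set.seed(51)
  sim <- simulate_coverage(list(uniform = 1), 2e5, c(chr1 = 1e5), dips = dips)
  prof <- metaprofile(sim$track,
                      data.frame(chrom = "chr1", pos = summit, strand = "+"),
                      window = 2000)
  expect_lte(abs(prof$offsets[which.min(prof$values)]), 50)
})

test_that("motif embedding matches rate, spread and truth table", {
  cfg <- tiny_config(seed = 6, embed_spread = 0, embed_rate = 1)
  b <- simulate_study(cfg)
  tr <- b$sequences$truth
  expect_equal(nrow(tr), length(b$sequences$targets))
  expect_true(all(tr$offset == 0))
  # every sequence has the motif exactly at the centre
  hits <- iupac_scan(b$sequences$targets, cfg$motif)
  center_hits <- hits[hits$offset == 0, ]
  expect_setequal(unique(center_hits$sequence_id), names(b$sequences$targets))

  cfg0 <- tiny_config(seed = 6, embed_rate = 0)
  b0 <- simulate_study(cfg0)
  expect_equal(nrow(b0$sequences$truth), 0L)

  # rate 0.6: embedded count within the binomial 99% interval
  cfg6 <- tiny_config(seed = 8, embed_rate = 0.6)
  b6 <- simulate_study(cfg6)
  n <- length(b6$sequences$targets)
  k <- nrow(b6$sequences$truth)
  expect_gte(k, qbinom(0.005, n, 0.6))
  expect_lte(k, qbinom(0.995, n, 0.6))
})

test_that("bundles write and read back through standard formats", {
  cfg <- tiny_config(seed = 12, n_genes = 100, n_per_category = 2,
                     n_baseline_off = 1, n_de_only = 1, n_polii_only = 1,
                     n_fragments = 4e3, n_background_loci = 4,
                     n_lowfold_peaks = 2, n_repeat_peaks = 2)
  b <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  counts <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(counts, b$counts)
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  expect_equal(sheet$sample_id, b$sample_sheet$sample_id)
  gm <- read_gene_models(file.path(dir, "genes.gtf"))
  expect_equal(gm$gene_id, b$genes$gene_id)
  expect_equal(gm$start, b$genes$start)
  p <- read_peaks(file.path(dir, "peaks", "SMAD2_Activin8h.narrowPeak"),
                  condition = "Activin8h")
  expect_equal(nrow(p), nrow(b$peaks$Activin8h))
  fa <- read_fasta(file.path(dir, "sequences", "summits.fa"))
  expect_identical(fa, b$sequences$targets)
})
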
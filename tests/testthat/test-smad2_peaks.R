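test_that("fold-enrichment and repeat filters follow the printed thresholds", {
  p <- mk_peaks("chr1", c(100, 400, 700), c(300, 600, 900),
                fe = c(2.9, 3.0, 10))
  reps <- data.frame(chrom = "chr1", start = 700, end = 820,
                     stringsAsFactors = FALSE)  # 60% of the third peak
  kept <- filter_peaks(p, reps)
  expect_setequal(kept$name, "p2")  # 2.9 dropped, 3.0 kept, repeat dropped
  expect_equal(filter_peaks(p, NULL)$name, c("p2", "p3"))
})

test_that("repeat-overlap fraction matches the per-base oracle", {
  set.seed(10)
  for (i in 1:40) {
    np <- sample(3:8, 1); nr <- sample(1:6, 1)
    ps <- sample(0:9000, np); pe <- ps + sample(50:400, np, replace = TRUE)
    rs <- sample(0:9000, nr); re <- rs + sample(50:500, nr, replace = TRUE)
    p <- mk_peaks("chr1", ps, pe)
    reps <- data.frame(chrom = "chr1", start = rs, end = re)
    got <- filter_peaks(p, reps, min_fold = 0, max_repeat_frac = 2)
    want <- vapply(seq_len(np), function(j)
      bf_repeat_frac(ps[j], pe[j], rs, re), numeric(1))
    expect_equal(got$repeat_frac, want)
  }
})

test_that("consensus construction merges on >= 1 shared nucleotide", {
  p <- mk_peaks("chr1", c(100, 150, 400), c(200, 300, 500),
                condition = c("Activin1h", "Activin8h", "Untreated"))
  cons <- build_consensus(p)
  expect_equal(cons$start, c(100, 400))
  expect_equal(cons$end, c(200 + 100, 500))
  expect_equal(cons$n_members, c(2L, 1L))
  expect_equal(cons$conditions[1], "Activin1h,Activin8h")
  # touching half-open peaks share no base: not merged
  touch <- mk_peaks("chr1", c(100, 200), c(200, 300))
  expect_equal(nrow(build_consensus(touch)), 2L)
  # disjoint input unchanged; empty input works
  expect_equal(nrow(build_consensus(p[3, ])), 1L)
  expect_equal(nrow(build_consensus(p[0, ])), 0L)
})

test_that("consensus is idempotent and input-order invariant", {
  set.seed(11)
  s <- sample(0:5000, 30); p <- mk_peaks("chr1", s, s + sample(50:500, 30, TRUE))
  cons <- build_consensus(p)
  again <- build_consensus(mk_peaks(cons$chrom, cons$start, cons$end,
                                    summit = cons$avg_summit))
  expect_equal(again[, c("start", "end")], cons[, c("start", "end")])
  shuf <- build_consensus(p[sample(nrow(p)), ])
  expect_equal(shuf[, c("start", "end", "n_members")],
               cons[, c("start", "end", "n_members")])
})

test_that("consensus merging matches the per-base oracle on random sets", {
  set.seed(12)
  for (i in 1:60) {
    n <- sample(2:20, 1)
    s <- sample(0:9000, n); e <- s + sample(20:600, n, replace = TRUE)
    cons <- build_consensus(mk_peaks("chr1", s, e))
    bf <- bf_merge(s, e)
    expect_equal(cons$start, bf$start)
    expect_equal(cons$end, bf$end)
    # membership: average summit lies inside its merged interval
    expect_true(all(cons$avg_summit >= cons$start & cons$avg_summit < cons$end))
  }
})

genes_fix <- function() {
  mk_genes(data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(10000, 40000), end = c(20000, 46000),
    strand = c("+", "-"), stringsAsFactors = FALSE),
    exons = data.frame(gene_id = c("gA", "gA", "gB"), chrom = "chr1",
                       start = c(10000, 16000, 40000),
                       end = c(12000, 20000, 46000),
                       strand = c("+", "+", "-"), stringsAsFactors = FALSE))
}

test_that("peak annotation follows the documented precedence", {
  g <- genes_fix()
  cons <- data.frame(consensus_id = sprintf("c%d", 1:5), chrom = "chr1",
                     start = 0, end = 1,
                     avg_summit = c(9700,   # 300 bp upstream of gA TSS
                                    11000,  # exon of gA
                                    13000,  # intron of gA
                                    30000,  # intergenic, + side of gA
                                    47000), # upstream of minus-strand gB
                     stringsAsFactors = FALSE)
  ann <- annotate_peaks(cons, g)
  expect_equal(ann, c("TSS", "exonic", "intronic", "downstream_intergenic",
                      "upstream_intergenic"))
  expect_error(annotate_peaks(cons, g[0, ]),
               class = "chromakin_annotation_error")
})

test_that("annotation matches the brute-force membership oracle", {
  set.seed(13)
  g <- genes_fix()
  ex <- attr(g, "exons")
  summits <- sample(0:60000, 300)
  cons <- data.frame(consensus_id = sprintf("c%d", seq_along(summits)),
                     chrom = "chr1", start = 0, end = 1, avg_summit = summits,
                     stringsAsFactors = FALSE)
  got <- annotate_peaks(cons, g)
  want <- vapply(summits, bf_annotate, character(1), genes = g, exons = ex)
  expect_equal(got, want)
})

test_that("normalized peak counts scale to 40e6 mapped reads with +100 shift", {
  cons <- data.frame(consensus_id = "c1", chrom = "chr1", start = 1000,
                     end = 1400, avg_summit = 1200, stringsAsFactors = FALSE)
  # 50 plus-strand reads whose shifted positions land inside the peak
  reads <- list(s1 = data.frame(chrom = "chr1", pos = rep(1100, 50),
                                strand = "+", stringsAsFactors = FALSE))
  out <- normalized_peak_counts(reads, cons, totals = c(s1 = 2e7))
  expect_equal(out["c1", "s1"], 100)  # 50 * 4e7 / 2e7
  out2 <- normalized_peak_counts(reads, cons, totals = c(s1 = 4e7))
  expect_equal(out2["c1", "s1"], 50)
  # minus-strand read shifts 3'-ward (leftward): pos 1450 -> 1350, inside
  readsm <- list(s1 = data.frame(chrom = "chr1", pos = 1450, strand = "-"))
  expect_equal(normalized_peak_counts(readsm, cons, c(s1 = 4e7))["c1", "s1"], 1)
  expect_error(normalized_peak_counts(reads, cons, c(s1 = 0)))
})

test_that("peak-gene association follows nearest-within-100kb", {
  g <- mk_genes(data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                           start = c(100000, 240000), end = c(110000, 250000),
                           strand = "+", stringsAsFactors = FALSE))
  cons <- data.frame(consensus_id = c("c1", "c2"), chrom = "chr1",
                     start = 0, end = 1,
                     avg_summit = c(160000,  # 50 kb from gA TTS, 80 kb from gB
                                    500000), # > 100 kb from everything
                     stringsAsFactors = FALSE)
  assoc <- associate_peaks(cons, g)
  expect_equal(assoc$gene_id, c("gA", NA))
  expect_equal(assoc$distance, c(50001, NA))
})

test_that("association matches the all-pairs distance oracle", {
  set.seed(14)
  for (i in 1:30) {
    ng <- sample(2:6, 1)
    gs <- sort(sample(seq(0, 4e5, by = 1000), ng))
    g <- mk_genes(data.frame(gene_id = sprintf("g%02d", seq_len(ng)),
                             chrom = "chr1", start = gs, end = gs + 5000,
                             strand = sample(c("+", "-"), ng, TRUE),
                             stringsAsFactors = FALSE))
    summits <- sample(0:5e5, 50)
    cons <- data.frame(consensus_id = sprintf("c%d", 1:50), chrom = "chr1",
                       start = 0, end = 1, avg_summit = summits,
                       stringsAsFactors = FALSE)
    got <- associate_peaks(cons, g)
    want <- vapply(summits, bf_associate, character(1), genes = g)
    expect_equal(got$gene_id, want)
  }
})

test_that("footprints sum replicate-averaged counts per gene", {
  assoc <- data.frame(consensus_id = c("c1", "c2", "c3"),
                      gene_id = c("gA", "gA", NA), distance = c(0, 10, NA),
                      stringsAsFactors = FALSE)
  nc <- matrix(c(100, 140, 50, 70,    # c1: means 120 (8 hr), 60 (SB)
                 60, 100, 30, 50,     # c2: means 80 (8 hr), 40 (SB)
                 0, 0, 0, 0), nrow = 3, byrow = TRUE,
               dimnames = list(c("c1", "c2", "c3"),
                               c("SMAD2_Activin8h_r1", "SMAD2_Activin8h_r2",
                                 "SMAD2_SB_r1", "SMAD2_SB_r2")))
  sheet <- data.frame(sample_id = colnames(nc), assay = "SMAD2",
                      condition = rep(c("Activin8h", "SB"), each = 2),
                      replicate = c(1, 2, 1, 2), stringsAsFactors = FALSE)
  fp <- smad2_footprint(assoc, nc, sheet, gene_ids = c("gA", "gZ"))
  # gA: peaks c1 (mean 120) + c2 (mean 80) = 200 at 8 hr
  expect_equal(fp$footprint_Activin8h[fp$gene_id == "gA"], 200)
  expect_equal(fp$footprint_SB[fp$gene_id == "gA"], 100)
  expect_equal(fp$n_peaks, c(2L, 0L))
  expect_equal(fp$footprint_Activin8h[fp$gene_id == "gZ"], 0)
  expect_true(is.na(fp$log2fc_Activin8h[fp$gene_id == "gZ"]))
})

test_that("footprint additivity and conservation hold", {
  nf <- nf_run()
  fp <- nf$res$footprints
  assoc <- nf$res$association
  nc <- nf$res$norm_counts
  sheet <- nf$bundle$sample_sheet
  smad2 <- sheet[sheet$assay == "SMAD2", ]
  # conservation: total footprint mass equals replicate-averaged normalized
  # counts over all assigned peaks
  for (cc in c("SB", "Activin8h")) {
    cols <- smad2$sample_id[smad2$condition == cc]
    assigned <- assoc$consensus_id[!is.na(assoc$gene_id)]
    expect_equal(sum(fp[[paste0("footprint_", cc)]]),
                 sum(rowMeans(nc[assigned, cols, drop = FALSE])))
  }
  # additivity: splitting a peak's counts across two pseudo-peaks of the same
  # gene leaves the footprint unchanged
  a2 <- rbind(assoc[!is.na(assoc$gene_id), ][1, ],
              assoc[!is.na(assoc$gene_id), ][1, ])
  a2$consensus_id <- c("x1", "x2")
  nc2 <- rbind(x1 = nc[assoc$consensus_id[!is.na(assoc$gene_id)][1], ] * 0.3,
               x2 = nc[assoc$consensus_id[!is.na(assoc$gene_id)][1], ] * 0.7)
  one <- smad2_footprint(assoc[!is.na(assoc$gene_id), ][1, , drop = FALSE],
                         nc, sheet)
  two <- smad2_footprint(a2, nc2, sheet)
  expect_equal(two$footprint_Activin8h, one$footprint_Activin8h)
})

test_that("peak density maps summits onto the 20-kb modeled gene", {
  g <- mk_genes(data.frame(gene_id = c("gP", "gM"), chrom = "chr1",
                           start = c(200000, 400000), end = c(250000, 410000),
                           strand = c("+", "-"), stringsAsFactors = FALSE))
  cons <- data.frame(consensus_id = c("c1", "c2", "c3"), chrom = "chr1",
                     start = 0, end = 1,
                     avg_summit = c(200000, 225000, 409999),
                     stringsAsFactors = FALSE)
  assoc <- data.frame(consensus_id = c("c1", "c2", "c3"),
                      gene_id = c("gP", "gP", "gM"), distance = 0,
                      stringsAsFactors = FALSE)
  d <- peak_density_profile(cons, g, assoc, binsize = 1000)
  # TSS summit -> coordinate 0; midpoint of a 50-kb gene -> 10 kb;
  # minus-strand TSS -> coordinate 0 after flipping
  expect_equal(d$count[d$bin_start == 0], 2L)
  expect_equal(d$count[d$bin_start == 10000], 1L)
  expect_equal(sum(d$count), 3L)
})
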
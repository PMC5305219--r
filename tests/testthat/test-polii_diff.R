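mk_noisy_track <- function(seed, len = 2e5, n = 2e4, enrich = NULL,
                           sample_id = "s") {
  set.seed(seed)
  pos <- runif(n, 0, len)
  if (!is.null(enrich)) {
    pos <- c(pos, runif(enrich$n, enrich$start, enrich$end))
  }
  frags <- data.frame(chrom = "chr1", start = round(pos) - 100,
                      end = round(pos) + 100)
  cov_from_fragments(frags, c(chr1 = len), sample_id = sample_id)
}

test_that("normalization factors: identity and scaling equivariance", {
  tr <- mk_noisy_track(1)
  tracks <- list(a = tr, b = tr, c = tr)
  expect_equal(unname(normalization_factors(tracks)), c(1, 1, 1))
  tr3 <- tr
  tr3$cov <- lapply(tr3$cov, function(r) r * 3L)
  f <- normalization_factors(list(a = tr, b = tr, c = tr3))
  expect_equal(f[["c"]] / f[["a"]], 3, tolerance = 1e-6)
})

test_that("planted enrichment in few bins is excluded by the CV filter", {
  base <- mk_noisy_track(2, len = 5e5, n = 1e5)
  # same library, 1% of the genome strongly enriched in one sample
  enr <- mk_noisy_track(2, len = 5e5, n = 1e5,
                        enrich = list(n = 2e4, start = 2e5, end = 2.05e5))
  f <- normalization_factors(list(a = base, b = base, c = enr))
  expect_equal(f[["c"]] / f[["a"]], 1, tolerance = 0.02)
})

test_that("normalization errors on too few usable bins", {
  tiny <- mk_noisy_track(3, len = 5e3, n = 500)
  expect_error(normalization_factors(list(a = tiny, b = tiny)),
               class = "chromakin_normalization_error")
})

test_that("SB geometric-mean harmonization is exact", {
  f1 <- c(SB_r1 = 1.0, SB_r2 = 1.44, t_r1 = 2.0, t_r2 = 1.8)
  f2 <- c(SB_r1 = 0.9, SB_r2 = 0.712, t_r1 = 0.5, t_r2 = 3.0)
  out <- harmonize_sb_geomean(list(f1, f2),
                              list(c("SB_r1", "SB_r2"), c("SB_r1", "SB_r2")))
  gm <- function(f) exp(mean(log(f[c("SB_r1", "SB_r2")])))
  expect_identical(out[[1]], f1)  # single reference comparison unchanged
  expect_lt(abs(gm(out[[2]]) - gm(out[[1]])), 1e-12)
  # within-comparison ratios preserved exactly
  expect_equal(out[[2]] / out[[2]][1], f2 / f2[1])
  expect_equal(harmonize_sb_geomean(list(f1), list(c("SB_r1", "SB_r2")))[[1]],
               f1)
})

test_that("differential windows find a planted enriched block", {
  len <- 3e5
  sb <- list(s1 = mk_noisy_track(4, len, 3e4),
             s2 = mk_noisy_track(5, len, 3e4))
  trt <- list(t1 = mk_noisy_track(6, len, 3e4,
                                  enrich = list(n = 2000, start = 1e5, end = 1.05e5)),
              t2 = mk_noisy_track(7, len, 3e4,
                                  enrich = list(n = 2000, start = 1e5, end = 1.05e5)))
  fac <- stats::setNames(rep(1, 4), c("s1", "s2", "t1", "t2"))
  reg <- call_differential_windows(trt, sb, fac)
  up <- reg[reg$direction == "up", ]
  expect_gt(nrow(up), 0)
  covered <- sum(pmin(up$end, 1.05e5) - pmax(up$start, 1e5))
  expect_gt(covered / 5e3, 0.8)
})

test_that("identical groups produce no differential regions post-BH", {
  len <- 2e5
  a <- mk_noisy_track(8, len, 2e4); b <- mk_noisy_track(9, len, 2e4)
  fac <- stats::setNames(rep(1, 4), c("s1", "s2", "t1", "t2"))
  reg <- call_differential_windows(list(t1 = a, t2 = b), list(s1 = a, s2 = b),
                                   fac)
  expect_lte(nrow(reg), 1)
  empty <- cov_from_fragments(data.frame(chrom = character(),
                                         start = numeric(), end = numeric()),
                              c(chr1 = len))
  reg0 <- call_differential_windows(list(t1 = empty, t2 = empty),
                                    list(s1 = empty, s2 = empty), fac)
  expect_equal(nrow(reg0), 0L)
})

test_that("overlap ratio boundary arithmetic is exact", {
  g <- mk_genes(data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
                           end = 20000, strand = "+", stringsAsFactors = FALSE))
  reg <- data.frame(chrom = "chr1", start = 12000, end = 12900,
                    direction = "up", stringsAsFactors = FALSE)
  out <- gene_overlap_ratio(reg, g)
  expect_equal(out$overlap_ratio, 0.09)
  expect_true(out$passes)
  out0 <- gene_overlap_ratio(reg[0, ], g)
  expect_equal(out0$overlap_ratio, 0)
  expect_false(out0$passes)
  # flanks count in the numerator but not the denominator
  rflank <- data.frame(chrom = "chr1", start = 8000, end = 22000)
  expect_equal(gene_overlap_ratio(rflank, g)$overlap_ratio, 14000 / 10000)
  expect_error(gene_overlap_ratio(reg, within(g, end <- start)),
               class = "chromakin_validation_error")
})

test_that("overlap ratios match the per-base oracle and are monotone", {
  set.seed(15)
  for (i in 1:30) {
    g <- mk_genes(data.frame(gene_id = "g1", chrom = "chr1",
                             start = s <- sample(2000:4000, 1),
                             end = s + sample(1000:5000, 1), strand = "+",
                             stringsAsFactors = FALSE))
    n <- sample(1:8, 1)
    rs <- sample(0:9000, n)
    reg <- data.frame(chrom = "chr1", start = rs,
                      end = rs + sample(100:2000, n, replace = TRUE))
    got <- gene_overlap_ratio(reg, g)$overlap_ratio
    expect_equal(got, bf_overlap_ratio(g[1, ], reg))
    # adding a region never lowers the ratio
    extra <- rbind(reg, data.frame(chrom = "chr1", start = 1000, end = 1500))
    expect_gte(gene_overlap_ratio(extra, g)$overlap_ratio, got)
  }
})

test_that("polii gene calls take the per-comparison maximum", {
  g <- mk_genes(data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                           start = c(0, 50000), end = c(10000, 60000),
                           strand = "+", stringsAsFactors = FALSE))
  r1 <- data.frame(chrom = "chr1", start = 0, end = 950, direction = "up")
  r2 <- data.frame(chrom = "chr1", start = 0, end = 200, direction = "up")
  calls <- polii_gene_calls(list(a = r1, b = r2), g)
  expect_equal(calls$max_ratio, c(0.095, 0))
  expect_equal(calls$passes, c(TRUE, FALSE))
  excl <- polii_gene_calls(list(a = r1, b = r2), g, exclude = "g1")
  expect_false(any(excl$passes))
})

test_that("gene-level log2FC recovers a planted 2-fold occupancy change", {
  g <- mk_genes(data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
                           end = 12000, strand = "+", stringsAsFactors = FALSE))
  sheet <- data.frame(sample_id = c("sb1", "sb2", "a1", "a2"),
                      assay = "PolII-Ser5P",
                      condition = rep(c("SB", "Activin1h"), each = 2),
                      replicate = c(1, 2, 1, 2), stringsAsFactors = FALSE)
  mk <- function(depth, noise, id) {
    set.seed(noise)
    v <- c(rep(0, 8000), rep(depth, 8000) + rpois(8000, 2), rep(0, 4000))
    mk_track_from_values(v, sample_id = id)
  }
  tracks <- list(sb1 = mk(20, 1, "sb1"), sb2 = mk(20, 2, "sb2"),
                 a1 = mk(42, 3, "a1"), a2 = mk(42, 4, "a2"))  # 2x over (20+2)
  fac <- stats::setNames(rep(1, 4), names(tracks))
  out <- gene_level_log2fc(tracks, g, fac, sheet)
  expect_equal(out$log2fc_Activin1h, 1, tolerance = 0.1)
  # identical conditions give ~0; an empty region gives NA
  same <- gene_level_log2fc(list(sb1 = tracks$sb1, sb2 = tracks$sb2,
                                 a1 = tracks$sb1, a2 = tracks$sb2),
                            g, fac, sheet)
  expect_lt(abs(same$log2fc_Activin1h), 0.05)
  g2 <- mk_genes(data.frame(gene_id = "g2", chrom = "chr1", start = 30000,
                            end = 32000, strand = "+",
                            stringsAsFactors = FALSE))
  empty <- lapply(tracks, function(t) mk_track_from_values(rep(0, 40000)))
  expect_true(is.na(gene_level_log2fc(empty, g2, fac, sheet)$log2fc_Activin1h))
})

test_that("bundle Pol II log2FCs separate planted up, down and flat genes", {
  nf <- nf_run()
  lfc <- nf$res$polii_lfc[["PolII-Ser5P"]]
  tg <- nf$bundle$truth$genes
  m <- match(tg$gene_id, lfc$gene_id)
  up <- tg$polii_gene & tg$polii_l2fc_Activin8h > 0
  down <- tg$polii_gene & tg$polii_l2fc_Activin8h < 0
  flat <- !tg$polii_gene
  expect_gt(min(lfc$log2fc_Activin8h[m][up]), 0.5)
  expect_lt(max(lfc$log2fc_Activin8h[m][down]), -0.3)
  # unchanged genes are exactly 0 in the zero-dispersion limit
  expect_lt(max(abs(lfc$log2fc_Activin8h[m][flat])), 1e-6)
})
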
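test_that("SMAD element scanning reports both strands around the centre", {
  hits <- iupac_scan(c(s1 = "TTAGACTT"), "AGAC")
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$offset, -2L)           # centre of an 8-mer is index 4
  expect_equal(plus$matched, "AGAC")
  # GTCT is the reverse complement: found as a minus-strand AGAC hit
  hits2 <- iupac_scan(c(s1 = "TTGTCTTT"), "AGAC")
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$matched, "GTCT")
})

test_that("IUPAC degeneracy: ARAC matches A[AG]AC", {
  hits <- iupac_scan(c(s = "AAACAGAC"), "ARAC")
  plus <- hits[hits$strand == "+", ]
  expect_equal(sort(plus$offset + 4L), c(0L, 4L))  # 0-based starts 0 and 4
  expect_error(iupac_scan(c(s = "AAXX"), "AGAC"),
               class = "chromakin_validation_error")
  expect_error(iupac_scan(c(s = "ACGT"), "AJC"),
               class = "chromakin_validation_error")
})

test_that("scanning matches a regex-expansion oracle on random sequences", {
  set.seed(40)
  seqs <- stats::setNames(rand_dna(300, 60), sprintf("s%03d", 1:300))
  for (pat in c("AGAC", "AATCCACA", "RYSWKM", "TGTNNATT")) {
    got <- iupac_scan(seqs, pat)
    want <- oracle_iupac_scan(seqs, pat)
    expect_equal(got$sequence_id, want$sequence_id)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
  }
})

test_that("reverse-complementing the sequences mirrors the hit set", {
  set.seed(41)
  seqs <- stats::setNames(rand_dna(50, 41), sprintf("s%02d", 1:50))
  pat <- "AGASCA"
  fwd <- iupac_scan(seqs, pat)
  rc <- iupac_scan(stats::setNames(
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs))),
    names(seqs)), pat)
  # a + hit starting at 0-based i becomes a - hit at n - len - i
  n <- 41L; len <- 6L; center <- n %/% 2L
  mirrored <- data.frame(sequence_id = fwd$sequence_id,
                         start = n - len - (fwd$offset + center),
                         strand = ifelse(fwd$strand == "+", "-", "+"),
                         stringsAsFactors = FALSE)
  mirrored$offset <- mirrored$start - center
  o1 <- mirrored[order(mirrored$sequence_id, mirrored$offset, mirrored$strand),
                 c("sequence_id", "offset", "strand")]
  o2 <- rc[, c("sequence_id", "offset", "strand")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o2, o1)
})

test_that("positional distribution and central fraction", {
  hits <- data.frame(sequence_id = "s", offset = c(0, 0, 0), strand = "+",
                     matched = "AGAC", stringsAsFactors = FALSE)
  pd <- positional_distribution(hits)
  expect_equal(sum(pd$hist$count), 3L)
  expect_equal(pd$central_fraction, 1)
  empty <- positional_distribution(hits[0, ])
  expect_equal(empty$n_hits, 0L)
  expect_true(is.na(empty$central_fraction))
  set.seed(42)
  u <- data.frame(sequence_id = "s", offset = sample(-250:249, 2000, TRUE),
                  strand = "+", matched = "X", stringsAsFactors = FALSE)
  pd2 <- positional_distribution(u)
  expect_equal(pd2$central_fraction, 101 / 500, tolerance = 0.12)
})

test_that("tri-nucleotide shuffle preserves the k-let spectrum exactly", {
  expect_equal(trinuc_shuffle("AAAA", seed = 1), "AAAA")
  set.seed(43)
  for (i in 1:25) {
    s <- rand_dna(1, sample(c(10, 50, 200), 1))
    sh <- trinuc_shuffle(s, seed = i)
    expect_equal(kmer_tab(sh), kmer_tab(s))
    expect_equal(nchar(sh), nchar(s))
  }
  expect_equal(suppressMessages(trinuc_shuffle("AC", seed = 1)), "AC")
})

test_that("shuffling is seed-deterministic and actually permutes", {
  s <- rand_dna(1, 300)
  expect_identical(trinuc_shuffle(s, seed = 9), trinuc_shuffle(s, seed = 9))
  shuffles <- vapply(1:10, function(k) trinuc_shuffle(s, seed = k),
                     character(1))
  expect_gt(length(unique(shuffles)), 5)
})

test_that("background enrichment: identity, planted rates, absent pattern", {
  set.seed(44)
  targets <- stats::setNames(rand_dna(400, 500), sprintf("t%03d", 1:400))
  emb <- targets
  idx <- 1:240  # 60% embedding
  substr(emb[idx], 245, 252) <- "AATCCACA"
  out <- background_enrichment("AATCCACA", emb,
                               list(raw = targets, self = emb))
  expect_equal(out$fold[out$set == "self"], 1)
  expect_gt(out$fold[out$set == "raw"], 5)
  expect_error(background_enrichment("AATCCACA", emb, list(empty = character())),
               class = "chromakin_validation_error")
  none <- background_enrichment("AAAAAAAAAAAAAAAA", emb, list(raw = targets))
  expect_equal(none$fraction, c(0, 0))
  expect_true(is.na(none$fold[2]))
})

test_that("central-window presence requires the full hit inside the window", {
  s <- paste(rep("C", 201), collapse = "")
  hit_center <- s; substr(hit_center, 99, 106) <- "AATCCACA"
  hit_edge <- s; substr(hit_edge, 180, 187) <- "AATCCACA"
  out <- motif_window_presence(c(a = hit_center, b = hit_edge, c = s),
                               "AATCCACA", window = 100)
  expect_equal(unname(out), c(TRUE, FALSE, FALSE))
})

test_that("chi-square 2x2 matches the hand computation", {
  out <- chi_square_2x2(matrix(c(10, 30, 90, 70), 2))
  expect_equal(out$statistic, 12.5)
  expect_lt(out$pvalue, 0.001)
  expect_equal(out$expected, matrix(c(20, 20, 80, 80), 2), ignore_attr = TRUE)
  same <- chi_square_2x2(matrix(c(20, 20, 80, 80), 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$pvalue, 1)
  # continuity correction reduces the statistic
  expect_lt(chi_square_2x2(matrix(c(10, 30, 90, 70), 2),
                           correct = TRUE)$statistic, 12.5)
})

test_that("chi-square is calibrated under a planted null", {
  set.seed(45)
  p <- replicate(500, {
    a <- rbinom(1, 100, 0.3); b <- rbinom(1, 100, 0.3)
    chi_square_2x2(matrix(c(a, b, 100 - a, 100 - b), 2))$pvalue
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("the shipped motif pattern file parses", {
  pats <- read_motifs(system.file("extdata", "motifs.tsv",
                                  package = "chromakin"))
  expect_true("FOXH1" %in% names(pats))
  expect_true(all(nchar(pats) > 0))
})
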
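# Brute-force / independent oracles used to check the IRanges-backed and
# rule-based implementations. All operate per base on small instances.

# distance between two 0-based half-open intervals via per-base sets:
# 0 on any shared base, else the number of bases strictly between the
# nearest occupied bases
bf_distance <- function(a, b) {
  sa <- seq(a$start, a$end - 1); sb <- seq(b$start, b$end - 1)
  if (length(intersect(sa, sb))) return(0)
  min(abs(outer(sa[c(1, length(sa))], sb[c(1, length(sb))], "-"))) - 1
}

# transitive >= 1-shared-base merge: union-find over pairwise per-base-set
# intersections (touching half-open intervals share no base and stay apart)
bf_merge <- function(starts, ends) {
  n <- length(starts)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- intersect(seq(starts[i], ends[i] - 1),
                          seq(starts[j], ends[j] - 1))
      if (length(shared)) comp[max(find(i), find(j))] <- min(find(i), find(j))
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(roots), function(r) {
    idx <- which(roots == r)
    data.frame(start = min(starts[idx]), end = max(ends[idx]))
  }))
  out[order(out$start), , drop = FALSE]
}

# fraction of peak bases covered by the union of repeat intervals
bf_repeat_frac <- function(pstart, pend, rstarts, rends) {
  bases <- seq(pstart, pend - 1)
  covered <- rep(FALSE, length(bases))
  for (i in seq_along(rstarts)) {
    covered <- covered | (bases >= rstarts[i] & bases < rends[i])
  }
  mean(covered)
}

# summit annotation by explicit membership checks (precedence as documented)
bf_annotate <- function(summit, genes, exons, tss_window = 500) {
  if (any(abs(summit - genes$tss) <= tss_window)) return("TSS")
  if (any(summit >= exons$start & summit < exons$end)) return("exonic")
  if (any(summit >= genes$start & summit < genes$end)) return("intronic")
  d <- pmax(genes$start - summit, summit - (genes$end - 1), 0)
  ng <- genes[which.min(d), ]
  st <- if (ng$strand == "-") "-" else "+"
  before <- summit < ng$start
  if ((st == "+" && before) || (st == "-" && !before)) {
    "upstream_intergenic"
  } else "downstream_intergenic"
}

# nearest regulated gene by all-pairs distance scan (ties: smallest gene_id)
bf_associate <- function(summit, genes, max_distance = 1e5) {
  genes <- genes[order(genes$gene_id), ]
  d <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (summit >= g$start && summit < g$end) return(0)
    min(abs(summit - g$tss), abs(summit - g$tts))
  }, numeric(1))
  j <- which.min(d)
  if (d[j] <= max_distance) genes$gene_id[j] else NA_character_
}

# differential bases over gene +/- flank by per-base counting
bf_overlap_ratio <- function(gene, regions, flank = 2000) {
  lo <- gene$start - flank; hi <- gene$end + flank
  bases <- seq(max(lo, 0), hi - 1)
  hit <- rep(FALSE, length(bases))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (bases >= regions$start[i] & bases < regions$end[i])
  }
  sum(hit) / (gene$end - gene$start)
}

# independent transcription of the printed kinetic rules (precedence order)
oracle_kinetics <- function(l1h, l8h, luntr) {
  if (l1h >= 0.7 && l8h > l1h && luntr >= 0) return("induced_sustained")
  if (l1h >= 0.7 && l8h < l1h && l8h >= 0 && luntr <= 0.7 && luntr >= -0.7) {
    return("transient_induced")
  }
  if (l1h <= 0.7 && l8h >= 0.7 && luntr > 0) return("delayed")
  if (l8h <= -0.7 && luntr <= 0) return("repressed")
  "unclassified"
}

# IUPAC scan oracle: expand the pattern to regex character classes and find
# overlapping matches with lookahead on both strands
oracle_iupac_scan <- function(seqs, pattern) {
  codes <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
             W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
             V = "ACG", N = "ACGT")
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  to_re <- function(p) {
    paste(vapply(strsplit(p, "")[[1]], function(ch) {
      cl <- codes[[ch]]
      if (nchar(cl) == 1) cl else paste0("[", cl, "]")
    }, character(1)), collapse = "")
  }
  rc <- function(p) {
    paste(rev(comp[strsplit(p, "")[[1]]]), collapse = "")
  }
  scan1 <- function(id, s, pat, strand) {
    m <- gregexpr(paste0("(?=", to_re(pat), ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    center <- floor(nchar(s) / 2)
    data.frame(sequence_id = id, offset = as.integer(m) - 1L - center,
               strand = strand, stringsAsFactors = FALSE)
  }
  prc <- rc(pattern)
  out <- do.call(rbind, c(
    lapply(names(seqs), function(id) scan1(id, seqs[[id]], pattern, "+")),
    if (!identical(prc, pattern)) {
      lapply(names(seqs), function(id) scan1(id, seqs[[id]], prc, "-"))
    }))
  if (is.null(out)) {
    return(data.frame(sequence_id = character(), offset = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out[order(out$sequence_id, out$offset, out$strand), , drop = FALSE]
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# random DNA string
rand_dna <- function(n, width) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = ""),
    character(1))
}

kmer_tab <- function(seq, k = 3) {
  n <- nchar(seq)
  table(vapply(seq_len(n - k + 1), function(i) substr(seq, i, i + k - 1),
               character(1)))
}
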
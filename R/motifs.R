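# Directed IUPAC motif analysis of summit sequences: double-strand scanning,
# summit-relative positional distributions, tri-nucleotide-preserving shuffle
# backgrounds, per-background enrichment, and the central-window chi-square
# comparison.

iupac_codes <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

check_iupac <- function(pattern) {
  ch <- strsplit(toupper(pattern), "")[[1L]]
  if (length(ch) == 0L || !all(ch %in% names(iupac_codes))) {
    ck_stop("invalid IUPAC pattern '%s'", pattern,
            class = "chromakin_validation_error")
  }
  paste(ch, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Scan sequences for an IUPAC motif on both strands
#'
#' Matching is delegated to Biostrings with IUPAC semantics
#' (`fixed = FALSE`); the reverse strand is scanned as the pattern's reverse
#' complement and reported with strand "-". Overlapping hits are all
#' reported. Offsets are relative to the sequence centre (index
#' `floor(length/2)`, 0-based), the summit position for 500-bp summit
#' sequences.
#'
#' @param seqs named character vector (or DNAStringSet) over A/C/G/T/N
#' @param pattern IUPAC motif string
#' @return data.frame sequence_id, offset, strand, matched
#' @export
iupac_scan <- function(seqs, pattern) {
  pattern <- check_iupac(pattern)
  if (!methods::is(seqs, "DNAStringSet")) {
    bad <- grepl("[^ACGTNacgtn]", seqs)
    if (any(bad)) {
      ck_stop("sequence %s contains non-ACGTN characters",
              names(seqs)[bad][1L] %||% which(bad)[1L],
              class = "chromakin_validation_error")
    }
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%d", seq_along(seqs))
  scan_one_strand <- function(pat, strand) {
    hits <- Biostrings::vmatchPattern(pat, seqs, fixed = FALSE)
    parts <- lapply(seq_along(seqs), function(i) {
      ir <- hits[[i]]
      if (length(ir) == 0L) return(NULL)
      center <- floor(length(seqs[[i]]) / 2)
      data.frame(sequence_id = names(seqs)[i],
                 offset = IRanges::start(ir) - 1L - center,
                 strand = strand,
                 matched = as.character(Biostrings::extractAt(seqs[[i]], ir)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  }
  fwd <- scan_one_strand(pattern, "+")
  rcp <- revcomp(pattern)
  rev_ <- if (identical(rcp, pattern)) NULL else scan_one_strand(rcp, "-")
  out <- rbind(fwd, rev_)
  if (is.null(out)) {
    out <- data.frame(sequence_id = character(), offset = integer(),
                      strand = character(), matched = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$sequence_id, out$offset, out$strand), , drop = FALSE]
}

#' Positional distribution of motif hits relative to the summit
#'
#' Strand-collapsed histogram of hit offsets, plus a central-enrichment score:
#' the fraction of hits within +/- `central` bp of the summit.
#'
#' @param hits output of [iupac_scan()]
#' @param binsize histogram bin (bp)
#' @param central central-window half-width (bp)
#' @return list: hist (data.frame bin_start, bin_mid, count),
#'   central_fraction, n_hits
#' @export
positional_distribution <- function(hits, binsize = 10, central = 50) {
  if (nrow(hits) == 0L) {
    return(list(hist = data.frame(bin_start = numeric(), bin_mid = numeric(),
                                  count = integer()),
                central_fraction = NA_real_, n_hits = 0L))
  }
  lo <- floor(min(hits$offset) / binsize) * binsize
  hi <- ceiling((max(hits$offset) + 1) / binsize) * binsize
  breaks <- seq(lo, hi, by = binsize)
  h <- graphics::hist(hits$offset, breaks = breaks, right = FALSE, plot = FALSE)
  list(hist = data.frame(bin_start = head(breaks, -1L), bin_mid = h$mids,
                         count = h$counts),
       central_fraction = mean(abs(hits$offset) <= central),
       n_hits = nrow(hits))
}

# run expr with a private, restored RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Tri-nucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson k-let shuffle (k = 3): a random Eulerian walk through the
#' di-nucleotide transition multigraph, so the tri-nucleotide multiset of the
#' output equals the input's exactly. Sequences shorter than 3 are returned
#' unchanged with a warning.
#'
#' @param seq single sequence (character scalar)
#' @param seed optional RNG seed (local, state restored)
#' @param k k-let size
#' @return shuffled sequence
#' @export
trinuc_shuffle <- function(seq, seed = NULL, k = 3L) {
  n <- nchar(seq)
  if (n < k) {
    ck_log("warning", "sequence shorter than k = ", k, "; returned unchanged")
    return(seq)
  }
  with_seed(seed, {
    ch <- strsplit(toupper(seq), "")[[1L]]
    km1 <- vapply(seq_len(n - k + 2L), function(i)
      paste(ch[i:(i + k - 2L)], collapse = ""), character(1))
    from <- km1[-length(km1)]
    to <- km1[-1L]
    verts <- unique(km1)
    last <- km1[length(km1)]
    adj <- split(to, factor(from, levels = verts))
    # random last-edge choice per vertex forming an arborescence toward `last`
    nonlast <- setdiff(verts[lengths(adj) > 0L], last)
    last_edge <- character(0)
    while (length(nonlast) > 0L) {
      last_edge <- vapply(nonlast, function(v) sample(adj[[v]], 1L), character(1))
      ok <- all(vapply(nonlast, function(v) {
        seen <- character()
        while (v != last && !v %in% seen && v %in% names(last_edge)) {
          seen <- c(seen, v)
          v <- last_edge[[v]]
        }
        v == last
      }, logical(1)))
      if (ok) break
    }
    ordered <- lapply(verts, function(v) {
      e <- adj[[v]]
      if (is.null(e) || length(e) == 0L) return(character())
      if (v %in% names(last_edge)) {
        le <- last_edge[[v]]
        e <- e[-match(le, e)]
        c(if (length(e) > 1L) sample(e) else e, le)
      } else {
        if (length(e) > 1L) sample(e) else e
      }
    })
    names(ordered) <- verts
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    out <- character(n - k + 1L)
    v <- km1[1L]
    for (i in seq_len(n - k + 1L)) {
      nxt <- ordered[[v]][ptr[[v]]]
      ptr[[v]] <- ptr[[v]] + 1L
      out[i] <- substr(nxt, k - 1L, k - 1L)
      v <- nxt
    }
    paste0(substr(seq, 1L, k - 1L), paste(out, collapse = ""))
  })
}

# contiguous k-mer count vector (used by tests and the shuffle invariant)
kmer_counts <- function(seq, k = 3L) {
  n <- nchar(seq)
  if (n < k) return(table(character()))
  table(vapply(seq_len(n - k + 1L), function(i) substr(seq, i, i + k - 1L),
               character(1)))
}

#' Motif enrichment against background sequence sets
#'
#' For the target set and each background, the fraction of sequences carrying
#' at least one hit (either strand); fold enrichment is target fraction over
#' background fraction (NA when the background fraction is 0).
#'
#' @param pattern IUPAC motif
#' @param targets named character vector of target sequences
#' @param backgrounds named list of background sequence sets
#' @return data.frame set, n, fraction, fold
#' @export
background_enrichment <- function(pattern, targets, backgrounds) {
  if (any(lengths(backgrounds) == 0L)) {
    ck_stop("empty background set", class = "chromakin_validation_error")
  }
  frac <- function(seqs) {
    hits <- iupac_scan(seqs, pattern)
    length(unique(hits$sequence_id)) / length(seqs)
  }
  tf <- frac(targets)
  rows <- lapply(names(backgrounds), function(nm) {
    bf <- frac(backgrounds[[nm]])
    data.frame(set = nm, n = length(backgrounds[[nm]]), fraction = bf,
               fold = if (bf > 0) tf / bf else NA_real_,
               stringsAsFactors = FALSE)
  })
  rbind(data.frame(set = "target", n = length(targets), fraction = tf,
                   fold = 1, stringsAsFactors = FALSE),
        do.call(rbind, rows))
}

#' Motif presence in a central window around each summit
#'
#' @param seqs named summit sequences (summit at the centre)
#' @param pattern IUPAC motif
#' @param window total window width (bp; 100 published for FOXH1)
#' @return named logical vector, one per sequence
#' @export
motif_window_presence <- function(seqs, pattern, window = 100) {
  hits <- iupac_scan(seqs, pattern)
  half <- window / 2
  # hit must lie fully inside the window
  inwin <- hits[hits$offset >= -half &
                  hits$offset + nchar(hits$matched) <= half, , drop = FALSE]
  stats::setNames(names(seqs) %in% inwin$sequence_id, names(seqs))
}

#' Chi-square test on a 2x2 contingency table
#'
#' Plain `sum((O - E)^2 / E)` with expectations from the margins, df = 1, and
#' no continuity correction by default (configurable); a warning is issued
#' when any expected cell is below 1.
#'
#' @param tab 2x2 count matrix (group x motif presence)
#' @param correct apply the Yates continuity correction
#' @return list: statistic, pvalue, expected
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  stopifnot(all(dim(tab) == c(2L, 2L)))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E < 1)) ck_log("warning", "expected cell count < 1")
  d <- abs(tab - E)
  if (correct) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / E)
  list(statistic = stat, pvalue = pchisq(stat, df = 1L, lower.tail = FALSE),
       expected = E)
}

#' Read a motif pattern file (name, IUPAC string per line)
#' @param path TSV with columns name, iupac
#' @return named character vector of patterns
#' @export
read_motifs <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE, header = TRUE)
  pats <- stats::setNames(toupper(x$iupac), x$name)
  vapply(pats, check_iupac, character(1))
}

#' Read/write FASTA as a named character vector
#' @param path FASTA file
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}
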
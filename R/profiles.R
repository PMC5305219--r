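# Strand-aware metaprofiles around anchors (peak summits, TSS, TTS) and
# browser-track export.
#
# Convention: these signal-level functions apply `factor` multiplicatively;
# to normalize with a size-factor-like value f (from normalization_factors()),
# pass factor = 1/f.

#' Pool two replicate coverage tracks by read addition
#' @param a,b `cov_track` objects over the same chromosomes
#' @return pooled `cov_track`
#' @export
pool_tracks <- function(a, b) {
  stopifnot(identical(names(a$cov), names(b$cov)))
  cov <- mapply(`+`, a$cov, b$cov, SIMPLIFY = FALSE)
  structure(list(cov = cov, chrom_lengths = a$chrom_lengths,
                 n_fragments = a$n_fragments + b$n_fragments,
                 sample_id = paste(a$sample_id, b$sample_id, sep = "+")),
            class = "cov_track")
}

# Savitzky-Golay smoothing (local polynomial least squares) with reflected
# edges; the window shrinks to the (odd) series length when necessary.
savgol <- function(y, window = 151L, order = 3L) {
  n <- length(y)
  if (window > n) window <- if (n %% 2L == 1L) n else n - 1L
  if (window < order + 2L) return(y)
  if (window %% 2L == 0L) window <- window - 1L
  h <- (window - 1L) %/% 2L
  x <- seq(-h, h)
  A <- outer(x, 0:order, `^`)
  w <- solve(crossprod(A), t(A))[1L, ]
  ypad <- c(rev(y[2:(h + 1L)]), y, rev(y[(n - h):(n - 1L)]))
  out <- as.numeric(stats::filter(ypad, rev(w), sides = 2L))
  out[(h + 1L):(h + n)]
}

#' Metaprofile of coverage around anchored, oriented windows
#'
#' Per-position depth is extracted in a +/- `window` span around each anchor,
#' reversed for minus-strand anchors so every profile runs 5' to 3', averaged
#' across anchors, multiplied by `factor`, and smoothed with a Savitzky-Golay
#' local-polynomial filter (151 bp, order 3 by default). Anchors whose window
#' would be clipped by a chromosome end are dropped with a warning.
#'
#' @param track `cov_track` (replicates pooled beforehand via [pool_tracks()])
#' @param anchors data.frame(chrom, pos, strand); pos is 0-based
#' @param window half-window in bp
#' @param factor multiplicative normalization
#' @param smooth apply the smoother
#' @param sg_window,sg_order smoother parameters
#' @return object of class `metaprofile`: values (length 2*window+1, clamped
#'   at 0 after smoothing), raw (unsmoothed), offsets, n_loci
#' @export
metaprofile <- function(track, anchors, window = 2500, factor = 1,
                        smooth = TRUE, sg_window = 151L, sg_order = 3L) {
  ok <- vapply(seq_len(nrow(anchors)), function(i) {
    chr <- anchors$chrom[i]
    chr %in% names(track$cov) &&
      anchors$pos[i] - window >= 0 &&
      anchors$pos[i] + window < track$chrom_lengths[[chr]]
  }, logical(1))
  if (any(!ok)) {
    ck_log("warning", sum(!ok), " anchor(s) clipped by chromosome ends, dropped")
  }
  anchors <- anchors[ok, , drop = FALSE]
  if (nrow(anchors) == 0L) ck_stop("empty anchor set",
                                   class = "chromakin_validation_error")
  strands <- effective_strand(anchors$strand %||% "+", warn = FALSE)
  acc <- numeric(2L * window + 1L)
  for (chr in unique(anchors$chrom)) {
    v <- as.numeric(track$cov[[chr]])
    idx <- which(anchors$chrom == chr)
    for (i in idx) {
      w <- v[(anchors$pos[i] - window + 1L):(anchors$pos[i] + window + 1L)]
      if (strands[i] == "-") w <- rev(w)
      acc <- acc + w
    }
  }
  raw <- acc / nrow(anchors) * factor
  values <- if (smooth) pmax(savgol(raw, sg_window, sg_order), 0) else raw
  structure(list(values = values, raw = raw,
                 offsets = seq(-window, window), window = window,
                 n_loci = nrow(anchors),
                 smoothing = list(method = if (smooth) "savitzky-golay" else "none",
                                  window = sg_window, order = sg_order)),
            class = "metaprofile")
}

#' @export
print.metaprofile <- function(x, ...) {
  cat(sprintf("metaprofile: +/-%d bp over %d loci (peak %.3g at offset %d)\n",
              x$window, x$n_loci, max(x$values),
              x$offsets[which.max(x$values)]))
  invisible(x)
}

#' Export a browser track from read positions
#'
#' Read 5' positions are extended 100 bp toward their 3' end (each read covers
#' 101 bases), piled up, smoothed with a running mean over `smooth`-bp
#' windows, scaled by `factor` and written as bedGraph.
#'
#' @param reads data.frame(chrom, pos, strand), 0-based 5' positions
#' @param chrom_lengths named chromosome lengths
#' @param path output bedGraph (NULL to skip writing)
#' @param extension 3'-ward extension in bp
#' @param smooth running-mean window in bp (0 disables)
#' @param factor multiplicative scaling
#' @return the exported `cov_track`, invisibly
#' @export
export_track <- function(reads, chrom_lengths, path = NULL, extension = 100,
                         smooth = 10, factor = 1) {
  st <- effective_strand(reads$strand %||% "+", warn = FALSE)
  start <- ifelse(st == "+", reads$pos, reads$pos - extension)
  end <- ifelse(st == "+", reads$pos + extension + 1, reads$pos + 1)
  frags <- data.frame(chrom = reads$chrom, start = start, end = end)
  track <- cov_from_fragments(frags, chrom_lengths, sample_id = "export")
  track$cov <- lapply(track$cov, function(r) {
    v <- as.numeric(r) * factor
    if (smooth > 1) {
      v <- as.numeric(stats::filter(v, rep(1 / smooth, smooth), sides = 2L))
      v[is.na(v)] <- 0
    }
    S4Vectors::Rle(v)
  })
  if (!is.null(path)) write_coverage(track, path)
  invisible(track)
}
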
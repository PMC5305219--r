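# Genomic coordinate substrate and standard-format I/O.
#
# All coordinates are 0-based, half-open (BED convention) internally; GTF input
# is converted on read. Strand "." is treated as "+" by orientation-sensitive
# operations, with a warning.

#' Experimental-design constants
#'
#' The four treatment conditions and the assay vocabulary used throughout the
#' pipeline: signal inhibition (SB-431542), acute (1 hr) and sustained (8 hr)
#' Activin stimulation, and chronic autocrine signalling (Untreated).
#'
#' @export
ck_conditions <- c("SB", "Activin1h", "Activin8h", "Untreated")

#' @rdname ck_conditions
#' @export
ck_assays <- c("RNA", "SMAD2", "PolII-Ser5P", "PolII-Ser2P",
               "H3K9Ac", "H3K27Ac", "H3", "input")

#' Construct a table of genomic intervals
#'
#' @param chrom chromosome identifiers
#' @param start 0-based inclusive start positions
#' @param end exclusive end positions
#' @param strand "+", "-" or "." (recycled)
#' @return a `data.frame` with columns chrom, start, end, strand
#' @export
gi <- function(chrom, start, end, strand = ".") {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  strand = rep_len(as.character(strand), length(chrom)),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x, where = "interval") {
  bad <- which(x$start < 0 | x$end <= x$start | is.na(x$start) | is.na(x$end))
  if (length(bad)) {
    ck_stop("%s record %d violates invariants (start >= 0, end > start): [%s,%s)",
            where, bad[1L], format(x$start[bad[1L]]), format(x$end[bad[1L]]),
            class = "chromakin_validation_error")
  }
  badstr <- which(!x$strand %in% c("+", "-", "."))
  if (length(badstr)) {
    ck_stop("%s record %d has invalid strand '%s'", where, badstr[1L],
            x$strand[badstr[1L]], class = "chromakin_validation_error")
  }
  invisible(x)
}

# 0-based half-open -> IRanges (1-based closed)
as_ir <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

effective_strand <- function(strand, warn = TRUE) {
  dot <- strand == "."
  if (any(dot) && warn) {
    ck_log("warning", sum(dot), " interval(s) with strand '.' treated as '+'")
  }
  ifelse(dot, "+", strand)
}

#' Distance between two genomic intervals
#'
#' Zero when the intervals share at least one base *or* touch end-to-start
#' (half-open adjacency has a zero-base gap but no shared base; such intervals
#' are at distance 0 yet are not merged by consensus-peak construction, which
#' requires a shared nucleotide). Otherwise the number of bases strictly
#' between the nearest ends.
#'
#' @param a,b single-row interval tables (see [gi()])
#' @return non-negative integer gap in bases
#' @export
interval_distance <- function(a, b) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  if (a$chrom != b$chrom) {
    ck_stop("undefined distance: intervals on different chromosomes (%s vs %s)",
            a$chrom, b$chrom, class = "chromakin_chrom_error")
  }
  max(0, max(a$start, b$start) - min(a$end, b$end))
}

## ---- narrowPeak-like peaks ----

#' Read MACS-style peaks (narrowPeak-like BED6+4)
#'
#' Columns: chrom, start, end, name, score, strand, signalValue (MACS fold
#' enrichment), pValue, qValue, summit offset from start. Unlike MACS output
#' the p/q columns hold plain probabilities (not -log10) so that write/read
#' round-trips are lossless.
#'
#' @param path narrowPeak-like file
#' @param condition optional condition label attached to every record
#' @return data.frame of peaks with an absolute `summit` column
#' @export
read_peaks <- function(path, condition = NA_character_) {
  x <- read_tsv_checked(path, 10L, "narrowPeak")
  names(x) <- c("chrom", "start", "end", "name", "score", "strand",
                "fold_enrichment", "pvalue", "qvalue", "summit_offset")
  validate_intervals(x, where = basename(path))
  bad <- which(x$summit_offset < 0 | x$summit_offset >= x$end - x$start)
  if (length(bad)) {
    ck_stop("%s record %d: summit offset outside peak", basename(path), bad[1L],
            class = "chromakin_validation_error")
  }
  if (any(x$fold_enrichment <= 0)) {
    ck_stop("%s: fold_enrichment must be > 0", basename(path),
            class = "chromakin_validation_error")
  }
  x$summit <- x$start + x$summit_offset
  x$summit_offset <- NULL
  x$condition <- condition
  x
}

#' @rdname read_peaks
#' @param peaks peak table as returned by [read_peaks()]
#' @export
write_peaks <- function(peaks, path) {
  out <- data.table::data.table(
    chrom = peaks$chrom, start = as.integer(peaks$start),
    end = as.integer(peaks$end),
    name = peaks$name %||% sprintf("peak_%d", seq_len(nrow(peaks))),
    score = peaks$score %||% 0L, strand = peaks$strand %||% ".",
    fold_enrichment = peaks$fold_enrichment, pvalue = peaks$pvalue %||% -1,
    qvalue = peaks$qvalue, summit_offset = as.integer(peaks$summit - peaks$start))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, ncol, what) {
  if (!file.exists(path)) ck_stop("missing %s file: %s", what, path)
  x <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE),
    error = function(e) ck_stop("malformed %s file %s: %s", what, path,
                                conditionMessage(e),
                                class = "chromakin_parse_error"))
  if (ncol(x) != ncol) {
    ck_stop("%s: expected %d columns, found %d", basename(path), ncol, ncol(x),
            class = "chromakin_parse_error")
  }
  x
}

## ---- BED6 ----

#' Read/write plain BED6 interval files (repeats, anchors)
#' @param path BED file
#' @return interval data.frame with name and score columns
#' @export
read_bed <- function(path) {
  x <- read_tsv_checked(path, 6L, "BED6")
  names(x) <- c("chrom", "start", "end", "name", "score", "strand")
  validate_intervals(x, where = basename(path))
  x
}

#' @rdname read_bed
#' @param bed interval table
#' @export
write_bed <- function(bed, path) {
  out <- data.table::data.table(
    chrom = bed$chrom, start = as.integer(bed$start), end = as.integer(bed$end),
    name = bed$name %||% ".", score = bed$score %||% 0L,
    strand = bed$strand %||% ".")
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- gene models (GTF) ----

#' Read gene models from a GTF (genes/exons only)
#'
#' GTF 1-based closed coordinates are converted to 0-based half-open. The TSS
#' is the first transcribed base (start for "+", end-1 for "-"); the TTS the
#' last. `exon_kb` is the total exonic length in kilobases.
#'
#' @param path GTF file with exon features carrying gene_id attributes
#' @return data.frame (gene_id, chrom, start, end, strand, tss, tts, exon_kb)
#'   with the per-gene exon table in `attr(, "exons")`
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0L) ck_stop("%s: no exon features", path,
                                class = "chromakin_parse_error")
  exons <- data.frame(gene_id = as.character(ex$gene_id),
                      chrom = as.character(GenomicRanges::seqnames(ex)),
                      start = GenomicRanges::start(ex) - 1,
                      end = as.numeric(GenomicRanges::end(ex)),
                      strand = as.character(GenomicRanges::strand(ex)),
                      stringsAsFactors = FALSE)
  exons$strand[exons$strand == "*"] <- "."
  validate_intervals(exons, where = basename(path))
  gene_models_from_exons(exons)
}

gene_models_from_exons <- function(exons) {
  exons <- exons[order(exons$gene_id, exons$start), ]
  sp <- split(exons, exons$gene_id)
  rows <- lapply(sp, function(e) {
    if (length(unique(e$chrom)) != 1L || length(unique(e$strand)) != 1L) {
      ck_stop("gene %s: exons span chromosomes/strands", e$gene_id[1L],
              class = "chromakin_validation_error")
    }
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      ck_stop("gene %s: overlapping exons", e$gene_id[1L],
              class = "chromakin_validation_error")
    }
    st <- effective_strand(e$strand[1L], warn = FALSE)
    gstart <- min(e$start); gend <- max(e$end)
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               start = gstart, end = gend, strand = e$strand[1L],
               tss = if (st == "+") gstart else gend - 1,
               tts = if (st == "+") gend - 1 else gstart,
               exon_kb = sum(e$end - e$start) / 1000,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  genes <- genes[order(genes$gene_id), ]
  attr(genes, "exons") <- exons[, c("gene_id", "chrom", "start", "end", "strand")]
  genes
}

#' @rdname read_gene_models
#' @param genes gene-model table with exon attribute
#' @export
write_gene_models <- function(genes, path) {
  exons <- attr(genes, "exons")
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = as_ir(exons$start, exons$end),
    strand = ifelse(exons$strand == ".", "*", exons$strand))
  gr$type <- "exon"
  gr$source <- "chromakin"
  gr$gene_id <- exons$gene_id
  gr$transcript_id <- paste0(exons$gene_id, ".t1")
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

## ---- coverage tracks (bedGraph <-> Rle) ----

#' Build a coverage track from sequenced fragments
#'
#' A coverage track stores per-base read depth as one run-length-encoded
#' vector per chromosome, plus the number of contributing fragments (the
#' "total mapped reads" used by depth normalization).
#'
#' @param frags data.frame(chrom, start, end) of fragment intervals
#' @param chrom_lengths named vector of chromosome lengths
#' @param sample_id label carried in the track
#' @return object of class `cov_track`
#' @export
cov_from_fragments <- function(frags, chrom_lengths, sample_id = NA_character_) {
  cov <- lapply(names(chrom_lengths), function(chr) {
    f <- frags[frags$chrom == chr, , drop = FALSE]
    if (nrow(f) == 0L) return(S4Vectors::Rle(0L, chrom_lengths[[chr]]))
    s <- pmax(f$start, 0); e <- pmin(f$end, chrom_lengths[[chr]])
    keep <- e > s
    IRanges::coverage(as_ir(s[keep], e[keep]), width = chrom_lengths[[chr]])
  })
  names(cov) <- names(chrom_lengths)
  structure(list(cov = cov, chrom_lengths = chrom_lengths,
                 n_fragments = nrow(frags), sample_id = sample_id),
            class = "cov_track")
}

#' @export
print.cov_track <- function(x, ...) {
  cat(sprintf("cov_track '%s': %d chromosome(s), %g fragments\n",
              x$sample_id, length(x$cov), x$n_fragments))
  invisible(x)
}

# depth over [start, end) (0-based half-open) as a plain numeric vector
cov_window <- function(track, chrom, start, end) {
  as.numeric(S4Vectors::window(track$cov[[chrom]], start + 1L, end))
}

# sum of depth over [start, end)
cov_sum <- function(track, chrom, start, end) {
  sum(S4Vectors::window(track$cov[[chrom]], start + 1L, end))
}

# vectorized depth sums over many regions via one per-chromosome cumsum
region_sums <- function(track, regions) {
  out <- numeric(nrow(regions))
  for (chr in unique(regions$chrom)) {
    idx <- which(regions$chrom == chr)
    if (!chr %in% names(track$cov)) next
    cs <- c(0, cumsum(as.numeric(track$cov[[chr]])))
    len <- length(cs) - 1L
    s <- pmax(regions$start[idx], 0)
    e <- pmin(regions$end[idx], len)
    out[idx] <- cs[e + 1L] - cs[s + 1L]
  }
  out
}

#' Read a bedGraph file into a coverage track
#'
#' Records must be non-overlapping within a chromosome; overlapping records
#' are a validation error (per-base depth would be ambiguous).
#'
#' @param path bedGraph file
#' @param chrom_lengths optional named lengths; defaults to the maximum end
#'   seen per chromosome
#' @param n_fragments total mapped fragments, if known
#' @inheritParams cov_from_fragments
#' @export
read_coverage <- function(path, chrom_lengths = NULL,
                          sample_id = NA_character_, n_fragments = NA_real_) {
  x <- read_tsv_checked(path, 4L, "bedGraph")
  names(x) <- c("chrom", "start", "end", "value")
  x$strand <- "."
  validate_intervals(x, where = basename(path))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(x$end, x$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  }
  cov <- lapply(names(chrom_lengths), function(chr) {
    f <- x[x$chrom == chr, , drop = FALSE]
    len <- chrom_lengths[[chr]]
    if (nrow(f) == 0L) return(S4Vectors::Rle(0, len))
    f <- f[order(f$start), ]
    if (nrow(f) > 1L && any(f$start[-1L] < f$end[-nrow(f)])) {
      i <- which(f$start[-1L] < f$end[-nrow(f)])[1L]
      ck_stop("%s: overlapping bedGraph records on %s near position %d",
              basename(path), chr, as.integer(f$start[i + 1L]),
              class = "chromakin_validation_error")
    }
    v <- numeric(len)
    for (i in seq_len(nrow(f))) v[(f$start[i] + 1):f$end[i]] <- f$value[i]
    S4Vectors::Rle(v)
  })
  names(cov) <- names(chrom_lengths)
  structure(list(cov = cov, chrom_lengths = chrom_lengths,
                 n_fragments = n_fragments, sample_id = sample_id),
            class = "cov_track")
}

#' @rdname read_coverage
#' @param track `cov_track` object
#' @export
write_coverage <- function(track, path) {
  parts <- lapply(names(track$cov), function(chr) {
    r <- track$cov[[chr]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    data.table::data.table(chrom = chr, start = starts[keep], end = ends[keep],
                           value = vals[keep])
  })
  out <- data.table::rbindlist(parts)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- count matrices & sample sheets ----

#' Read a gene-by-sample count matrix (TSV; first column gene_id)
#' @param path TSV file
#' @return numeric matrix, rownames = gene ids
#' @export
read_counts <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (ncol(x) < 2L) ck_stop("%s: count matrix needs >= 2 columns", path,
                            class = "chromakin_parse_error")
  m <- as.matrix(x[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(m < 0)) {
    ck_stop("%s: counts must be non-negative numbers", basename(path),
            class = "chromakin_validation_error")
  }
  rownames(m) <- as.character(x[[1L]])
  m
}

#' @rdname read_counts
#' @param counts numeric matrix with gene rownames
#' @export
write_counts <- function(counts, path) {
  out <- data.table::data.table(gene_id = rownames(counts))
  out <- cbind(out, data.table::as.data.table(counts))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read/validate a sample sheet
#'
#' Required columns: sample_id, assay, condition, replicate; the
#' (assay, condition, replicate) triple must be unique.
#' @param path TSV file
#' @export
read_sample_sheet <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  validate_sample_sheet(x)
}

validate_sample_sheet <- function(x) {
  need <- c("sample_id", "assay", "condition", "replicate")
  if (!all(need %in% names(x))) {
    ck_stop("sample sheet missing columns: %s",
            paste(setdiff(need, names(x)), collapse = ", "),
            class = "chromakin_validation_error")
  }
  if (!all(x$assay %in% ck_assays)) {
    ck_stop("unknown assay: %s",
            paste(setdiff(x$assay, ck_assays), collapse = ", "),
            class = "chromakin_validation_error")
  }
  if (!all(x$condition %in% ck_conditions)) {
    ck_stop("unknown condition: %s",
            paste(setdiff(x$condition, ck_conditions), collapse = ", "),
            class = "chromakin_validation_error")
  }
  key <- paste(x$assay, x$condition, x$replicate)
  if (anyDuplicated(key)) {
    ck_stop("duplicate (assay, condition, replicate): %s", key[duplicated(key)][1L],
            class = "chromakin_validation_error")
  }
  x
}

#' @rdname read_sample_sheet
#' @param sheet sample-sheet data.frame
#' @export
write_sample_sheet <- function(sheet, path) {
  data.table::fwrite(sheet, path, sep = "\t", quote = FALSE)
  invisible(path)
}
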
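# Rule-based kinetic classification of regulated genes and one-phase mRNA
# decay fitting. All log2 fold changes are relative to the SB-431542
# (signal-inhibited) baseline.

ck_categories <- c("induced_sustained", "transient_induced", "delayed",
                   "repressed", "unclassified")

#' Classify the temporal expression pattern of a regulated gene
#'
#' The four published rules, applied in their printed precedence order (first
#' match wins; ties on the rule boundaries are therefore deterministic):
#'
#' * induced sustained: `l1h >= 0.7`, `l8h > l1h`, `luntr >= 0`
#' * transient induced: `l1h >= 0.7`, `0 <= l8h < l1h`, `-0.7 <= luntr <= 0.7`
#' * delayed: `l1h <= 0.7`, `l8h >= 0.7`, `luntr > 0`
#' * repressed: `l8h <= -0.7`, `luntr <= 0`
#'
#' The repressed threshold is printed as `<= 0.7`; that sign is treated as a
#' typo (a repressed gene must pass the |log2FC| >= 0.7 filter downward) and
#' the literal rule is available with `repressed_literal = TRUE`.
#'
#' @param l1h,l8h,luntr log2FC of 1 hr Activin, 8 hr Activin and Untreated vs
#'   SB-431542 (vectorized)
#' @param repressed_literal use the printed `l8h <= 0.7` repressed threshold
#' @return character vector of categories (see `ck_categories`)
#' @export
classify_kinetics <- function(l1h, l8h, luntr, repressed_literal = FALSE) {
  if (any(!is.finite(c(l1h, l8h, luntr)))) {
    ck_stop("non-finite log2FC input", class = "chromakin_validation_error")
  }
  rp_thr <- if (repressed_literal) 0.7 else -0.7
  is_ <- l1h >= 0.7 & l8h > l1h & luntr >= 0
  ti_ <- l1h >= 0.7 & l8h < l1h & l8h >= 0 & luntr <= 0.7 & luntr >= -0.7
  dl_ <- l1h <= 0.7 & l8h >= 0.7 & luntr > 0
  rp_ <- l8h <= rp_thr & luntr <= 0
  out <- rep("unclassified", length(l1h))
  out[rp_] <- "repressed"
  out[dl_] <- "delayed"
  out[ti_] <- "transient_induced"
  out[is_] <- "induced_sustained"  # assigned last = highest precedence
  out
}

#' Baseline transcriptional state
#'
#' "Baseline off" means fewer than 30 raw reads in the SB-431542 sample(s):
#' the gene is transcriptionally silent before stimulation.
#'
#' @param sb_reads raw read counts in the SB condition (vectorized)
#' @param min_reads the published floor (30)
#' @return "on"/"off" character vector
#' @export
classify_baseline <- function(sb_reads, min_reads = 30) {
  stopifnot(all(sb_reads >= 0))
  ifelse(sb_reads < min_reads, "off", "on")
}

#' Direct vs indirect target classification
#'
#' Uses translation-inhibitor (cycloheximide and emetine) time courses. A gene
#' is *indirect* when, in **both** inhibitors:
#' * induced sustained / delayed: the 8 hr log2FC does not reach > 0.5;
#' * repressed: the 8 hr log2FC does not reach < -0.5;
#' * transient induced: the inhibitor-treated 8 hr log2FC exceeds the 1 hr one
#'   (the transient down-phase requires new protein synthesis).
#'
#' @param category kinetic category (one gene)
#' @param l8h_chx,l8h_eme inhibitor-treated 8 hr log2FC
#' @param l1h_chx,l1h_eme inhibitor-treated 1 hr log2FC (transient rule only)
#' @return "direct", "indirect", or "not_applicable" when inhibitor data are
#'   missing
#' @export
classify_directness <- function(category, l8h_chx, l8h_eme,
                                l1h_chx = NA_real_, l1h_eme = NA_real_) {
  if (!category %in% setdiff(ck_categories, "unclassified")) {
    return("not_applicable")
  }
  need <- if (category == "transient_induced") {
    c(l8h_chx, l8h_eme, l1h_chx, l1h_eme)
  } else {
    c(l8h_chx, l8h_eme)
  }
  if (any(is.na(need))) return("not_applicable")
  indirect <- switch(category,
    induced_sustained = ,
    delayed = l8h_chx <= 0.5 && l8h_eme <= 0.5,
    repressed = l8h_chx >= -0.5 && l8h_eme >= -0.5,
    transient_induced = l8h_chx > l1h_chx && l8h_eme > l1h_eme)
  if (indirect) "indirect" else "direct"
}

#' Kinetic calls for a regulated-gene table
#'
#' Convenience wrapper combining [classify_kinetics()], [classify_baseline()]
#' and (when an inhibitor table is supplied) [classify_directness()].
#'
#' @param de filtered DE table from [apply_target_filters()] (regulated genes)
#' @param counts raw counts (for SB baseline reads)
#' @param sample_sheet sample sheet
#' @param inhibitor optional data.frame(gene_id, l1h_chx, l8h_chx, l1h_eme,
#'   l8h_eme)
#' @return data.frame gene_id, category, baseline, directness
#' @export
kinetic_calls <- function(de, counts, sample_sheet, inhibitor = NULL) {
  reg <- de[de$passes_filters, , drop = FALSE]
  cat_ <- classify_kinetics(reg$log2fc_Activin1h, reg$log2fc_Activin8h,
                            reg$log2fc_Untreated)
  ss <- sample_sheet[sample_sheet$assay == "RNA" &
                       sample_sheet$condition == "SB", , drop = FALSE]
  sb_reads <- rowSums(counts[reg$gene_id, ss$sample_id, drop = FALSE])
  base_ <- classify_baseline(sb_reads)
  dir_ <- rep("not_applicable", nrow(reg))
  if (!is.null(inhibitor)) {
    m <- match(reg$gene_id, inhibitor$gene_id)
    dir_ <- vapply(seq_len(nrow(reg)), function(i) {
      if (is.na(m[i])) return("not_applicable")
      ih <- inhibitor[m[i], ]
      classify_directness(cat_[i], ih$l8h_chx, ih$l8h_eme, ih$l1h_chx,
                          ih$l1h_eme)
    }, character(1))
  }
  data.frame(gene_id = reg$gene_id, category = cat_, baseline = base_,
             directness = dir_, sb_reads = sb_reads, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fit a one-phase exponential decay
#'
#' Least-squares fit of `y = (y0 - plateau) * exp(-k * t) + plateau` (the
#' "one phase decay" model of Prism), used for mRNA half-life estimation after
#' transcriptional shut-off. Initialized from a log-linear regression of
#' `y - min(y)`; `k` is bounded to (1e-6, 1e3) per hour.
#'
#' @param t time in hours (t[1] must be 0)
#' @param y expression values
#' @return list of class `decay_fit`: y0, plateau, k (1/hr),
#'   half_life (= ln 2 / k, hr), rss
#' @export
fit_one_phase_decay <- function(t, y) {
  if (length(t) < 4L || t[1L] != 0) {
    ck_stop("need >= 4 points with t[1] = 0", class = "chromakin_fit_error")
  }
  if (sd(y) == 0) {
    ck_stop("constant series: decay rate unidentifiable",
            class = "chromakin_fit_error")
  }
  resid_fn <- function(par) {
    yhat <- (par[1L] - par[2L]) * exp(-par[3L] * t) + par[2L]
    sum((y - yhat)^2)
  }
  # log-linear initial guess for k from the decay toward the minimum
  ypos <- y - min(y)
  ok <- ypos > 0
  k0 <- if (sum(ok) >= 2L) {
    max(1e-3, -coef(lm(log(ypos[ok]) ~ t[ok]))[[2L]])
  } else 0.5
  inits <- list(c(y0 = y[1L], plateau = min(y), k = min(max(k0, 1e-3), 100)),
                c(y0 = y[1L], plateau = 0, k = 0.1),
                c(y0 = max(y), plateau = min(y), k = 1))
  fit <- NULL
  for (init in inits) {
    cand <- tryCatch(
      optim(init, resid_fn, method = "L-BFGS-B",
            lower = c(-Inf, -Inf, 1e-6), upper = c(Inf, Inf, 1e3),
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(cand) && cand$convergence == 0 &&
        (is.null(fit) || cand$value < fit$value)) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    ck_stop("decay fit did not converge from any start",
            class = "chromakin_fit_error")
  }
  k <- unname(fit$par[3L])
  if (k <= 1e-6 || k >= 1e3) {
    ck_stop("decay rate at bound (k = %g /hr): unidentifiable", k,
            class = "chromakin_fit_error")
  }
  structure(list(y0 = unname(fit$par[1L]), plateau = unname(fit$par[2L]),
                 k = k, half_life = log(2) / k, rss = fit$value),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("one-phase decay: k = %.4g /hr, half-life = %.4g hr (rss %.3g)\n",
              x$k, x$half_life, x$rss))
  invisible(x)
}
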
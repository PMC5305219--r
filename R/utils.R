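# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

geomean <- function(x) exp(mean(log(x)))

#' @importFrom stats median quantile p.adjust pnorm pchisq rnbinom runif rnorm
#'   rbinom rpois sd var cor t.test qt hclust cutree dist optim coef lm
#' @importFrom utils head tail
NULL

ck_log_levels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

#' Set or query the pipeline log level
#'
#' @param level one of "debug", "info", "warning", "error"
#' @return the active level, invisibly
#' @export
ck_log_level <- function(level = NULL) {
  if (!is.null(level)) {
    level <- match.arg(level, names(ck_log_levels))
    options(chromakin.log_level = level)
  }
  invisible(getOption("chromakin.log_level", "info"))
}

ck_log <- function(level, ...) {
  active <- ck_log_levels[[getOption("chromakin.log_level", "info")]]
  if (ck_log_levels[[level]] >= active) {
    message(sprintf("[chromakin %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

ck_stop <- function(fmt, ..., class = "chromakin_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

# deterministic child seed derived from a master seed; kept below 2^31
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
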
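# Internal helpers shared across modules.

logistic <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All stochastic stages take an explicit integer seed. Pipeline-level runs
#' derive one seed per stage from a single master seed so that stage-level
#' reruns reproduce pipeline-level results. Kept strictly below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param k stage index (non-negative integer).
#' @return an integer seed.
#' @export
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629L)
}

# Column quantile at prob `p` (type-7 linear interpolation) over the non-NA
# entries of each column; NA when fewer than `min_n` draws are available.
col_quantile <- function(m, p, min_n = 1L) {
  apply(m, 2L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < min_n) return(NA_real_)
    stats::quantile(x, probs = p, names = FALSE, type = 7)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
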
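#' @keywords internal
"_PACKAGE"

#' @importFrom stats ks.test kmeans median predict rnorm runif rbinom rlnorm sd quantile setNames
#' @importFrom utils read.csv write.csv head
#' @importFrom graphics barplot boxplot
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and an index
#'
#' Repeats, tuning splits and subsampling trials each draw from their own
#' stream so that, e.g., adding AUC computation to a run does not perturb the
#' resampling. Kept below 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param seed master integer seed
#' @param index stream index (repeat number, trial number, ...)
#' @return an integer seed
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 1000003) * 2099 + (index %% 1000) * 7919 + index) %% 2147483629L
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))

# string hash used for fingerprint folding: polynomial rolling hash mod a
# Mersenne prime with a final multiplicative mix so that low-order bits
# disperse well under power-of-two folding; exact in double arithmetic
# (intermediate values stay < 2^53)
hash_string <- function(s) {
  p <- 2147483647
  vapply(s, function(si) {
    h <- 0
    for (b in utf8ToInt(si)) h <- (h * 131 + b) %% p
    (((h * 48271) %% p) * 69621) %% p
  }, numeric(1), USE.NAMES = FALSE)
}
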
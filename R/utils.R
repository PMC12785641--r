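#' @keywords internal
"_PACKAGE"

# Internal validation helpers ------------------------------------------------

stop_domain <- function(...) {
  stop(structure(
    class = c("xtalgen_domain_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_config <- function(...) {
  stop(structure(
    class = c("xtalgen_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_config(name, " must be a single number")
  if (finite && !is.finite(x)) stop_config(name, " must be finite")
  if (positive && x <= 0) stop_config(name, " must be > 0")
  invisible(x)
}

#' Derive the per-structure seed from a root seed and a structure index
#'
#' Structure `k` of a batch must be reproducible independently of the batch
#' size, so every structure gets its own substream seed computed by an
#' integer hash (SplitMix-style multiply/xor mix) of `(root_seed, k)`.
#' The result is kept in `[0, 2^31 - 1)` so it is always a valid input to
#' [set.seed()].
#'
#' @param root_seed Integer root seed of the run.
#' @param index Structure index (0-based or 1-based, any non-negative int).
#' @return A single integer seed.
#' @export
#' @examples
#' structure_seed(42, 1)
structure_seed <- function(root_seed, index) {
  check_number(root_seed, "root_seed")
  check_number(index, "index")
  # 64-bit-free mixing: work modulo 2^31 - 1 with doubles (exact below 2^53)
  m <- 2147483647
  z <- (as.numeric(root_seed) %% m) + 1
  k <- (as.numeric(index) %% m) + 1
  z <- (z * 48271) %% m
  z <- (z + k * 69621) %% m
  z <- (z * 16807 + 12345) %% m
  z <- (z * 48271 + k) %% m
  as.integer(z)
}

# Wrap fractional coordinates into [0, 1)
wrap_frac <- function(x) {
  y <- x - floor(x)
  # guard against 1 - eps rounding up to exactly 1
  y[y >= 1] <- 0
  y
}

# Empirical one-sample KS statistic against a vectorized cdf function
ks_stat_cdf <- function(sample, cdf) {
  x <- sort(sample)
  n <- length(x)
  f <- cdf(x)
  max(max(seq_len(n) / n - f), max(f - (seq_len(n) - 1) / n))
}

# Two-sample KS statistic
ks_stat_two <- function(a, b) {
  na <- length(a); nb <- length(b)
  all <- c(a, b)
  o <- order(all)
  z <- cumsum(ifelse(o <= na, 1 / na, -1 / nb))
  # handle ties: only evaluate at distinct values' last occurrence
  sorted <- all[o]
  keep <- c(diff(sorted) != 0, TRUE)
  max(abs(z[keep]))
}
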
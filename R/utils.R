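#' @keywords internal
#' @useDynLib vibrofirm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# condition helper: all package errors carry a subclass so callers/tests can
# distinguish domain errors from generic failures
vf_stop <- function(subclass, msg, call. = FALSE) {
  stop(structure(
    class = c(subclass, "vibrofirm_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

vf_check <- function(ok, subclass, msg) {
  if (!isTRUE(ok)) vf_stop(subclass, msg)
  invisible(TRUE)
}

# truncated normal via inverse-CDF; vectorised over n
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# largest-remainder apportionment of n into parts proportional to ratios;
# ties broken by earlier position
largest_remainder <- function(n, ratios) {
  q <- n * ratios / sum(ratios)
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    frac <- q - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# derive a child seed below 2^31 from a root seed and a stream label
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483587L) + 1L
}
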
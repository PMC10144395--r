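# Weighted moment helpers used across the index and decomposition code.
# All take raw (unnormalized) sampling weights.

wtd_mean <- function(x, w) sum(w * x) / sum(w)

# Population-style weighted covariance (divides by total weight, not n-1):
# the concentration-index literature's covariance.
wtd_cov <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sum(w * (x - mx) * (y - my)) / sw
}

wtd_var <- function(x, w) wtd_cov(x, x, w)

`%||%` <- rlang::`%||%`

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}
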
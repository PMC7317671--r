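# Internal numeric helpers shared across modules.

# Round half away from zero (so 0.5 -> 1, 2.5 -> 3, -0.5 -> -1).
# Stated explicitly because base round() uses banker's rounding and
# half-integer latent scores occur in noise-free simulations.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw from a normal truncated to [lo, hi] by rejection (vectorised).
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (all(sd == 0)) {
    return(clip(rep_len(mean, n), lo, hi))
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), rep_len(mean, n)[bad], rep_len(sd, n)[bad])
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}
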
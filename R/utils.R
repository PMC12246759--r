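## Shared constants and small helpers.

# Statement roles in the nine-item battery: items 1-5 are fake claims,
# items 6-9 are true statements.
FAKE_STATEMENTS <- 1:5
TRUE_STATEMENTS <- 6:9
N_STATEMENTS <- 9L

#' Derive a per-stage, per-unit RNG seed from one global seed
#'
#' Counter-based scheme: mixing a global seed with small stage/unit indices
#' yields independent-looking 31-bit streams, so adding towns or stages never
#' perturbs the draws of existing ones.
#'
#' @param seed Global integer seed.
#' @param ... One or more small non-negative integer indices (stage, town,
#'   replicate, ...).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, ...) {
  idx <- c(as.integer(seed), as.integer(c(...)))
  h <- 0
  for (k in idx) {
    # multiplier kept small enough that h * m + k stays exact in double
    # (p * m < 2^53) before reduction mod a prime p < 2^31
    h <- (h * 69069 + k + 1.0) %% 2147483629
  }
  as.integer(h)
}

# Clamp probabilities into [0, 1], returning the clamped vector with an
# attribute recording how many entries were out of range.
clamp01 <- function(p) {
  out <- pmin(pmax(p, 0), 1)
  attr(out, "n_clamped") <- sum(p < 0 | p > 1)
  out
}
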
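# Deterministic child-seed derivation. A fixed affine rule keeps every
# derived seed a positive 32-bit integer and makes any simulated object
# exactly reproducible from the master seed alone.

#' Derive a child seed from a master seed
#'
#' Fixed arithmetic rule `(master * 48271 + k) mod (2^31 - 1)` (the Lehmer
#' multiplier), so per-eye / per-trace streams are decorrelated but fully
#' determined by the master seed and an index.
#'
#' @param master Master seed (non-negative integer).
#' @param k Non-negative integer index of the child stream.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, k) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(k)
  as.integer(s %% m + 1)
}

# Run `expr` under `seed` if non-NULL/NA, restoring the caller's RNG state.
with_seed_if <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}
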
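#' Derive a child seed from a master seed and a label
#'
#' All randomness in the package flows from a single integer seed. Stages
#' that need independent random streams (per-subject profiles, per-recording
#' noise, per-repetition network initialisations, ...) derive a child seed
#' deterministically from the master seed and a string key, so that any
#' stage can be re-run in isolation and reproduce its draws exactly.
#'
#' The derivation is a small multiplicative hash over the key's bytes,
#' reduced modulo 2^31 - 1; it is not cryptographic, it only needs to be
#' deterministic and to decorrelate nearby seeds.
#'
#' @param seed integer master seed.
#' @param key character label identifying the consumer of the stream.
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' child_seed(42, "subject/3")
child_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key), length(key) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(key)) {
    # h <- (h * 31 + b) mod m, kept in double-precision-exact range
    h <- (h * 31 + b) %% m
  }
  h <- (h * 2654435761) %% m  # final avalanche (Knuth multiplicative)
  as.integer(h %% (m - 2L) + 1L)
}

# Run `code` under a temporary RNG state seeded from (seed, key); the
# caller's RNG state is untouched.
with_child_seed <- function(seed, key, code) {
  withr::with_seed(child_seed(seed, key), code)
}
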
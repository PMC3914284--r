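# Deterministic substream derivation. All stochastic operations in the
# package draw from substreams keyed by (root seed, integer tags) so that
# results do not depend on iteration order and each source of variation
# (fold assignment, imputation, forest growth) can be frozen independently.

#' Derive a substream seed from a root seed and integer tags
#'
#' Mixes a root seed with an arbitrary sequence of non-negative integer tags
#' into a single 32-bit seed. The mixing is a fixed-multiplier linear
#' congruential hash, exact in double precision, so identical inputs always
#' give identical seeds regardless of platform.
#'
#' @param seed integer root seed.
#' @param ... non-negative integer tags (e.g. repetition, feature index,
#'   class code). Character tags are hashed by their bytes.
#' @return a single integer seed in `[0, 2^31 - 21)`.
#' @export
#' @examples
#' mixSeed(1L, 3L, 7L)
mixSeed <- function(seed, ...) {
  tags <- list(...)
  h <- as.double(seed) %% 2147483563
  bump <- function(h, x) (h * 69069 + x + 10007) %% 2147483563
  for (tag in tags) {
    if (is.character(tag)) {
      for (b in utf8ToInt(paste(tag, collapse = "\r"))) h <- bump(h, b)
    } else {
      for (x in as.double(tag)) h <- bump(h, x %% 2147483563)
    }
  }
  as.integer(h)
}

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}
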
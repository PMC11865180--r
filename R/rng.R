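#' Derive a reproducible sub-stream seed
#'
#' One root seed drives named sub-streams (design, layout, response, ...) so
#' that, e.g., changing the observer model never perturbs the trial sequence.
#' The derivation is a small deterministic string hash folded with the root
#' seed, kept below 2^31 so it is always a valid R integer seed.
#'
#' @param seed Integer root seed.
#' @param stream Character label of the sub-stream.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(42, "design/P01")
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- 5381
  for (cc in utf8ToInt(stream)) h <- (h * 33 + cc) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 1000003 + h) %% 2147483647)
}

# Run code under a derived seed without disturbing the caller's RNG state.
with_stream <- function(seed, stream, code) {
  withr::with_seed(derive_seed(seed, stream), code)
}
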
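#' Derive a child seed from a root seed
#'
#' Deterministic hierarchical seed splitting: stages and indices mix into
#' the root with a Lehmer-style hash, so every line, generation and cross
#' gets an independent, reproducible stream regardless of evaluation
#' order. All arithmetic stays below 2^53, and results are valid 32-bit
#' seeds.
#'
#' @param root integer root seed.
#' @param ... integer indices identifying the stage (line number,
#'   generation, cross number, ...).
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(root, ...) {
  m <- 2147483647  # 2^31 - 1
  s <- as.numeric(root) %% m
  for (k in c(...)) {
    s <- (s * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(s + 1)
}
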
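#' Derive a named random substream seed from a master seed
#'
#' All randomness in the package flows from a single master seed. Each
#' stochastic stage (genome synthesis, methylation assignment, read
#' simulation per sample) draws its own seed from the master seed and a
#' stream label, so stages are reproducible independently of execution
#' order.
#'
#' @param seed Master integer seed.
#' @param stream Character label of the substream.
#' @return An integer in `[0, 2^31 - 1]` suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "genome")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # Knuth-style multiplicative mix, kept in double precision; values stay
  # below 2^31 so they are valid R integers.
  h <- (as.double(seed) %% 2147483647) + 1
  for (k in utf8ToInt(stream)) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside the ACGTN alphabet", what),
         call. = FALSE)
  }
  invisible(seq)
}
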
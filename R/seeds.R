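# Named random substreams: every generator derives its own 32-bit seed from
# one master seed plus a stream label, so any stage can be regenerated
# independently and reruns are byte-identical.

#' Derive a substream seed from a master seed and a stream label
#'
#' All stochastic functions in the package draw their randomness through a
#' named substream: the master seed and a short label (e.g.
#' `"residues:carbosulfan"`) are hashed together into an integer seed for
#' [set.seed()]. Two different labels give (for practical purposes)
#' independent streams; the same label always gives the same stream.
#'
#' @param seed master seed, a single non-negative integer below 2^31.
#' @param stream character label naming the substream.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @examples
#' substream_seed(1, "blanks")
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, seed < 2^31)
  stopifnot(is.character(stream), length(stream) == 1L, nzchar(stream))
  m <- 2147483647  # 2^31 - 1, prime
  h <- seed %% m
  for (b in utf8ToInt(stream)) {
    # 127 and 16807 keep intermediates < 2^53, exact in doubles
    h <- (h * 127 + b) %% m
    h <- (h * 16807 + 1) %% m
  }
  as.integer(h)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substream_seed(seed, stream))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
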
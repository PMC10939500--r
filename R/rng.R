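#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All stochastic operations in the package draw their randomness from a
#' single user-supplied master seed through named substreams, so that e.g.
#' cohort generation and permutation testing can be re-run independently yet
#' reproducibly.  The sub-seed is a deterministic 31-bit hash of
#' `(seed, name)`.
#'
#' @param seed master integer seed.
#' @param name character stream name (e.g. `"cohort"`, `"perm"`).
#' @return an integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  seed <- check_count(seed, "seed")
  stopifnot(is.character(name), length(name) == 1L)
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(name)) {
    # 31-bit multiplicative string hash (Park-Miller modulus)
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}
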
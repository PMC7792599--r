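# Seed plumbing: every stochastic operation takes an explicit integer seed,
# evaluated inside a local RNG scope so the caller's RNG state is untouched.

with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a root seed
#'
#' Counter-based fan-out so that sub-operations of a pipeline receive
#' independent, reproducible seeds below 2^31.
#'
#' @param root Integer root seed.
#' @param index Non-negative counter distinguishing the consumer.
#' @return Integer seed.
#' @export
derive_seed <- function(root, index) {
  as.integer((as.double(root) * 48271 + as.double(index) * 99991) %% 2147483587)
}
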
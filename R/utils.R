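# Seed plumbing: every stochastic stage runs inside with_seed() so package
# functions never disturb the caller's RNG stream, and the pipeline derives
# per-stage seeds from one global seed by stage-name hashing, so adding a
# stage never perturbs the randomness of earlier ones.

with_seed <- function(seed, expr) {
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
  expr
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Hashes the stage name into `[0, 2^31 - 2]` with a polynomial rolling hash
#' and mixes it with the global seed, so each named stage gets an independent,
#' stable random substream.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed below `2^31`.
#' @export
derive_seed <- function(seed, stage) {
  mod <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed) %% mod
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% mod
  }
  as.integer(h)
}
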
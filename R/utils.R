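# Seeding helpers: every stochastic component draws from R's RNG through
# a locally scoped seed, so a single master seed determines every output
# while leaving the caller's RNG state untouched.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Derive a named sub-stream seed from a master seed
#'
#' Deterministic integer mixing so that independent components (weight
#' initialization, shuffling, augmentation, per-sample phantom draws) each
#' get their own reproducible stream below 2^31.
#' @param seed nonnegative integer master seed.
#' @param label character label of the sub-stream.
#' @return integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) *
             (seq_along(utf8ToInt(as.character(label))) * 131))
  as.integer((as.numeric(seed) * 2654435 + h * 40503 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
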
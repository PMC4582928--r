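# evaluate code under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic child seed
#'
#' All stochastic stages derive their seeds from one top-level seed so that
#' a whole run is reproducible from a single integer. The derivation is a
#' fixed affine map modulo a Mersenne prime, keeping results inside the
#' 32-bit integer range.
#'
#' @param seed top-level integer seed.
#' @param k stage index (any non-negative integer).
#' @return integer child seed.
#' @export
child_seed <- function(seed, k) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  for (i in seq_len(k + 1L)) s <- (s * 48271) %% m
  as.integer(s)
}
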
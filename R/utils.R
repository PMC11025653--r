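# Seeding: every stochastic entry point takes an integer seed and restores
# the caller's RNG state on exit, so package functions never perturb the
# session RNG stream.
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fn <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
  do.call(on.exit, list(substitute(fn(), list(fn = fn)), add = TRUE),
          envir = envir)
  invisible(seed)
}

# derive a distinct 31-bit sub-seed from a base seed and a stream label
# (double arithmetic: R integers are 32-bit and would overflow)
sub_seed <- function(seed, stream) {
  cs <- utf8ToInt(as.character(stream))
  h <- sum(cs * seq_along(cs))
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483647)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
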
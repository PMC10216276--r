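# Seeded RNG streams that never disturb the caller's global RNG state, plus
# deterministic derivation of sub-seeds (kept below 2^31 - 1).

local_rng <- function(seed) {
  state <- NULL
  with_state <- function(draw) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(as.integer(seed)) else {
      assign(".Random.seed", state, envir = globalenv())
    }
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (had_seed) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
    draw()
  }
  list(
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    rbinom = function(n, size, prob) with_state(function() stats::rbinom(n, size, prob)),
    sample = function(x, size, replace = FALSE) with_state(function() sample(x, size, replace = replace))
  )
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65537 * 31259 + as.numeric(k) * 7919 + 12345) %%
               2147483647)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}
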
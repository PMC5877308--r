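# Seeded RNG closure with its own stream, isolated from the caller's
# .Random.seed. Every generator in the package draws through one of these so
# fixtures are reproducible per seed without side effects on user code.
local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  state <- NULL
  with_state <- function(f) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    f()
  }
  list(
    sample = function(n, size = n, replace = FALSE, prob = NULL) {
      with_state(function() sample.int(n, size, replace = replace, prob = prob))
    },
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    rlnorm = function(n, meanlog, sdlog) with_state(function() stats::rlnorm(n, meanlog, sdlog)),
    rexp = function(n, rate) with_state(function() stats::rexp(n, rate)),
    derive = function(k) with_state(function() sample.int(.Machine$integer.max - 1L, k))
  )
}
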
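# Internal utilities.

# A self-contained RNG stream: seeded once, advances only when its methods
# are called, and never disturbs the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  swap_in <- function() {
    env$outer <- get0(".Random.seed", globalenv(), inherits = FALSE)
    if (is.null(env$state)) set.seed(seed)
    else assign(".Random.seed", env$state, globalenv())
  }
  swap_out <- function() {
    env$state <- get(".Random.seed", globalenv(), inherits = FALSE)
    if (is.null(env$outer)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", env$outer, globalenv())
    }
  }
  run <- function(f) {
    swap_in(); on.exit(swap_out()); f()
  }
  list(
    run = run,
    sample_int = function(n, k, replace = FALSE)
      run(function() sample.int(n, k, replace = replace)),
    runif = function(n, min = 0, max = 1) run(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    rnbinom_mu = function(n, mu, size) run(function() stats::rnbinom(n, mu = mu, size = size)),
    spawn_seed = function() run(function() sample.int(.Machine$integer.max, 1L))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "tf_error")))
}
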
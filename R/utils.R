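# Isolated, named random streams.
#
# Every object produced by a generator in this package draws from its own
# seedable stream so that results are reproducible independently of the
# caller's global RNG state, and the seed can be recorded in the object's
# metadata.

local_rng <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be a finite integer", call. = FALSE)
  env <- new.env(parent = emptyenv())
  swap_in <- function() {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(env$state)) {
      set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    } else {
      assign(".Random.seed", env$state, envir = globalenv())
    }
    old
  }
  swap_out <- function(old) {
    env$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  wrap <- function(f) {
    function(...) {
      old <- swap_in()
      on.exit(swap_out(old))
      f(...)
    }
  }
  list(
    seed = seed,
    runif = wrap(stats::runif),
    rnorm = wrap(stats::rnorm),
    rpois = wrap(stats::rpois),
    rbinom = wrap(stats::rbinom),
    sample_int = wrap(function(n, size, replace = FALSE)
      sample.int(n, size, replace = replace))
  )
}

# A value flagged as undefined (propagated instead of silently becoming 0).
undefined_value <- function() NA_real_
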
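## Isolated RNG stream: draws are a pure function of `seed` and do not
## disturb (or depend on) the caller's global RNG state.
.seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  wrap <- function(f) {
    force(f)
    function(...) {
      g <- globalenv()
      old <- if (exists(".Random.seed", envir = g, inherits = FALSE)) {
        get(".Random.seed", envir = g)
      } else NULL
      on.exit({
        env$state <- get(".Random.seed", envir = g)
        if (is.null(old)) {
          rm(".Random.seed", envir = g)
        } else {
          assign(".Random.seed", old, envir = g)
        }
      })
      if (is.null(env$state)) {
        set.seed(seed)
      } else {
        assign(".Random.seed", env$state, envir = g)
      }
      f(...)
    }
  }
  list(runif = wrap(stats::runif),
       rnorm = wrap(stats::rnorm),
       sample_int = wrap(function(n) sample.int(n)))
}

## Multiplicative lognormal factor with unit mean and coefficient of
## variation cv (mechanical properties are positive and heteroscedastic).
.lognormal_factor <- function(rng, n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  exp(rng$rnorm(n, -sdl^2 / 2, sdl))
}
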
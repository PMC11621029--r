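## Seeded randomness without disturbing the caller's global RNG stream.

.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

## Evaluate expr under set.seed(seed), then restore the caller's stream.
.withSeed <- function(seed, expr) {
  old <- .saveSeed()
  on.exit(.restoreSeed(old))
  set.seed(as.integer(seed))
  expr
}

## A persistent seeded stream: successive draws continue from the same
## stream, isolated from the global RNG.
.seededRNG <- function(seed) {
  env <- new.env()
  old <- .saveSeed()
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = globalenv())
  .restoreSeed(old)
  draw <- function(f) {
    old <- .saveSeed()
    assign(".Random.seed", env$state, envir = globalenv())
    res <- f()
    env$state <- get(".Random.seed", envir = globalenv())
    .restoreSeed(old)
    res
  }
  list(
    sample = function(x, size) draw(function() sample(x, size)),
    sampleInt = function(n, size) draw(function() sample.int(n, size)),
    sampleIntProb = function(n, prob)
      draw(function() sample.int(n, 1L, prob = prob)),
    permute = function(n) draw(function() sample.int(n, n)),
    runif = function(n) draw(function() stats::runif(n)),
    rnorm = function(n, mean = 0, sd = 1)
      draw(function() stats::rnorm(n, mean, sd)),
    rgamma = function(n, shape, rate = 1)
      draw(function() stats::rgamma(n, shape, rate = rate)),
    geomRun = function(n, prob) draw(function() stats::rgeom(n, prob) + 1L)
  )
}
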
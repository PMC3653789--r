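# Internal seeded RNG utilities. Policies and generators each own a private
# uniform stream so that replays are bit-identical and independent of whatever
# the caller does with the global RNG.

#' Evaluate code under a temporary seed, restoring the global RNG state
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Create a private uniform stream seeded once; draws are buffered so the
#' global RNG is swapped only on refills.
#' @noRd
rng_stream <- function(seed, buffer = 2048L) {
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed)
  env$state <- NULL
  env$buf <- numeric(0)
  env$pos <- 0L
  env$buffer <- as.integer(buffer)
  class(env) <- "bcst_rng"
  env
}

#' @noRd
rng_refill <- function(rng) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  if (is.null(rng$state)) set.seed(rng$seed) else
    assign(".Random.seed", rng$state, envir = genv)
  rng$buf <- stats::runif(rng$buffer)
  rng$state <- get(".Random.seed", envir = genv, inherits = FALSE)
  rng$pos <- 0L
  if (had) assign(".Random.seed", old, envir = genv) else
    rm(".Random.seed", envir = genv)
  invisible(rng)
}

#' Draw one Uniform(0,1) from a private stream
#' @noRd
rng_unif <- function(rng) {
  if (rng$pos >= length(rng$buf)) rng_refill(rng)
  rng$pos <- rng$pos + 1L
  rng$buf[[rng$pos]]
}

#' Draw one element of `x` uniformly from a private stream
#' @noRd
rng_pick <- function(rng, x) {
  n <- length(x)
  if (n == 1L) return(x[[1L]])
  x[[1L + as.integer(floor(rng_unif(rng) * n)) %% n]]
}
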
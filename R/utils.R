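# Internal helpers: deterministic seed substreams and local RNG scope.

# Mix a master seed with stream indices into a 32-bit seed. Order-stable:
# the substream for (partition b, round r, step s, fit f) never depends on
# how many other substreams were consumed, so parallel and serial execution
# agree.
substream_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(master) %% m
  primes <- c(1299721, 15485863, 32452843, 49979687, 67867967)
  for (i in seq_along(idx)) {
    p <- primes[((i - 1L) %% length(primes)) + 1L]
    h <- (h * 48271 + as.numeric(idx[i]) * p) %% m
  }
  as.integer(h) + 1L
}

# Evaluate `expr` under a fixed seed without clobbering the caller's RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_pf <- function(msg, class = "panelforest_error") {
  abort(msg, class = class)
}
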
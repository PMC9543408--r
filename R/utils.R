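# internal helpers: seed discipline and small utilities

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.  All stochastic entry
# points route through this so that results are pure functions of
# (inputs, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic named substreams derived from a master seed.  Keeps every
# derived seed a positive 32-bit integer; distinct (master, id) pairs map to
# distinct seeds with overwhelming probability for the id ranges used here.
substream <- function(master, id) {
  stopifnot(is.numeric(master), length(master) == 1L)
  x <- (abs(as.numeric(master)) %% 2147483647) + 1
  x <- (x * 48271) %% 2147483647
  x <- (x + as.numeric(id) * 69621) %% 2147483647
  as.integer(x) + 1L
}

# ids for the generator's named substreams (toggling one mechanism leaves
# the draws of the others unchanged)
.stream_ids <- c(
  baseline = 11L, ranef = 23L, resid = 37L, dropout = 53L,
  intermittent = 71L, j2r = 89L, pmm = 101L, ps = 113L, runall = 131L
)

stream_seed <- function(master, name, extra = 0L) {
  substream(master, .stream_ids[[name]] + 1000L * as.numeric(extra))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# length of the trailing run of FALSE in a logical vector
trailing_missing_run <- function(obs) {
  v <- length(obs)
  r <- 0L
  while (r < v && !obs[v - r]) r <- r + 1L
  r
}
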
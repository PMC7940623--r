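# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so package functions never perturb the global stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != as.integer(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name),
         call. = FALSE)
  }
  as.numeric(x)
}

# Round half away from zero (the fixed convention for top-fraction sizes).
round_half_up <- function(x) floor(x + 0.5)
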
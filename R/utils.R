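# internal helpers shared across modules

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Derive an integer seed (< 2^31) for a named generator stream. Each
# generator owns a fixed tag so adding a generator never shifts the stream
# of another.
derive_stream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 97561
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# Evaluate expr under a generator-local RNG stream, restoring the caller's
# RNG state afterwards so generators are pure functions of (seed, args).
with_stream <- function(seed, tag, expr) {
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(derive_stream_seed(seed, tag))
  force(expr)
}

# Error with the pipeline stage name attached, so failures are attributable.
stop_stage <- function(stage, fmt, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
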
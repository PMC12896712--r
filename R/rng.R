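# Seed plumbing shared by the stochastic stages.
#
# Top-level entry points accept `seed = NULL`; when given, the global RNG
# state is set locally and restored on exit so library calls do not disturb
# the caller's stream. Stage-level child seeds are derived deterministically
# from a master seed so that one replicate seed reproduces the whole run.

local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  expr <- if (has_old)
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  else
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(seed)
}

# Deterministic child seeds, kept inside the 32-bit integer range.
derive_seeds <- function(master, n, stage = 0L) {
  master <- as.integer(master) %% 2147480000L
  (master + 7919L * stage + 104729L * seq_len(n)) %% 2147480000L + 1L
}
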
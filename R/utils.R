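# Internal helpers shared across modules.

# Raise a classed condition so callers can distinguish error families
# (format/parse/validation/integrity/usage/model/degenerate/alignment/pairing).
oa_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("odoradapt_", class), "odoradapt_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    oa_stop("usage_error", "seed must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
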
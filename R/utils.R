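# Internal helpers shared across modules.

# Classed error so callers can distinguish failure modes with tryCatch().
cc_stop <- function(msg, class, call. = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ccpipe_error", "error", "condition"),
                      call = call.))
}

cc_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "ccpipe_warning", "warning", "condition")))
}

# Evaluate `code` under a fixed RNG seed without touching global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
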
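# Classed conditions so callers (and the CLI) can map failures to exit codes.

dx_abort <- function(message, class, data = list()) {
  cond <- structure(
    class = c(class, "dx_error", "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
  stop(cond)
}

stop_validation <- function(message, data = list()) {
  dx_abort(message, "dx_validation_error", data)
}

stop_dependency <- function(message, data = list()) {
  dx_abort(message, "dx_dependency_error", data)
}

stop_failover <- function(message, data = list()) {
  dx_abort(message, "dx_failover_error", data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Small deterministic string hash (31-bit), used to derive per-(model, case)
# RNG substreams and stable synthetic ICD-style codes. Not cryptographic.
str_hash31 <- function(x, mod = 2147483647) {
  h <- 0
  for (b in utf8ToInt(x)) {
    h <- (h * 131 + b) %% mod
  }
  as.integer(h)
}
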
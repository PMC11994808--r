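#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish failure modes programmatically.
mcir_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mcir_error")))
}

# Channels modeled by the digital twin, in canonical order.
TWIN_CHANNELS <- c("hr", "hrv", "rr", "activity", "skin_temp")

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream of child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC")
}

hours <- function(h) h * 3600
minutes <- function(m) m * 60

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    mcir_abort(sprintf("'%s' must be a finite scalar number", name),
               "validation_error")
}
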
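# Internal helpers shared across the pipeline.

# Classed error conditions so callers can distinguish geometry problems from
# data problems from configuration problems.
abort <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "oscillage_error", "error")))
}

abort_geometry     <- function(msg, ...) abort(msg, "oscillage_geometry_error", ...)
abort_shape        <- function(msg, ...) abort(msg, "oscillage_shape_error", ...)
abort_config       <- function(msg, ...) abort(msg, "oscillage_config_error", ...)
abort_data         <- function(msg, ...) abort(msg, "oscillage_insufficient_data_error", ...)
abort_numeric      <- function(msg, ...) abort(msg, "oscillage_numeric_error", ...)
abort_rank         <- function(msg, ...) abort(msg, "oscillage_rank_error", ...)
abort_convergence  <- function(msg, ...) abort(msg, "oscillage_convergence_error", ...)
abort_degenerate   <- function(msg, ...) abort(msg, "oscillage_degenerate_error", ...)
abort_schema       <- function(msg, ...) abort(msg, "oscillage_schema_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression with a private RNG state so library code never disturbs
# the caller's random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a global seed; kept below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629 + 1)
}

vnorm <- function(x) sqrt(sum(x^2))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
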
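# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Stop with a classed error so callers/tests can match on condition class.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "p300lbp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

validation_error <- function(msg) abort(msg, "p300lbp_validation_error")
alignment_error  <- function(msg) abort(msg, "p300lbp_alignment_error")
bounds_error     <- function(msg) abort(msg, "p300lbp_bounds_error")
parse_error      <- function(msg) abort(msg, "p300lbp_parse_error")
training_error   <- function(msg, history = NULL) {
  stop(structure(
    class = c("p300lbp_training_error", "p300lbp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), history = history)
  ))
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error(sprintf("'%s' must be a finite numeric scalar", name))
  if (x < lo || x > hi)
    validation_error(sprintf("'%s' must be in [%s, %s] (got %s)", name, lo, hi, x))
  if (integer && x != round(x))
    validation_error(sprintf("'%s' must be a whole number (got %s)", name, x))
  invisible(x)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic fan-out of one global seed into per-stage seeds (< 2^31).
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
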
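# Internal helpers: classed errors so callers can distinguish bad input
# (validation/domain) from numerical failure, and a seed sandbox for the
# synthetic-data generators.

stop_validation <- function(msg) {
  stop(structure(
    class = c("bilispec_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_domain <- function(msg) {
  stop(structure(
    class = c("bilispec_domain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_numerical <- function(msg) {
  stop(structure(
    class = c("bilispec_numerical_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_scalar <- function(x, name, finite = TRUE, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_domain(sprintf("`%s` must be a single numeric value", name))
  }
  if (finite && !is.finite(x)) {
    stop_domain(sprintf("`%s` must be finite", name))
  }
  if (!is.null(min) && x < min) {
    stop_domain(sprintf("`%s` must be >= %g", name, min))
  }
  invisible(x)
}

check_ph <- function(pH) {
  if (!is.numeric(pH) || length(pH) == 0L || any(!is.finite(pH))) {
    stop_domain("`pH` must be numeric and finite")
  }
  invisible(pH)
}

check_sorted_grid <- function(pH_grid) {
  check_ph(pH_grid)
  if (length(pH_grid) > 1L && any(diff(pH_grid) <= 0)) {
    stop_validation("`pH_grid` must be strictly increasing")
  }
  invisible(pH_grid)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
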
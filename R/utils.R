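# Internal helpers: classed conditions, seeded RNG scopes, small numerics.

# MPa * nm^2 -> nN  (1 MPa = 1e6 N/m^2 = 1e-12 N/nm^2 = 1e-3 nN/nm^2)
.MPA_NM2_TO_NN <- 1e-3

cm_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "corneomech_error")))
}

cm_warn <- function(msg, class = "corneomech_warning") {
  warning(warningCondition(msg, class = c(class, "corneomech_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a private, seeded RNG state
#'
#' Saves and restores `.Random.seed` so that seeded operations never leak
#' into (or depend on) the caller's random state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    cm_abort("'seed' must be a single non-missing number", "cm_config_error")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stage offset, kept < 2^31.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             open_lower = FALSE, open_upper = FALSE,
                             class = "cm_config_error") {
  ok <- is_scalar_number(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok)
    cm_abort(sprintf("'%s' must be a finite scalar in %s%s, %s%s (got %s)",
                     name, if (open_lower) "(" else "[", format(lower),
                     format(upper), if (open_upper) ")" else "]",
                     paste(format(x), collapse = ", ")),
             class)
  invisible(x)
}
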
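# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_ <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_(name, " must be a single non-missing number")
  if (strict_lower && x <= lower)
    stop_(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    stop_(name, " must be >= ", lower)
  if (x > upper)
    stop_(name, " must be <= ", upper)
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  assert_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) stop_(name, " must be an integer")
  invisible(as.integer(x))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators do not perturb user code.
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
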
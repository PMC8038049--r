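#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded stages do not perturb the
#' caller's RNG stream. All stochastic operations in the package route their
#' randomness through this helper, which is what makes every stage a pure
#' function of (inputs, seed).
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed and string identifiers
#'
#' Deterministic 31-bit hash (polynomial rolling hash over the UTF-8 bytes of
#' the identifiers, mixed with the master seed). Used to give every subject,
#' region and reference-network draw its own reproducible stream.
#'
#' @param master integer master seed.
#' @param ... identifiers (coerced to character).
#' @return a positive integer < 2^31.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L)
  ids <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(master) %% 2147483647
  for (b in utf8ToInt(ids)) h <- (h * 131 + b) %% 2147483647
  as.integer(h %% 2147483629 + 1)
}

# argument checks -------------------------------------------------------

stop_if_not_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

stop_if_not_count <- function(x, name, lo = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < lo)
    stop(sprintf("`%s` must be an integer >= %d", name, lo), call. = FALSE)
  invisible(as.integer(x))
}
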
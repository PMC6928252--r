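#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

#' Derive a stream of reproducible child seeds from one parent seed
#'
#' Keeps every derived seed strictly below 2^31 (R integers are 32-bit).
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(index) * 104729 + 13) %%
               2147483629)
}

#' Frobenius norm of an array
#' @noRd
fnorm <- function(a) sqrt(sum(a^2))

#' Cosine similarity of two vectors
#' @noRd
cosine <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
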
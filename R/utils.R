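# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state so that seeded package functions do not perturb the
#' user's random stream. With `seed = NULL` the code runs on the current
#' stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    genv <- globalenv()
    if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      old <- get(".Random.seed", envir = genv)
      on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
    }
    set.seed(seed)
  }
  code
}

# Draw n isotropic 2-D Brownian step lengths for diffusion coefficient D
# over one frame interval: |dr| is Rayleigh with scale sqrt(2 D dt).
rrayleigh_step <- function(n, D, dt) {
  sqrt(-4 * D * dt * log(runif(n)))
}

# Derive a stream of sub-seeds from one user seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 7919L * seq_len(n)) %% .Machine$integer.max
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1) {
  length(x) == 1 && is.finite(x) && x == round(x) && x >= min
}
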
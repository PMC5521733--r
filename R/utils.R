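#' Derive a reproducible sub-seed from a master seed
#'
#' A single master seed drives every stochastic component of the pipeline.
#' Each component (and, inside the Monte Carlo engine, each replicate of
#' each uncertainty source) draws from its own stream, derived here, so
#' that switching one source off leaves the draws of every other source
#' unchanged.
#'
#' @param master integer master seed.
#' @param stream character stream label.
#' @param rep integer replicate index (0 for non-replicated streams).
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(master, stream, rep = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  # small multiplicative string hash kept inside double precision
  h <- 0
  for (cc in utf8ToInt(stream)) h <- (h * 131 + cc) %% 1e6
  s <- ((abs(master) %% 1e6) * 31337 + h * 7919 + (rep %% 1e6) * 1009) %%
    2147483629
  as.integer(s + 1L)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb
#' the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Sign-preserving cube root
#'
#' @param x numeric vector.
#' @return `sign(x) * abs(x)^(1/3)`.
#' @export
signed_cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

# stop() with a consistent configuration-error prefix naming the field
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
    call. = FALSE
  )
}
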
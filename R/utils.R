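# Internal helpers: argument checking, seeded evaluation, seed derivation.

stop_param <- function(...) {
  stop(structure(class = c("microfusion_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_param(...)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x, min = -Inf) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministically combine a base seed with integer tags into a new seed
# below 2^31. All arithmetic stays exactly representable in doubles.
derive_seed <- function(base, ...) {
  s <- as.numeric(base) %% 2147483647
  for (v in c(...)) s <- (s * 69069 + as.numeric(v)) %% 2147483647
  as.integer(s)
}

# Population (divide-by-n) standard deviation; the SD convention used for
# all feature statistics in the package.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
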
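# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the prior
#' RNG state afterwards, so generators are pure functions of their inputs
#' and never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a sub-seed so that distinct pipeline stages
# (class means, ID draws, OOD draws, splits, ...) consume independent
# streams while remaining a pure function of the user-facing seed.
# Stays below 2^31 - 1.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) %% 2147483587 * 7919 +
                as.double(salt) * 104729) %% 2147483587)
}

# Coerce a vector to a 1-row matrix; pass matrices through.
as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(what, " must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  invisible(x)
}

# Largest-remainder apportionment: integer counts summing exactly to
# round(sum(target)). Ties on the fractional part go to the lower index.
largest_remainder <- function(target) {
  n_total <- round(sum(target))
  base <- floor(target)
  rem <- n_total - sum(base)
  if (rem > 0) {
    frac <- target - base
    give <- order(-frac, seq_along(target))[seq_len(rem)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}
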
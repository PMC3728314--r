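# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the RNG alone.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single number or NULL.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  force(expr)
}

# Deterministic child-seed derivation, kept below 2^31 so derived seeds are
# themselves valid R seeds. Used where one user-facing seed drives several
# independent random components.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483647
}

check_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (strict && x <= min) abort(sprintf("`%s` must be > %g.", name, min))
  if (!strict && x < min) abort(sprintf("`%s` must be >= %g.", name, min))
  invisible(x)
}
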
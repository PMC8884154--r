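# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a deterministic sub-stream seed from a parent seed. Kept below
# 2^31 - 1 so the result is always a valid integer seed.
child_seed <- function(seed, stream) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 9973) %% 2147483629)
}

# Sample coefficient of variation over a numeric vector, NA meaning
# "not observed" unless zeros_as_values (RNA convention: zeros are data).
cv_of <- function(x, zeros_as_values = FALSE) {
  if (!zeros_as_values) {
    x <- x[!is.na(x)]
  }
  if (length(x) < 2) {
    return(NA_real_)
  }
  m <- mean(x)
  if (m == 0) {
    return(NA_real_)
  }
  stats::sd(x) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
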
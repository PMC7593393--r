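# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
NULL

# Evaluate `expr` with the RNG seeded by `seed`, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Population standard deviation across a vector (divisor n, not n - 1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Degrees <-> radians
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

# All permutations of 1..n as a matrix (n! rows). Guarded for small n only.
all_permutations <- function(n) {
  if (n > 7) abort("permutation enumeration limited to n <= 7 levels")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
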
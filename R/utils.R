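#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Tolerance used for the simplex-sum invariant throughout the package.
.simplex_tol <- 1e-12

# Threshold below which x + y is treated as exactly 0 for the 1/(x+y)
# response functions (cases 4 and 5).
.xy_singularity_tol <- 1e-12

# Opinion coding used in agent state vectors.
.OP_X <- 1L
.OP_Y <- 2L
.OP_Z <- 3L
.OP_LABELS <- c("X", "Y", "Z")

#' Construct a population state on the 3-simplex
#'
#' A population state records the fractions of the population committed to
#' opinion X, committed to opinion Y, and uncommitted (Z). The three
#' fractions must be nonnegative and sum to one.
#'
#' @param x,y Fractions in states X and Y.
#' @param z Fraction in the uncommitted state; defaults to `1 - x - y`.
#' @return A named numeric vector `c(x =, y =, z =)`.
#' @examples
#' population_state(0.5, 0.3)
#' @export
population_state <- function(x, y, z = 1 - x - y) {
  s <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  validate_state(s)
  s
}

validate_state <- function(s, tol = 1e-9) {
  if (length(s) != 3L || !is.numeric(s)) {
    abort("a population state must be three numeric fractions (x, y, z)")
  }
  if (any(s < -tol) || any(s > 1 + tol)) {
    abort(sprintf(
      "population fractions must lie in [0, 1]; got (%g, %g, %g)",
      s[[1]], s[[2]], s[[3]]
    ))
  }
  if (abs(sum(s) - 1) > 1e-8) {
    abort(sprintf("population fractions must sum to 1; got %.12g", sum(s)))
  }
  invisible(s)
}

# Accepts either c(x, y) or c(x, y, z); returns unnamed c(x, y).
as_xy <- function(state) {
  if (length(state) == 3L) {
    validate_state(state)
    unname(state[1:2])
  } else if (length(state) == 2L) {
    unname(as.numeric(state))
  } else {
    abort("state must be (x, y) or (x, y, z)")
  }
}

# Deterministic child-seed derivation: mixes a base seed with index terms so
# that replicate runs are reproducible piecewise and as a whole. Arithmetic
# stays below 2^53 so it is exact in doubles; result is a valid 32-bit seed.
child_seed <- function(seed, ...) {
  idx <- c(...)
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (k in seq_along(idx)) {
    h <- (h * 48271 + as.numeric(idx[[k]]) * 1299721 + k) %% 2147483647
  }
  as.integer(h)
}

# Runs expr under a temporary RNG seed when seed is non-NULL; otherwise uses
# the ambient RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

ramp <- function(u) ifelse(u > 0, u, 0)
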
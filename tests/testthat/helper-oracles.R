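# Independent oracles: literal re-statements of the model's defining
# arithmetic, written without calling the package's own kernels, used to
# cross-check the implementation on small inputs.

# Response-function values per case, spelled out directly.
oracle_f <- function(case_id, m, d, x, y) {
  x <- unname(x)
  y <- unname(y)
  inv <- if (x + y < 1e-12) 0 else 1 / (x + y)
  switch(case_id,
    c(1, 1, 1, 1),
    c(1, y^(m - 1), x^(m - 1), 1),
    c(x^(d - 1), 1, 1, y^(d - 1)),
    c(1, inv, inv, 1),
    c(inv, 1, 1, inv)
  )
}

# One step of the macroscopic dynamics, by direct hand arithmetic
# (no clipping: valid for the parameter ranges the oracle is used with).
oracle_mf_step <- function(x, y, a11, a12, a21, a22, case_id = 1, m = 1, d = 1) {
  f <- oracle_f(case_id, m, d, x, y)
  z <- 1 - x - y
  c(
    x - a12 * f[2] * x * y + a11 * x * f[1] * z,
    y - a21 * f[3] * x * y + a22 * y * f[4] * z
  )
}

# Expected gain of candidate action i over current action j, by explicit
# loop over the positive payoff differences.
oracle_expected_gain <- function(A, i, j, shares) {
  total <- 0
  for (k in seq_len(ncol(A))) {
    diffk <- A[i, k] - A[j, k]
    if (diffk > 0) total <- total + diffk * shares[k]
  }
  total
}

# Closed-form interior equilibrium of the linear-response dynamics
# (case 1): balances a12 y = a11 z and a21 x = a22 z.
oracle_case1_interior <- function(a11, a12, a21, a22) {
  rx <- a22 / a21
  ry <- a11 / a12
  z <- 1 / (1 + rx + ry)
  c(x = rx * z, y = ry * z, z = z, q = (a11 * a21) / (a12 * a22))
}

# Hand-derived Jacobian of the case-1 map.
oracle_case1_jacobian <- function(x, y, a11, a12, a21, a22) {
  matrix(c(
    1 - a12 * y + a11 * (1 - 2 * x - y), -(a12 + a11) * x,
    -(a21 + a22) * y, 1 - a21 * x + a22 * (1 - x - 2 * y)
  ), 2, 2, byrow = TRUE)
}

# The four reward parameterisations of the comparison study.
study_matrices <- function() {
  list(
    payoff_params(0.2, 0.2, 0.2, 0.2),
    payoff_params(0.9, 0.2, 0.2, 0.2),
    payoff_params(0.9, 0.4, 0.4, 0.9),
    payoff_params(0.1, 0.5, 0.3, 0.6)
  )
}

# One case_spec per mechanism, with the group sizes used throughout the
# tests (m = d = 3 where group sizes apply).
all_cases <- function(m = 3L) {
  list(
    case_spec(1), case_spec(2, m = m), case_spec(3, m = m),
    case_spec(4), case_spec(5)
  )
}

# Drop the ci_* classes so dplyr joins see plain tibbles.
as_tibble_strip <- function(x) {
  tibble::as_tibble(as.data.frame(x))
}

random_interior_state <- function() {
  u <- stats::runif(3, 0.05, 1)
  u <- u / sum(u)
  c(x = u[1], y = u[2], z = u[3])
}
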
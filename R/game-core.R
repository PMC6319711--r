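#' Payoff parameters of the three-opinion game
#'
#' The four nonnegative reward constants of the identical-payoff game:
#' `a11` rewards recruitment into X, `a22` recruitment into Y, while `a12`
#' and `a21` weight the cross-inhibitory signals that push committed agents
#' back to the uncommitted state. In the per-step dynamics these constants
#' bound transition probabilities, so values above 1 trigger a warning
#' (probabilities are clipped where needed).
#'
#' @param a11,a12,a21,a22 Nonnegative dimensionless reward constants.
#' @return An object of class `ci_params` (a named list).
#' @examples
#' payoff_params(0.9, 0.2, 0.2, 0.2)
#' @export
payoff_params <- function(a11, a12, a21, a22) {
  a <- c(a11 = a11, a12 = a12, a21 = a21, a22 = a22)
  if (!is.numeric(a) || anyNA(a)) abort("payoff constants must be numeric")
  if (any(a < 0)) {
    abort(sprintf("payoff constant %s must be nonnegative",
                  names(a)[a < 0][[1]]))
  }
  if (any(a > 1)) {
    warn("payoff constants above 1 can exceed per-step probability bounds; rates will be clipped")
  }
  structure(as.list(a), class = "ci_params")
}

#' @export
print.ci_params <- function(x, ...) {
  cat(sprintf(
    "<ci_params> a11 = %g, a12 = %g, a21 = %g, a22 = %g\n",
    x$a11, x$a12, x$a21, x$a22
  ))
  invisible(x)
}

#' Case specification for the five consensus mechanisms
#'
#' Selects one of five quantised-consensus rules, differing in how many
#' sampled neighbours must agree before an agent changes opinion:
#' \describe{
#'   \item{Case 1}{linear recruitment and cross-inhibition; every decision
#'     uses a single sampled neighbour.}
#'   \item{Case 2}{stubborn committed agents: a committed agent abandons its
#'     opinion only if `m` sampled neighbours all hold the opposite one.}
#'   \item{Case 3}{stubborn uncommitted agents: an uncommitted agent commits
#'     only if `d` sampled neighbours all share an opinion.}
#'   \item{Case 4}{committed agents respond to the local fraction of
#'     committed peers (cross-inhibition scaled by 1/(x + y)).}
#'   \item{Case 5}{uncommitted agents respond to the local fraction of
#'     committed peers (recruitment scaled by 1/(x + y)).}
#' }
#'
#' @param case_id Integer in 1..5.
#' @param m Committed-side group size (case 2); must be 1 for cases 1, 4,
#'   5. For case 3 it only supplies the default for `d` (the committed-side
#'   sample stays a single neighbour).
#' @param d Uncommitted-side group size (case 3); defaults to `m` for case 3
#'   and to 1 otherwise.
#' @return An object of class `ci_case`.
#' @examples
#' case_spec(2, m = 3)
#' case_spec(3, m = 3) # d defaults to m
#' @export
case_spec <- function(case_id, m = 1L, d = NULL) {
  case_id <- as.integer(case_id)
  if (length(case_id) != 1L || is.na(case_id) || !case_id %in% 1:5) {
    abort("case_id must be a single integer in 1..5")
  }
  m <- as.integer(m)
  if (is.na(m) || m < 1L) abort("m must be an integer >= 1")
  if (is.null(d)) d <- if (case_id == 3L) m else 1L
  d <- as.integer(d)
  if (is.na(d) || d < 1L) abort("d must be an integer >= 1")
  if (case_id %in% c(1L, 4L, 5L) && (m != 1L || d != 1L)) {
    abort(sprintf("case %d uses single-neighbour sampling: m and d must both be 1", case_id))
  }
  if (case_id == 2L && d != 1L) abort("case 2 samples a single neighbour on the uncommitted side: d must be 1")
  structure(list(case_id = case_id, m = m, d = d), class = "ci_case")
}

#' @export
print.ci_case <- function(x, ...) {
  cat(sprintf("<ci_case> case %d (m = %d, d = %d)\n", x$case_id, x$m, x$d))
  invisible(x)
}

# Sample-set cardinalities per case: committed agents sample |M| neighbours,
# uncommitted agents sample |D|.
case_cardinalities <- function(case) {
  switch(case$case_id,
    list(M = 1L, D = 1L),          # case 1
    list(M = case$m, D = 1L),      # case 2
    list(M = 1L, D = case$d),      # case 3
    list(M = 1L, D = 1L),          # case 4
    list(M = 1L, D = 1L)           # case 5
  )
}

#' Case-specific response functions
#'
#' Evaluates the four response functions that modulate the baseline rewards
#' in each consensus mechanism: `f1` scales recruitment into X, `f2`
#' cross-inhibition of X, `f3` cross-inhibition of Y, `f4` recruitment into
#' Y. Cases 2 and 3 use power-law responses (`y^(m-1)`, `x^(m-1)` and
#' `x^(d-1)`, `y^(d-1)` respectively); cases 4 and 5 scale by the inverse
#' committed fraction `1/(x + y)`, defined as 0 when `x + y` vanishes (there
#' are no committed peers to observe, and every transition rate carries an
#' extra factor of x or y that vanishes faster).
#'
#' @param case A [case_spec()].
#' @param state A population state `(x, y, z)` (or `(x, y)`).
#' @return Named numeric vector `c(f1, f2, f3, f4)`, all nonnegative.
#' @examples
#' response_functions(case_spec(3, m = 3), population_state(0.5, 0.2))
#' @export
response_functions <- function(case, state) {
  xy <- as_xy(state)
  x <- xy[[1]]
  y <- xy[[2]]
  f <- switch(case$case_id,
    c(1, 1, 1, 1),
    c(1, y^(case$m - 1L), x^(case$m - 1L), 1),
    c(x^(case$d - 1L), 1, 1, y^(case$d - 1L)),
    {
      inv <- if (x + y < .xy_singularity_tol) 0 else 1 / (x + y)
      c(1, inv, inv, 1)
    },
    {
      inv <- if (x + y < .xy_singularity_tol) 0 else 1 / (x + y)
      c(inv, 1, 1, inv)
    }
  )
  names(f) <- c("f1", "f2", "f3", "f4")
  f
}

#' Payoff matrix of the three-action game at a population state
#'
#' Builds the 3x3 payoff matrix over actions (X, Y, Z): committed diagonal
#' entries `a11 f1` and `a22 f4` reward staying with the crowd, off-diagonal
#' entries `-a12 f2` and `-a21 f3` penalise facing the opposite camp, and
#' the uncommitted row and column are identically zero.
#'
#' @param params A [payoff_params()].
#' @param case A [case_spec()].
#' @param state Population state at which the response functions are
#'   evaluated.
#' @return A 3x3 numeric matrix with dimnames `(X, Y, Z)`.
#' @export
payoff_matrix <- function(params, case, state) {
  f <- response_functions(case, state)
  A <- matrix(0, 3, 3, dimnames = list(.OP_LABELS, .OP_LABELS))
  A["X", "X"] <- params$a11 * f[["f1"]]
  A["X", "Y"] <- -params$a12 * f[["f2"]]
  A["Y", "X"] <- -params$a21 * f[["f3"]]
  A["Y", "Y"] <- params$a22 * f[["f4"]]
  A
}

#' Expected gain of switching action under pairwise comparison
#'
#' The expected-gain revision protocol: the attractiveness of a candidate
#' action i to a player currently using action j is the population-weighted
#' sum of the positive parts of the payoff differences,
#' `sum_k max(a_ik - a_jk, 0) * x_k`. Negative differences contribute
#' nothing (strict positive-part operator), so gains are always
#' nonnegative.
#'
#' @param A An n x n payoff matrix.
#' @param current Current action (index or dimname).
#' @param candidate Candidate action (index or dimname).
#' @param shares Numeric vector of length n: the fraction of players using
#'   each action. Must sum to 1.
#' @return A nonnegative scalar.
#' @examples
#' A <- payoff_matrix(payoff_params(0.2, 0.2, 0.2, 0.2), case_spec(1),
#'                    population_state(0.5, 0.3))
#' expected_gain(A, current = "Z", candidate = "X", shares = c(0.5, 0.3, 0.2))
#' @export
expected_gain <- function(A, current, candidate, shares) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) abort("A must be a square matrix")
  n <- nrow(A)
  if (length(shares) != n) abort("shares must have one entry per action")
  if (any(shares < -1e-12) || abs(sum(shares) - 1) > 1e-8) {
    abort("shares must be nonnegative and sum to 1")
  }
  i <- resolve_action(A, candidate)
  j <- resolve_action(A, current)
  sum(ramp(A[i, ] - A[j, ]) * shares)
}

resolve_action <- function(A, action) {
  if (is.character(action)) {
    idx <- match(action, rownames(A))
    if (is.na(idx)) abort(sprintf("unknown action '%s'", action))
    idx
  } else {
    idx <- as.integer(action)
    if (is.na(idx) || idx < 1L || idx > nrow(A)) abort("action index out of range")
    idx
  }
}

#' Per-step transition probabilities of the population process
#'
#' Computes the four macroscopic transition probabilities between opinion
#' states: recruitment `pZX = a11 x f1` and `pZY = a22 y f4`, and
#' cross-inhibition `pXZ = a12 y f2` and `pYZ = a21 x f3`. These equal the
#' expected gain of the corresponding action switch under the game's payoff
#' matrix. Raw values are retained for diagnostics; the working values are
#' clipped to [0, 1], and if the two exit probabilities from Z together
#' exceed 1 they are jointly rescaled so the uncommitted row of the
#' single-agent transition matrix stays stochastic.
#'
#' @inheritParams payoff_matrix
#' @return An object of class `ci_rates`: list with elements `raw` and
#'   `clipped` (named vectors `pZX, pXZ, pYZ, pZY`), plus logical flags
#'   `any_clipped` and `z_row_rescaled`.
#' @examples
#' transition_rates(payoff_params(0.2, 0.2, 0.2, 0.2), case_spec(1),
#'                  population_state(0.5, 0.3))
#' @export
transition_rates <- function(params, case, state) {
  xy <- as_xy(state)
  x <- xy[[1]]
  y <- xy[[2]]
  f <- response_functions(case, c(x, y))
  raw <- c(
    pZX = params$a11 * x * f[["f1"]],
    pXZ = params$a12 * y * f[["f2"]],
    pYZ = params$a21 * x * f[["f3"]],
    pZY = params$a22 * y * f[["f4"]]
  )
  clipped <- pmin(pmax(raw, 0), 1)
  z_exit <- clipped[["pZX"]] + clipped[["pZY"]]
  rescaled <- FALSE
  if (z_exit > 1) {
    clipped[["pZX"]] <- clipped[["pZX"]] / z_exit
    clipped[["pZY"]] <- clipped[["pZY"]] / z_exit
    rescaled <- TRUE
  }
  structure(
    list(
      raw = raw, clipped = clipped,
      any_clipped = any(clipped != raw), z_row_rescaled = rescaled
    ),
    class = "ci_rates"
  )
}

#' @export
print.ci_rates <- function(x, ...) {
  cat("<ci_rates>\n")
  print(rbind(raw = x$raw, clipped = x$clipped))
  if (x$z_row_rescaled) cat("note: Z-exit probabilities rescaled to sum 1\n")
  invisible(x)
}

#' Microscopic event probabilities for one agent's opinion change
#'
#' Maps the macroscopic reward constants to the four per-event switching
#' probabilities of the agent-based process: `p1` (X abandons to Z after
#' seeing an all-Y sample), `p2` (Y abandons to Z), `p3` (Z recruits to X),
#' `p4` (Z recruits to Y). The mapping `p1 = a12, p2 = a21, p3 = a11,
#' p4 = a22` makes the well-mixed agent process agree with the macroscopic
#' rates. In case 4 the abandonment probabilities, and in case 5 the
#' recruitment probabilities, are divided by the local committed fraction
#' `x~ + y~` of the focal agent's neighbourhood (set to 0 when no neighbour
#' is committed). Results are clipped to [0, 1].
#'
#' @inheritParams payoff_matrix
#' @param neighbor_x_fraction,neighbor_y_fraction Fractions of the focal
#'   agent's neighbours holding opinion X and Y; used by cases 4 and 5.
#' @return Named numeric vector `c(p1, p2, p3, p4)`.
#' @examples
#' micro_event_probabilities(payoff_params(0.2, 0.2, 0.2, 0.2), case_spec(4),
#'                           0.25, 0.25)
#' @export
micro_event_probabilities <- function(params, case,
                                      neighbor_x_fraction = 0,
                                      neighbor_y_fraction = 0) {
  xt <- neighbor_x_fraction
  yt <- neighbor_y_fraction
  if (any(c(xt, yt) < 0) || any(c(xt, yt) > 1) || any(xt + yt > 1 + 1e-9)) {
    abort("neighbour fractions must lie in [0, 1] and sum to at most 1")
  }
  pm <- micro_probs_vec(params, case, xt, yt)
  stats::setNames(as.numeric(pm[1, ]), c("p1", "p2", "p3", "p4"))
}

# Vectorised form used by the agent-based stepper: one row of (p1..p4) per
# supplied local (x~, y~) pair.
micro_probs_vec <- function(params, case, xt, yt) {
  n <- max(length(xt), length(yt))
  xt <- rep_len(xt, n)
  yt <- rep_len(yt, n)
  pm <- matrix(rep(c(params$a12, params$a21, params$a11, params$a22), each = n),
               nrow = n, dimnames = list(NULL, c("p1", "p2", "p3", "p4")))
  committed <- xt + yt
  inv <- ifelse(committed < .xy_singularity_tol, 0, 1 / committed)
  if (case$case_id == 4L) {
    pm[, c("p1", "p2")] <- pm[, c("p1", "p2")] * inv
  } else if (case$case_id == 5L) {
    pm[, c("p3", "p4")] <- pm[, c("p3", "p4")] * inv
  }
  pm[] <- pmin(pmax(pm, 0), 1)
  pm
}
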
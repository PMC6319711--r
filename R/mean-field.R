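#' One step of the deterministic mean-field dynamics
#'
#' Applies the macroscopic update of the evolutionary-game dynamics to a
#' population state: committed fractions lose mass through cross-inhibition
#' and gain mass through recruitment from the uncommitted pool,
#' \deqn{x' = x - \pi_{XZ} x + \pi_{ZX} (1 - x - y),}
#' \deqn{y' = y - \pi_{YZ} y + \pi_{ZY} (1 - x - y),}
#' with `z' = 1 - x' - y'`. The transition probabilities are the (possibly
#' clipped) values from [transition_rates()].
#'
#' @param state Population state `(x, y, z)` (or `(x, y)`).
#' @param params A [payoff_params()].
#' @param case A [case_spec()].
#' @return A named numeric state `c(x, y, z)` on the simplex.
#' @examples
#' mean_field_step(population_state(0.5, 0.3),
#'                 payoff_params(0.2, 0.2, 0.2, 0.2), case_spec(1))
#' @export
mean_field_step <- function(state, params, case) {
  xy <- as_xy(state)
  x <- xy[[1]]
  y <- xy[[2]]
  p <- transition_rates(params, case, c(x, y))$clipped
  z <- 1 - x - y
  x1 <- x - p[["pXZ"]] * x + p[["pZX"]] * z
  y1 <- y - p[["pYZ"]] * y + p[["pZY"]] * z
  c(x = x1, y = y1, z = 1 - x1 - y1)
}

# Unclipped one-step update (x, y) -> (x', y'): the literal polynomial /
# rational form of the dynamics, defined for arguments slightly outside the
# simplex. Used for differentiation; coincides with mean_field_step wherever
# no probability clipping triggers.
mean_field_step_raw <- function(xy, params, case) {
  x <- xy[[1]]
  y <- xy[[2]]
  f <- response_functions(case, c(x, y))
  z <- 1 - x - y
  c(
    x - params$a12 * f[["f2"]] * x * y + params$a11 * x * f[["f1"]] * z,
    y - params$a21 * f[["f3"]] * x * y + params$a22 * y * f[["f4"]] * z
  )
}

#' Iterate the mean-field dynamics
#'
#' Runs the deterministic population map for `T` steps, recording every
#' intermediate state (the process is studied through its per-step
#' population distribution).
#'
#' @param initial Initial population state.
#' @param T_steps Number of steps (0 or more; at most 1e5).
#' @inheritParams mean_field_step
#' @return A tibble of class `ci_trajectory` with columns `t, x, y, z` and
#'   `T_steps + 1` rows; `params` and `case` are attached as attributes.
#' @examples
#' tr <- iterate_mean_field(population_state(0.3, 0.4),
#'                          params = payoff_params(0.9, 0.2, 0.2, 0.2),
#'                          case = case_spec(1), T_steps = 50)
#' tail(tr)
#' @export
iterate_mean_field <- function(initial, T_steps, params, case) {
  T_steps <- as.integer(T_steps)
  if (is.na(T_steps) || T_steps < 0L) abort("T_steps must be a nonnegative integer")
  if (T_steps > 1e5) abort("T_steps is capped at 1e5")
  validate_state(initial)
  out <- matrix(NA_real_, nrow = T_steps + 1L, ncol = 2L)
  xy <- as_xy(initial)
  out[1L, ] <- xy
  if (T_steps > 0L) {
    for (t in seq_len(T_steps)) {
      s <- mean_field_step(xy, params, case)
      xy <- s[1:2]
      out[t + 1L, ] <- xy
    }
  }
  res <- tibble(
    t = 0:T_steps,
    x = out[, 1L],
    y = out[, 2L],
    z = 1 - out[, 1L] - out[, 2L]
  )
  structure(res,
    class = c("ci_trajectory", class(res)),
    params = params, case = case
  )
}

#' Single-agent opinion transition matrix
#'
#' Builds the 3x3 row-stochastic matrix governing one agent's opinion
#' distribution over (X, Y, Z) given the current population-level
#' transition probabilities. Direct X-Y transitions are structurally
#' impossible: committed agents can only fall back to the uncommitted
#' state, and uncommitted agents can only be recruited.
#'
#' @param rates A `ci_rates` object from [transition_rates()].
#' @return A 3x3 numeric matrix with rows summing to 1.
#' @examples
#' r <- transition_rates(payoff_params(0.2, 0.2, 0.2, 0.2), case_spec(1),
#'                       population_state(0.5, 0.3))
#' single_agent_matrix(r)
#' @export
single_agent_matrix <- function(rates) {
  p <- rates$clipped
  if (p[["pZX"]] + p[["pZY"]] > 1 + 1e-12) {
    abort("Z-exit probabilities exceed 1; rates must come from transition_rates()")
  }
  P <- matrix(0, 3, 3, dimnames = list(.OP_LABELS, .OP_LABELS))
  P["X", "X"] <- 1 - p[["pXZ"]]
  P["X", "Z"] <- p[["pXZ"]]
  P["Y", "Y"] <- 1 - p[["pYZ"]]
  P["Y", "Z"] <- p[["pYZ"]]
  P["Z", "X"] <- p[["pZX"]]
  P["Z", "Y"] <- p[["pZY"]]
  P["Z", "Z"] <- 1 - p[["pZX"]] - p[["pZY"]]
  P
}

#' Phase portrait of the mean-field map over the simplex
#'
#' Evaluates the one-step displacement `(x' - x, y' - y)` on a regular grid
#' over the closed simplex `x, y >= 0, x + y <= 1`, for quiver-style phase
#' portraits. Grid points on the Z-vertex use the singular-limit convention
#' of [response_functions()].
#'
#' @inheritParams mean_field_step
#' @param grid_resolution Number of grid points per axis (>= 2);
#'   `grid_resolution = 2` evaluates exactly the three vertices.
#' @return A tibble of class `ci_phase_portrait` with columns
#'   `x, y, dx, dy`.
#' @examples
#' phase_portrait(payoff_params(0.2, 0.2, 0.2, 0.2), case_spec(1), 6)
#' @export
phase_portrait <- function(params, case, grid_resolution = 21L) {
  grid_resolution <- as.integer(grid_resolution)
  if (is.na(grid_resolution) || grid_resolution < 2L) {
    abort("grid_resolution must be an integer >= 2")
  }
  g <- seq(0, 1, length.out = grid_resolution)
  pts <- tidyr::expand_grid(x = g, y = g)
  pts <- dplyr::filter(pts, .data$x + .data$y <= 1 + 1e-12)
  step1 <- purrr::pmap(pts, function(x, y) mean_field_step(c(x, y), params, case))
  res <- dplyr::mutate(pts,
    dx = purrr::map_dbl(step1, 1) - .data$x,
    dy = purrr::map_dbl(step1, 2) - .data$y
  )
  structure(res,
    class = c("ci_phase_portrait", class(res)),
    params = params, case = case
  )
}

#' Write a trajectory to CSV
#'
#' Writes `t,x,y,z` rows at full precision.
#'
#' @param trajectory A trajectory tibble (`t, x, y, z` columns).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(
    as.data.frame(trajectory)[, c("t", "x", "y", "z")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write a phase portrait to CSV
#'
#' Writes `x,y,dx,dy` rows.
#'
#' @param portrait A [phase_portrait()] tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_phase_portrait_csv <- function(portrait, path) {
  utils::write.csv(
    as.data.frame(portrait)[, c("x", "y", "dx", "dy")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
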
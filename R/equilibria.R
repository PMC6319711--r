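#' Jacobian of the mean-field map
#'
#' Differentiates the two-dimensional map `(x, y) -> (x', y')` of
#' [mean_field_step()] at a state. The default is a central finite
#' difference with step `h`; when a coordinate is within `h` of the simplex
#' boundary a one-sided difference is used (with a warning). For case 1 the
#' map is polynomial and an exact analytic Jacobian is available via
#' `method = "analytic"`.
#'
#' @inheritParams mean_field_step
#' @param h Finite-difference step (default 1e-6).
#' @param method `"numeric"` (any case) or `"analytic"` (case 1 only).
#' @return A 2x2 numeric matrix.
#' @examples
#' p <- payoff_params(0.2, 0.2, 0.2, 0.2)
#' jacobian_mean_field(p, case_spec(1), population_state(0, 0, 1),
#'                     method = "analytic")
#' @export
jacobian_mean_field <- function(params, case, state, h = 1e-6,
                                method = c("numeric", "analytic")) {
  method <- match.arg(method)
  xy <- as_xy(state)
  if (method == "analytic") {
    if (case$case_id != 1L) abort("the analytic Jacobian is implemented for case 1 only")
    return(jacobian_case1_analytic(params, xy))
  }
  if (h <= 0) abort("h must be positive")
  x <- xy[[1]]
  y <- xy[[2]]
  # Differentiate the raw (unclipped) update: it is the dynamics' defining
  # polynomial/rational map and extends smoothly past the simplex boundary,
  # so central differences are valid at vertices and edges. Clipping only
  # kicks in away from probability bounds, where the two maps coincide.
  step_fn <- function(x, y) mean_field_step_raw(c(x, y), params, case)
  # the 1/(x + y) responses (cases 4, 5) are singular on x + y = 0: keep
  # difference stencils on the side where x + y stays positive
  singular <- case$case_id %in% c(4L, 5L)
  J <- matrix(NA_real_, 2, 2)
  for (k in 1:2) {
    lo <- xy
    hi <- xy
    lo[k] <- lo[k] - h
    hi[k] <- hi[k] + h
    lo_ok <- !singular || sum(lo) > .xy_singularity_tol
    if (lo_ok) {
      J[, k] <- (step_fn(hi[1], hi[2]) - step_fn(lo[1], lo[2])) / (2 * h)
    } else {
      warn("state near the 1/(x+y) singularity: using a one-sided difference")
      J[, k] <- (step_fn(hi[1], hi[2]) - step_fn(x, y)) / h
    }
  }
  J
}

# Exact Jacobian of the case-1 (linear response) map, valid where no
# probability clipping triggers.
jacobian_case1_analytic <- function(params, xy) {
  x <- xy[[1]]
  y <- xy[[2]]
  a11 <- params$a11
  a12 <- params$a12
  a21 <- params$a21
  a22 <- params$a22
  matrix(c(
    1 - a12 * y + a11 * (1 - 2 * x - y), -(a12 + a11) * x,
    -(a21 + a22) * y, 1 - a21 * x + a22 * (1 - x - 2 * y)
  ), nrow = 2, byrow = TRUE)
}

# Residual of the fixed-point condition at (x, y), sup norm.
fixed_point_residual <- function(params, case, xy) {
  s <- mean_field_step(xy, params, case)
  max(abs(s[1:2] - xy))
}

#' Locate the equilibria of the mean-field dynamics
#'
#' The three simplex vertices (consensus on X, consensus on Y, everyone
#' uncommitted) are always fixed points and are returned first. In
#' addition, a mixed equilibrium of the form `(x, qx, 1 - (1+q)x)` may
#' exist in the interior, where the recruitment and cross-inhibition flows
#' for both opinions balance. For case 1 the balance equations are linear
#' in the state and solved in closed form; for all cases a damped-Newton
#' search of the fixed-point condition is run from a coarse interior grid,
#' and distinct converged roots are merged. Every returned point has
#' fixed-point residual at most `residual_tol`.
#'
#' @inheritParams mean_field_step
#' @param residual_tol Maximum allowed sup-norm fixed-point residual
#'   (default 1e-10).
#' @param grid_n Starts per axis for the multistart search (default 7).
#' @return A tibble with columns `label` (`vertex_X`, `vertex_Y`,
#'   `vertex_Z`, `interior`), `x, y, z`, `q` (the ratio y/x, `NA` where x is
#'   0), `feasible`, and `residual`.
#' @examples
#' find_equilibria(payoff_params(0.2, 0.2, 0.2, 0.2), case_spec(1))
#' @export
find_equilibria <- function(params, case, residual_tol = 1e-10, grid_n = 7L) {
  vertices <- tibble(
    label = c("vertex_X", "vertex_Y", "vertex_Z"),
    x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1)
  )
  vertices$q <- c(0, NA_real_, NA_real_)
  vertices$feasible <- TRUE
  vertices$residual <- purrr::map2_dbl(
    vertices$x, vertices$y,
    ~ fixed_point_residual(params, case, c(.x, .y))
  )

  roots <- list()
  cf <- case1_interior_closed_form(params, case)
  if (!is.null(cf)) roots <- c(roots, list(cf))
  roots <- c(roots, interior_newton_search(params, case, grid_n, residual_tol))

  interior <- dedupe_roots(roots)
  interior <- purrr::keep(interior, function(r) {
    fixed_point_residual(params, case, r) <= residual_tol &&
      max(abs(balance_residuals(params, case, r))) <= 1e-10 &&
      !is_vertex(r)
  })
  if (length(interior) > 0L) {
    int_tbl <- purrr::map_dfr(interior, function(r) {
      x <- r[[1]]
      y <- r[[2]]
      tibble(
        label = "interior", x = x, y = y, z = 1 - x - y,
        q = if (abs(x) > 1e-12) y / x else NA_real_,
        feasible = x >= -1e-12 && y >= -1e-12 && x + y <= 1 + 1e-12,
        residual = fixed_point_residual(params, case, c(x, y))
      )
    })
    out <- dplyr::bind_rows(vertices, int_tbl)
  } else {
    out <- vertices
  }
  structure(out, class = c("ci_equilibrium_set", class(out)),
            params = params, case = case)
}

# Closed-form interior equilibrium for case 1: the balance conditions
# a12 y = a11 z and a21 x = a22 z give x : y : z = a22/a21 : a11/a12 : 1.
# NULL when a denominator vanishes (degenerate reward structure) or the
# case has state-dependent responses; those fall through to the numeric
# search.
case1_interior_closed_form <- function(params, case) {
  # cases 2 and 3 with unit group sizes reduce to case 1 exactly
  reduces <- case$case_id == 1L ||
    (case$case_id == 2L && case$m == 1L) ||
    (case$case_id == 3L && case$d == 1L)
  if (!reduces) return(NULL)
  if (params$a12 <= 0 || params$a21 <= 0) return(NULL)
  rx <- params$a22 / params$a21
  ry <- params$a11 / params$a12
  z <- 1 / (1 + rx + ry)
  c(x = rx * z, y = ry * z)
}

# Interior balance residuals with the common factors x and y divided out:
# at an interior equilibrium both recruitment/inhibition flows balance,
#   a12 f2 y = a11 f1 z  and  a21 f3 x = a22 f4 z.
# Dividing out x and y removes the degenerate vertex factors, so roots of
# this system are well conditioned even when the raw fixed-point residual
# is flat near a vertex.
balance_residuals <- function(params, case, xy) {
  x <- xy[[1]]
  y <- xy[[2]]
  f <- response_functions(case, c(x, y))
  z <- 1 - x - y
  c(
    params$a12 * f[["f2"]] * y - params$a11 * f[["f1"]] * z,
    params$a21 * f[["f3"]] * x - params$a22 * f[["f4"]] * z
  )
}

interior_newton_search <- function(params, case, grid_n, residual_tol) {
  g <- seq(0.05, 0.95, length.out = grid_n)
  starts <- tidyr::expand_grid(x = g, y = g)
  starts <- dplyr::filter(starts, .data$x + .data$y <= 0.98)
  starts <- rbind(as.matrix(starts), c(1 / 3, 1 / 3))
  found <- list()
  for (i in seq_len(nrow(starts))) {
    r <- newton_balance_root(params, case, starts[i, ])
    if (!is.null(r)) found <- c(found, list(r))
  }
  found
}

# Damped Newton iteration on the divided balance system, constrained to
# the closed simplex. Returns the root or NULL.
newton_balance_root <- function(params, case, xy, max_iter = 80L) {
  xy <- as.numeric(xy)
  G <- function(v) balance_residuals(params, case, v)
  gv <- G(xy)
  hd <- 1e-7
  for (iter in seq_len(max_iter)) {
    if (max(abs(gv)) <= 1e-13) return(xy)
    J <- matrix(NA_real_, 2, 2)
    for (k in 1:2) {
      hi <- xy
      lo <- xy
      hi[k] <- hi[k] + hd
      lo[k] <- lo[k] - hd
      J[, k] <- (G(hi) - G(lo)) / (2 * hd)
    }
    if (!all(is.finite(J)) || abs(det(J)) < 1e-16) return(NULL)
    delta <- tryCatch(solve(J, -gv), error = function(e) NULL)
    if (is.null(delta)) return(NULL)
    step_len <- 1
    improved <- FALSE
    for (k in 1:10) {
      cand <- xy + step_len * delta
      cand <- pmin(pmax(cand, 1e-9), 1 - 1e-9)
      if (cand[1] + cand[2] > 1 - 1e-9) {
        cand <- cand / (cand[1] + cand[2]) * (1 - 1e-9)
      }
      gc_ <- G(cand)
      if (max(abs(gc_)) < max(abs(gv))) {
        xy <- cand
        gv <- gc_
        improved <- TRUE
        break
      }
      step_len <- step_len / 2
    }
    if (!improved) return(NULL)
  }
  if (max(abs(gv)) <= 1e-13) xy else NULL
}

dedupe_roots <- function(roots, tol = 1e-7) {
  out <- list()
  for (r in roots) {
    dup <- any(vapply(out, function(o) max(abs(o - r)) < tol, logical(1)))
    if (!dup) out <- c(out, list(r))
  }
  out
}

is_vertex <- function(xy, tol = 1e-6) {
  v <- list(c(1, 0), c(0, 1), c(0, 0))
  any(vapply(v, function(u) max(abs(u - xy)) < tol, logical(1)))
}

#' Classify the stability of a fixed point
#'
#' Evaluates the Jacobian of the mean-field map at an equilibrium and
#' classifies it by the spectral radius: `stable` when both eigenvalue
#' moduli are below `1 - tolerance`, `unstable` when the largest modulus
#' exceeds `1 + tolerance`, `marginal` otherwise (the discrete-time linear
#' stability criterion).
#'
#' @inheritParams mean_field_step
#' @param equilibrium A state `(x, y, z)` (or one row of
#'   [find_equilibria()] output).
#' @param tolerance Half-width of the marginal band around modulus 1
#'   (default 1e-8).
#' @param h Finite-difference step for the Jacobian.
#' @return An object of class `ci_stability`: list with `state`,
#'   `jacobian`, `eigenvalues` (complex pair), `moduli`, `classification`,
#'   `tolerance`.
#' @examples
#' p <- payoff_params(0.2, 0.2, 0.2, 0.2)
#' classify_stability(p, case_spec(1), population_state(0, 0, 1))
#' @export
classify_stability <- function(params, case, equilibrium, tolerance = 1e-8,
                               h = 1e-6) {
  if (is.data.frame(equilibrium)) {
    equilibrium <- c(
      x = equilibrium$x[[1]], y = equilibrium$y[[1]], z = equilibrium$z[[1]]
    )
  }
  xy <- as_xy(equilibrium)
  if (fixed_point_residual(params, case, xy) > 1e-8) {
    abort("classify_stability requires a fixed point (residual <= 1e-8)")
  }
  J <- suppressWarnings(jacobian_mean_field(params, case, xy, h = h))
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)
  moduli <- Mod(ev)
  rho <- max(moduli)
  classification <- if (rho < 1 - tolerance) {
    "stable"
  } else if (rho > 1 + tolerance) {
    "unstable"
  } else {
    "marginal"
  }
  structure(
    list(
      state = c(x = xy[[1]], y = xy[[2]], z = 1 - sum(xy)),
      jacobian = J, eigenvalues = ev, moduli = moduli,
      classification = classification, tolerance = tolerance
    ),
    class = "ci_stability"
  )
}

#' @export
print.ci_stability <- function(x, ...) {
  cat(sprintf(
    "<ci_stability> (%0.6g, %0.6g, %0.6g): %s (|lambda| = %.6g, %.6g)\n",
    x$state[[1]], x$state[[2]], x$state[[3]], x$classification,
    x$moduli[[1]], x$moduli[[2]]
  ))
  invisible(x)
}

#' Full equilibrium and stability analysis
#'
#' Locates all fixed points of the mean-field dynamics and classifies each
#' by its Jacobian eigenvalues. The result supports [tidy()], [glance()]
#' and [ggplot2::autoplot()].
#'
#' @inheritParams find_equilibria
#' @inheritParams classify_stability
#' @return An object of class `ci_equilibria`.
#' @examples
#' eq <- equilibrium_analysis(payoff_params(0.9, 0.2, 0.2, 0.2), case_spec(1))
#' tidy(eq)
#' glance(eq)
#' @export
equilibrium_analysis <- function(params, case, tolerance = 1e-8, h = 1e-6,
                                 residual_tol = 1e-10, grid_n = 7L) {
  eq <- find_equilibria(params, case, residual_tol = residual_tol, grid_n = grid_n)
  reports <- purrr::pmap(
    list(eq$x, eq$y),
    function(x, y) classify_stability(params, case, c(x, y, 1 - x - y),
                                      tolerance = tolerance, h = h)
  )
  tbl <- dplyr::mutate(as_tibble(eq),
    lambda1 = vapply(reports, function(r) r$eigenvalues[[1]], complex(1)),
    lambda2 = vapply(reports, function(r) r$eigenvalues[[2]], complex(1)),
    lambda1_abs = purrr::map_dbl(reports, ~ .x$moduli[[1]]),
    lambda2_abs = purrr::map_dbl(reports, ~ .x$moduli[[2]]),
    classification = purrr::map_chr(reports, "classification")
  )
  structure(
    list(table = tbl, reports = reports, params = params, case = case,
         tolerance = tolerance),
    class = "ci_equilibria"
  )
}

#' @export
print.ci_equilibria <- function(x, ...) {
  cat(sprintf("<ci_equilibria> case %d, %d equilibria\n",
              x$case$case_id, nrow(x$table)))
  print(dplyr::select(
    x$table, "label", "x", "y", "z",
    "lambda1_abs", "lambda2_abs", "classification"
  ))
  invisible(x)
}

#' @rdname equilibrium_analysis
#' @param x A `ci_equilibria` object.
#' @param ... Unused.
#' @export
tidy.ci_equilibria <- function(x, ...) {
  x$table
}

#' @rdname equilibrium_analysis
#' @export
glance.ci_equilibria <- function(x, ...) {
  tibble(
    case_id = x$case$case_id,
    n_equilibria = nrow(x$table),
    n_interior = sum(x$table$label == "interior"),
    n_stable = sum(x$table$classification == "stable"),
    n_unstable = sum(x$table$classification == "unstable"),
    n_marginal = sum(x$table$classification == "marginal"),
    max_residual = max(x$table$residual)
  )
}

#' Write an equilibrium report to CSV
#'
#' One row per equilibrium with the reward constants, coordinates, the
#' interior ratio q, eigenvalue moduli and the stability classification.
#'
#' @param analysis A [equilibrium_analysis()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_equilibrium_csv <- function(analysis, path) {
  tbl <- analysis$table
  out <- data.frame(
    case = analysis$case$case_id,
    a11 = analysis$params$a11, a12 = analysis$params$a12,
    a21 = analysis$params$a21, a22 = analysis$params$a22,
    label = tbl$label, x = tbl$x, y = tbl$y, z = tbl$z, q = tbl$q,
    lambda1_abs = tbl$lambda1_abs, lambda2_abs = tbl$lambda2_abs,
    classification = tbl$classification
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
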
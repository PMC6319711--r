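#' Reward matrices used in the paired comparison study
#'
#' The four payoff parameterisations used by the trajectory comparison
#' experiment: a fully symmetric one (equally favourable options), one
#' where recruitment to X dominates, a strong symmetric one, and an
#' asymmetric one with strong cross-inhibition of X.
#'
#' @return A named list of [payoff_params()] objects.
#' @examples
#' names(study_payoffs())
#' @export
study_payoffs <- function() {
  list(
    symmetric      = payoff_params(0.2, 0.2, 0.2, 0.2),
    x_recruitment  = payoff_params(0.9, 0.2, 0.2, 0.2),
    strong_mixed   = payoff_params(0.9, 0.4, 0.4, 0.9),
    asymmetric     = payoff_params(0.1, 0.5, 0.3, 0.6)
  )
}

#' Final collective decision of a run
#'
#' Labels the final state of a trajectory (or a bare state vector) by the
#' opinion whose share reaches `threshold`; `"mixed"` when no opinion
#' does. A threshold above 1/3 guarantees at most one qualifying opinion.
#'
#' @param state A population state `(x, y, z)`, or a trajectory tibble with
#'   `x, y, z` columns (the last row is used).
#' @param threshold Decision threshold in (1/3, 1].
#' @return One of `"X"`, `"Y"`, `"Z"`, `"mixed"`.
#' @examples
#' final_decision(c(0.97, 0.01, 0.02))
#' @export
final_decision <- function(state, threshold = 0.5) {
  if (threshold <= 1 / 3 || threshold > 1) abort("threshold must lie in (1/3, 1]")
  if (is.data.frame(state)) {
    last <- state[nrow(state), ]
    state <- c(last$x, last$y, last$z)
  }
  shares <- as.numeric(state[1:3])
  hit <- which(shares >= threshold)
  if (length(hit) == 0L) "mixed" else .OP_LABELS[[hit[[1]]]]
}

# Builds a ci_graph from a lightweight spec list, an igraph object, or a
# ready-made ci_graph.
build_graph <- function(graph_spec, min_degree = 1L, seed = NULL,
                        max_attempts = 1000L) {
  if (inherits(graph_spec, "ci_graph")) return(graph_spec)
  if (inherits(graph_spec, "igraph")) return(new_ci_graph(graph_spec))
  type <- graph_spec$type %||% "er"
  switch(type,
    er = er_graph(graph_spec$N, graph_spec$p %||% 0.2,
                  min_degree = min_degree, seed = seed,
                  max_attempts = max_attempts),
    ws = ws_graph(graph_spec$N, graph_spec$K, graph_spec$rewire_p %||% 0.1,
                  min_degree = min_degree, seed = seed,
                  max_attempts = max_attempts),
    complete = {
      g <- igraph::make_full_graph(graph_spec$N)
      new_ci_graph(g, "complete", list(N = graph_spec$N))
    },
    abort(sprintf("unknown graph type '%s'", type))
  )
}

#' Paired comparison of the agent-based and mean-field processes
#'
#' Runs the stochastic agent-based process on a graph and the
#' deterministic mean-field map from matched initial conditions (the
#' mean-field start is the exact initial opinion fractions of the agent
#' population) and pairs the two trajectories step by step.
#'
#' @inheritParams run_abm
#' @param params A [payoff_params()].
#' @param case A [case_spec()].
#' @param graph_spec A graph specification: a `ci_graph`, an igraph object,
#'   or a list such as `list(type = "er", N = 1000, p = 0.2)` or
#'   `list(type = "ws", N = 100, K = 8, rewire_p = 0.1)`.
#' @param T_steps Number of steps for both processes.
#' @param seed Integer seed; graph generation, initial opinions and the
#'   agent process use deterministically derived child seeds.
#' @param threshold Decision threshold for [final_decision()].
#' @param initial_opinions Optional integer opinion vector used as the
#'   shared initial condition; drawn uniformly when `NULL`.
#' @return An object of class `ci_comparison`: list with `trajectories`
#'   (long tibble `source, t, x, y, z`), `discrepancy` (tibble `t, dev`
#'   with the per-step maximum absolute share difference), and
#'   `final_decisions`.
#' @examples
#' cmp <- compare_processes(payoff_params(0.9, 0.2, 0.2, 0.2), case_spec(1),
#'                          graph_spec = list(type = "er", N = 200, p = 0.2),
#'                          T_steps = 50, seed = 7)
#' glance(cmp)
#' @export
compare_processes <- function(params, case,
                              graph_spec = list(type = "er", N = 1000, p = 0.2),
                              T_steps = 200, seed = NULL, threshold = 0.5,
                              initial_opinions = NULL) {
  if (T_steps < 1L) abort("T_steps must be >= 1")
  card <- case_cardinalities(case)
  graph <- build_graph(graph_spec, min_degree = max(card$M, card$D),
                       seed = if (is.null(seed)) NULL else child_seed(seed, 1))
  w0 <- initial_opinions %||%
    init_opinions(graph$n, seed = if (is.null(seed)) NULL else child_seed(seed, 2))
  abm <- run_abm(graph, w0, params, case, T_steps,
                 seed = if (is.null(seed)) NULL else child_seed(seed, 3))
  mf <- iterate_mean_field(opinion_fractions(w0), T_steps, params, case)
  long <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(mf)[, c("t", "x", "y", "z")], source = "mf"),
    dplyr::mutate(as_tibble(abm)[, c("t", "x", "y", "z")], source = "abm")
  )
  long <- dplyr::relocate(long, "source")
  dev <- pmax(
    abs(mf$x - abm$x), abs(mf$y - abm$y), abs(mf$z - abm$z)
  )
  structure(
    list(
      trajectories = long,
      discrepancy = tibble(t = mf$t, dev = dev),
      final_decisions = c(
        mf = final_decision(mf, threshold),
        abm = final_decision(abm, threshold)
      ),
      params = params, case = case, seed = seed,
      graph = graph$descriptor, T_steps = T_steps
    ),
    class = "ci_comparison"
  )
}

#' @export
print.ci_comparison <- function(x, ...) {
  cat(sprintf(
    "<ci_comparison> case %d, T = %d: mean dev %.4f, decisions mf = %s / abm = %s\n",
    x$case$case_id, x$T_steps, mean(x$discrepancy$dev),
    x$final_decisions[["mf"]], x$final_decisions[["abm"]]
  ))
  invisible(x)
}

#' @rdname compare_processes
#' @param x A `ci_comparison` object.
#' @param ... Unused.
#' @export
tidy.ci_comparison <- function(x, ...) {
  x$trajectories
}

#' @rdname compare_processes
#' @export
glance.ci_comparison <- function(x, ...) {
  tibble(
    case_id = x$case$case_id,
    T_steps = x$T_steps,
    mean_dev = mean(x$discrepancy$dev),
    max_dev = max(x$discrepancy$dev),
    decision_mf = x$final_decisions[["mf"]],
    decision_abm = x$final_decisions[["abm"]],
    agreement = x$final_decisions[["mf"]] == x$final_decisions[["abm"]] &&
      x$final_decisions[["mf"]] != "mixed"
  )
}

#' Reward-ratio sweep of the final X share
#'
#' Sweeps the two reward ratios that govern the balance between
#' cross-inhibition and recruitment — `ratio_xz = a12 / a11` (inhibition
#' of X relative to recruitment into X) and `ratio_yz = a21 / a22` — and
#' records the final X share of the chosen process started from uniform
#' random opinions, averaged over replicates. Each replicate draws a fresh
#' graph and initial configuration from derived seeds.
#'
#' @param ratio_xz,ratio_yz Positive ratio grids.
#' @param base_a11,base_a22 Baseline recruitment rewards; the swept
#'   constants are `a12 = ratio_xz * base_a11` and
#'   `a21 = ratio_yz * base_a22`.
#' @inheritParams compare_processes
#' @param replicates Replicate runs per grid cell.
#' @param mode `"abm"` (default) or `"meanfield"` (the mean-field map from
#'   a random interior start).
#' @return A tibble of class `ci_sweep` with columns
#'   `ratio_xz, ratio_yz, final_x_fraction, n_reps, clip_warning`.
#' @export
ratio_sweep <- function(ratio_xz = seq(0.1, 2, length.out = 21),
                        ratio_yz = seq(0.1, 2, length.out = 21),
                        base_a11 = 0.5, base_a22 = 0.5,
                        case = case_spec(1),
                        graph_spec = list(type = "er", N = 1000, p = 0.2),
                        T_steps = 200, replicates = 1L, seed = NULL,
                        mode = c("abm", "meanfield")) {
  mode <- match.arg(mode)
  if (any(ratio_xz <= 0) || any(ratio_yz <= 0)) abort("ratios must be positive")
  if (replicates < 1L) abort("replicates must be >= 1")
  grid <- tidyr::expand_grid(ratio_xz = ratio_xz, ratio_yz = ratio_yz)
  card <- case_cardinalities(case)
  min_deg <- max(card$M, card$D)
  cells <- purrr::pmap_dfr(
    list(grid$ratio_xz, grid$ratio_yz, seq_len(nrow(grid))),
    function(rxz, ryz, cell_idx) {
      params <- suppressWarnings(payoff_params(
        a11 = base_a11, a12 = rxz * base_a11,
        a21 = ryz * base_a22, a22 = base_a22
      ))
      clip_warning <- any(unlist(params) > 1)
      finals <- vapply(seq_len(replicates), function(r) {
        s <- if (is.null(seed)) NULL else child_seed(seed, cell_idx, r)
        if (mode == "abm") {
          graph <- build_graph(graph_spec, min_degree = min_deg,
                               seed = if (is.null(s)) NULL else child_seed(s, 1))
          w0 <- init_opinions(graph$n,
                              seed = if (is.null(s)) NULL else child_seed(s, 2))
          tr <- run_abm(graph, w0, params, case, T_steps,
                        seed = if (is.null(s)) NULL else child_seed(s, 3))
          tr$x[[nrow(tr)]]
        } else {
          w0 <- with_seed_if(s, {
            u <- stats::runif(3)
            u / sum(u)
          })
          tr <- iterate_mean_field(c(x = w0[1], y = w0[2], z = w0[3]),
                                   T_steps, params, case)
          tr$x[[nrow(tr)]]
        }
      }, numeric(1))
      tibble(
        ratio_xz = rxz, ratio_yz = ryz,
        final_x_fraction = mean(finals),
        n_reps = replicates, clip_warning = clip_warning
      )
    }
  )
  structure(cells, class = c("ci_sweep", class(cells)),
            base_a11 = base_a11, base_a22 = base_a22,
            case = case, mode = mode, seed = seed)
}

#' Small-world agreement study
#'
#' Measures how often the agent-based process and the mean-field map reach
#' the same final decision on Watts–Strogatz networks, as a function of the
#' node degree `K = m + j` and of the composite reward ratio
#' `a11 a21 / (a22 a12)` (large when opinion X is much more rewarding than
#' Y). Each replication draws fresh i.i.d. rewards, a fresh network and
#' fresh uniform initial opinions from derived seeds; agreement requires
#' both processes to reach the same non-mixed decision.
#'
#' @param case_id Consensus mechanism, 1..5.
#' @param m Group-size parameter: committed-side sample size in case 2,
#'   uncommitted-side in case 3; also the baseline for `K = m + j`.
#' @param j_values Increments over `m` defining the degrees `K = m + j`
#'   (odd K values are rounded up to the next even lattice degree).
#' @param rewire_p Watts–Strogatz rewiring probability.
#' @param N Number of agents.
#' @param T_steps Steps per process.
#' @param replications Replications per K.
#' @param reward_sampler Function `n -> n` draws for each reward constant;
#'   defaults to Uniform(0.05, 0.95) (bounded away from 0 so the composite
#'   ratio stays finite).
#' @param ratio_breaks Logarithmic bin edges for the composite reward
#'   ratio.
#' @param seed Integer seed.
#' @param threshold Decision threshold for [final_decision()].
#' @return A tibble of class `ci_agreement` with columns
#'   `case, K, ratio_bin_low, ratio_bin_high, agreement_fraction, n_reps`;
#'   the per-replication table is attached as attribute `"runs"`.
#' @export
smallworld_agreement <- function(case_id = 1, m = 3,
                                 j_values = c(1:10, 15, 20),
                                 rewire_p = 0.1, N = 100, T_steps = 200,
                                 replications = 100,
                                 reward_sampler = function(n) stats::runif(n, 0.05, 0.95),
                                 ratio_breaks = 10^seq(-3, 3, by = 0.5),
                                 seed = NULL, threshold = 0.5) {
  if (replications < 1L) abort("replications must be >= 1")
  case <- switch(as.integer(case_id),
    case_spec(1), case_spec(2, m = m), case_spec(3, m = 1, d = m),
    case_spec(4), case_spec(5)
  )
  K_values <- vapply(j_values, function(j) {
    K <- m + j
    if (K %% 2L == 1L) K + 1L else K
  }, numeric(1))
  if (any(K_values >= N)) abort("every K = m + j must be below N")
  runs <- purrr::map_dfr(seq_along(K_values), function(ki) {
    K <- K_values[[ki]]
    purrr::map_dfr(seq_len(replications), function(r) {
      s <- if (is.null(seed)) NULL else child_seed(seed, ki, r)
      a <- with_seed_if(s, reward_sampler(4))
      params <- suppressWarnings(payoff_params(a[1], a[2], a[3], a[4]))
      cmp <- compare_processes(
        params, case,
        graph_spec = list(type = "ws", N = N, K = K, rewire_p = rewire_p),
        T_steps = T_steps,
        seed = if (is.null(s)) NULL else child_seed(s, 99),
        threshold = threshold
      )
      tibble(
        K = K, rep = r,
        a11 = a[1], a12 = a[2], a21 = a[3], a22 = a[4],
        reward_ratio = (a[1] * a[3]) / (a[4] * a[2]),
        decision_mf = cmp$final_decisions[["mf"]],
        decision_abm = cmp$final_decisions[["abm"]],
        agree = cmp$final_decisions[["mf"]] == cmp$final_decisions[["abm"]] &&
          cmp$final_decisions[["mf"]] != "mixed"
      )
    })
  })
  runs$bin <- cut(runs$reward_ratio, breaks = ratio_breaks,
                  include.lowest = TRUE)
  binned <- dplyr::summarise(
    dplyr::group_by(runs, .data$K, .data$bin),
    agreement_fraction = mean(.data$agree),
    n_reps = dplyr::n(),
    .groups = "drop"
  )
  edges <- ratio_breaks
  bin_idx <- as.integer(binned$bin)
  out <- tibble(
    case = case$case_id,
    K = binned$K,
    ratio_bin_low = edges[bin_idx],
    ratio_bin_high = edges[bin_idx + 1L],
    agreement_fraction = binned$agreement_fraction,
    n_reps = binned$n_reps
  )
  structure(out, class = c("ci_agreement", class(out)),
            runs = runs, case = case, seed = seed, N = N,
            T_steps = T_steps, rewire_p = rewire_p)
}
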
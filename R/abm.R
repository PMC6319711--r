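#' Initial opinion configuration
#'
#' Assigns each of `N` agents an opinion drawn independently and uniformly
#' from \{X, Y, Z\}. Opinions are coded as integers 1 (X), 2 (Y), 3 (Z);
#' use [opinion_labels()] for the character form.
#'
#' @param N Number of agents.
#' @param seed Optional integer seed for reproducible draws.
#' @return An integer vector of length `N` with values in 1..3.
#' @examples
#' table(opinion_labels(init_opinions(300, seed = 1)))
#' @export
init_opinions <- function(N, seed = NULL) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) abort("N must be an integer >= 1")
  with_seed_if(seed, sample.int(3L, N, replace = TRUE))
}

#' @rdname init_opinions
#' @param opinions Integer opinion codes.
#' @export
opinion_labels <- function(opinions) {
  .OP_LABELS[opinions]
}

#' @rdname init_opinions
#' @export
opinion_counts <- function(opinions) {
  cnt <- tabulate(opinions, nbins = 3L)
  c(nX = cnt[[1]], nY = cnt[[2]], nZ = cnt[[3]])
}

#' @rdname init_opinions
#' @export
opinion_fractions <- function(opinions) {
  cnt <- opinion_counts(opinions) / length(opinions)
  c(x = cnt[["nX"]], y = cnt[["nY"]], z = cnt[["nZ"]])
}

# Per-agent local committed fractions over the full neighbourhood (focal
# agent excluded): columns x~ and y~.
local_committed_fractions <- function(graph, opinions) {
  seg <- rep.int(seq_len(graph$n), graph$deg)
  nb_state <- opinions[graph$nbr]
  cx <- rowsum((nb_state == .OP_X) + 0, seg, reorder = TRUE)[, 1]
  cy <- rowsum((nb_state == .OP_Y) + 0, seg, reorder = TRUE)[, 1]
  cbind(xt = cx / graph$deg, yt = cy / graph$deg)
}

#' One synchronous step of the quantised-consensus process
#'
#' Every agent evaluates its update rule against the time-t configuration:
#' a committed agent samples `|M|` distinct neighbours and abandons its
#' opinion (switches to Z) with probability p1 (or p2) only if all sampled
#' neighbours hold the opposing opinion; an uncommitted agent samples `|D|`
#' distinct neighbours and adopts X with probability p3 if they are all X,
#' or Y with probability p4 if they are all Y. Sample-set sizes follow the
#' active case, and in cases 4 and 5 the event probabilities depend on the
#' local fraction of committed neighbours. Direct X to Y transitions never
#' occur. Consumes the ambient RNG stream; seed at the [run_abm()] level.
#'
#' @param graph A `ci_graph`.
#' @param opinions Integer opinion vector (one entry per node).
#' @param params A [payoff_params()].
#' @param case A [case_spec()].
#' @return The opinion vector at time t + 1.
#' @export
abm_step <- function(graph, opinions, params, case) {
  n <- graph$n
  if (length(opinions) != n) abort("opinions must have one entry per node")
  card <- case_cardinalities(case)
  kmax <- max(card$M, card$D)
  if (min(graph$deg) < kmax) {
    bad <- which(graph$deg < kmax)[[1]]
    abort(sprintf(
      "node %d has degree %d but the case requires at least %d neighbours",
      bad, graph$deg[[bad]], kmax
    ))
  }

  if (case$case_id %in% c(4L, 5L)) {
    loc <- local_committed_fractions(graph, opinions)
    pm <- micro_probs_vec(params, case, loc[, "xt"], loc[, "yt"])
  } else {
    pm <- micro_probs_vec(params, case, 0, 0)
    pm <- pm[rep(1L, n), , drop = FALSE]
  }

  all_x <- all_y <- logical(n)
  if (card$M == 1L && card$D == 1L) {
    # single-neighbour sampling, fully vectorised
    u <- stats::runif(n)
    pos <- graph$ptr[seq_len(n)] + pmin(floor(u * graph$deg), graph$deg - 1L) + 1L
    picked <- opinions[graph$nbr[pos]]
    all_x <- picked == .OP_X
    all_y <- picked == .OP_Y
  } else {
    k_needed <- ifelse(opinions == .OP_Z, card$D, card$M)
    for (i in seq_len(n)) {
      k <- k_needed[[i]]
      idx <- if (k == 1L) {
        sample.int(graph$deg[[i]], 1L)
      } else {
        sample.int(graph$deg[[i]], k)
      }
      st <- opinions[graph$nbr[graph$ptr[[i]] + idx]]
      all_x[[i]] <- all(st == .OP_X)
      all_y[[i]] <- all(st == .OP_Y)
    }
  }

  v <- stats::runif(n)
  out <- opinions
  is_x <- opinions == .OP_X
  is_y <- opinions == .OP_Y
  is_z <- opinions == .OP_Z
  out[is_x & all_y & v < pm[, "p1"]] <- .OP_Z
  out[is_y & all_x & v < pm[, "p2"]] <- .OP_Z
  out[is_z & all_x & v < pm[, "p3"]] <- .OP_X
  out[is_z & all_y & v < pm[, "p4"]] <- .OP_Y
  out
}

# Random-sequential variant: agents update one at a time, in a random
# order, each against the current configuration.
abm_step_async <- function(graph, opinions, params, case) {
  n <- graph$n
  card <- case_cardinalities(case)
  order_ <- sample.int(n)
  w <- opinions
  for (i in order_) {
    nbrs <- graph$nbr[(graph$ptr[[i]] + 1L):graph$ptr[[i + 1L]]]
    st_nb <- w[nbrs]
    if (case$case_id %in% c(4L, 5L)) {
      pm <- micro_probs_vec(params, case,
                            mean(st_nb == .OP_X), mean(st_nb == .OP_Y))
    } else {
      pm <- micro_probs_vec(params, case, 0, 0)
    }
    k <- if (w[[i]] == .OP_Z) card$D else card$M
    picked <- st_nb[sample.int(length(nbrs), k)]
    v <- stats::runif(1)
    if (w[[i]] == .OP_X && all(picked == .OP_Y) && v < pm[1, "p1"]) {
      w[[i]] <- .OP_Z
    } else if (w[[i]] == .OP_Y && all(picked == .OP_X) && v < pm[1, "p2"]) {
      w[[i]] <- .OP_Z
    } else if (w[[i]] == .OP_Z) {
      if (all(picked == .OP_X) && v < pm[1, "p3"]) {
        w[[i]] <- .OP_X
      } else if (all(picked == .OP_Y) && v < pm[1, "p4"]) {
        w[[i]] <- .OP_Y
      }
    }
  }
  w
}

#' Run the agent-based consensus process
#'
#' Simulates the quantised-consensus process for `T_steps` steps on an
#' explicit graph, recording the opinion counts at every step (including
#' the initial one). Runs are bit-reproducible given the seed.
#'
#' @inheritParams abm_step
#' @param initial Integer opinion vector at t = 0 (see [init_opinions()]).
#' @param T_steps Number of steps (>= 0).
#' @param seed Optional integer seed.
#' @param update `"synchronous"` (default: all agents update against the
#'   time-t snapshot) or `"asynchronous"` (random-sequential).
#' @return A tibble of class `ci_abm_trajectory` with columns
#'   `t, nX, nY, nZ, x, y, z`; the seed, graph descriptor, params and case
#'   are attached as attributes.
#' @examples
#' g <- er_graph(100, 0.2, seed = 1)
#' w0 <- init_opinions(100, seed = 2)
#' run_abm(g, w0, payoff_params(0.9, 0.2, 0.2, 0.2), case_spec(1),
#'         T_steps = 20, seed = 3)
#' @export
run_abm <- function(graph, initial, params, case, T_steps, seed = NULL,
                    update = c("synchronous", "asynchronous")) {
  update <- match.arg(update)
  T_steps <- as.integer(T_steps)
  if (is.na(T_steps) || T_steps < 0L) abort("T_steps must be a nonnegative integer")
  if (length(initial) != graph$n) abort("initial opinions must match the graph size")
  card <- case_cardinalities(case)
  kmax <- max(card$M, card$D)
  if (min(graph$deg) < kmax) {
    bad <- which(graph$deg < kmax)[[1]]
    abort(sprintf(
      "node %d has degree %d but case %d requires at least %d neighbours",
      bad, graph$deg[[bad]], case$case_id, kmax
    ))
  }
  counts <- matrix(NA_integer_, nrow = T_steps + 1L, ncol = 3L)
  counts[1L, ] <- tabulate(initial, nbins = 3L)
  w <- initial
  stepper <- if (update == "synchronous") abm_step else abm_step_async
  with_seed_if(seed, {
    for (t in seq_len(T_steps)) {
      w <- stepper(graph, w, params, case)
      counts[t + 1L, ] <- tabulate(w, nbins = 3L)
    }
  })
  res <- tibble(
    t = 0:T_steps,
    nX = counts[, 1L], nY = counts[, 2L], nZ = counts[, 3L],
    x = counts[, 1L] / graph$n,
    y = counts[, 2L] / graph$n,
    z = counts[, 3L] / graph$n
  )
  structure(res,
    class = c("ci_abm_trajectory", class(res)),
    seed = seed, graph = graph$descriptor, params = params, case = case,
    final_opinions = w, update = update
  )
}

#' Write an agent-based trajectory to CSV
#'
#' Writes `t,nX,nY,nZ,x,y,z` rows.
#'
#' @param trajectory A [run_abm()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_abm_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(
    as.data.frame(trajectory)[, c("t", "nX", "nY", "nZ", "x", "y", "z")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
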
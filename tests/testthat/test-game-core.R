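test_that("constructors validate payoffs and cases", {
  expect_error(payoff_params(0.2, -0.1, 0.2, 0.2), "a12")
  expect_warning(payoff_params(1.5, 0.2, 0.2, 0.2), "clip")
  expect_error(case_spec(6), "case_id")
  expect_error(case_spec(1, m = 2), "m and d")
  expect_error(case_spec(4, d = 2), "m and d")
  expect_error(case_spec(2, m = 0), "m must be")
  expect_error(case_spec(2, m = 3, d = 2), "d must be 1")
  # case 3's uncommitted-side group size defaults to m
  cs3 <- case_spec(3, m = 4)
  expect_identical(cs3$d, 4L)
  expect_error(population_state(0.7, 0.5), "lie in")
  expect_error(population_state(0.5, 0.2, 0.4), "sum")
})

test_that("response functions match their closed forms per case", {
  s <- population_state(0.5, 0.2, 0.3)
  expect_equal(unname(response_functions(case_spec(1), s)), c(1, 1, 1, 1))
  # unit group sizes reduce every power law to the linear case
  expect_equal(unname(response_functions(case_spec(2, m = 1), s)), c(1, 1, 1, 1))
  expect_equal(unname(response_functions(case_spec(3, m = 1), s)), c(1, 1, 1, 1))
  expect_equal(unname(response_functions(case_spec(3, m = 3), s)),
               c(0.25, 1, 1, 0.04))
  s44 <- population_state(0.4, 0.4, 0.2)
  expect_equal(unname(response_functions(case_spec(4), s44)),
               c(1, 1.25, 1.25, 1))
  expect_equal(unname(response_functions(case_spec(5), s44)),
               c(1.25, 1, 1, 1.25))
  # the 1/(x+y) entries vanish at the uncommitted vertex
  zv <- population_state(0, 0, 1)
  expect_equal(unname(response_functions(case_spec(4), zv)), c(1, 0, 0, 1))
  expect_equal(unname(response_functions(case_spec(5), zv)), c(0, 1, 1, 0))
  # randomized agreement with the hand-written oracle
  withr::with_seed(42, {
    for (rep in 1:50) {
      st <- random_interior_state()
      cid <- sample(1:5, 1)
      m <- if (cid == 2) sample(2:4, 1) else 1L
      d <- if (cid == 3) sample(2:4, 1) else NULL
      cs <- case_spec(cid, m = m, d = d)
      expect_equal(unname(response_functions(cs, st)),
                   oracle_f(cid, cs$m, cs$d, st[1], st[2]))
    }
  })
})

test_that("expected gain implements positive-part pairwise comparison", {
  sh <- c(0.5, 0.3, 0.2)
  expect_equal(expected_gain(matrix(0, 3, 3), 1, 2, sh), 0)
  A <- payoff_matrix(payoff_params(0.2, 0.2, 0.2, 0.2), case_spec(1),
                     population_state(0.5, 0.3))
  # only the X-column difference a11 - 0 is positive for Z -> X
  expect_equal(expected_gain(A, current = "Z", candidate = "X", sh), 0.1)
  expect_equal(expected_gain(A, current = "Y", candidate = "Y", sh), 0)
  expect_error(expected_gain(A, "Z", "X", c(0.5, 0.3, 0.3)), "sum")
  # randomized: matches the loop oracle, and gains are never negative
  withr::with_seed(7, {
    for (rep in 1:30) {
      M <- matrix(stats::rnorm(16), 4, 4)
      sh4 <- stats::runif(4)
      sh4 <- sh4 / sum(sh4)
      i <- sample(4, 1)
      j <- sample(4, 1)
      g <- expected_gain(M, j, i, sh4)
      expect_equal(g, oracle_expected_gain(M, i, j, sh4))
      expect_gte(g, 0)
    }
  })
})

test_that("transition rates follow the macroscopic law and the gain identity", {
  p17 <- payoff_params(0.2, 0.2, 0.2, 0.2)
  r <- transition_rates(p17, case_spec(1), population_state(0.5, 0.3))
  expect_equal(unname(r$raw), c(0.10, 0.06, 0.10, 0.06))
  expect_false(r$any_clipped)
  # no committed agents: nothing moves
  r0 <- transition_rates(p17, case_spec(1), population_state(0, 0, 1))
  expect_equal(unname(r0$raw), c(0, 0, 0, 0))
  r2 <- transition_rates(payoff_params(0.2, 0.2, 0.2, 0.2), case_spec(2, m = 2),
                         population_state(0.3, 0.6, 0.1))
  expect_equal(r2$raw[["pXZ"]], 0.2 * 0.6 * 0.6)
  # expected-gain equivalence on randomized draws
  withr::with_seed(11, {
    for (rep in 1:1000) {
      a <- stats::runif(4, 0, 1)
      params <- payoff_params(a[1], a[2], a[3], a[4])
      cid <- sample(1:5, 1)
      cs <- case_spec(cid,
                      m = if (cid == 2) sample(1:4, 1) else 1L,
                      d = if (cid == 3) sample(1:4, 1) else NULL)
      st <- random_interior_state()
      A <- payoff_matrix(params, cs, st)
      rr <- transition_rates(params, cs, st)$raw
      gains <- c(
        pZX = expected_gain(A, "Z", "X", st),
        pXZ = expected_gain(A, "X", "Z", st),
        pYZ = expected_gain(A, "Y", "Z", st),
        pZY = expected_gain(A, "Z", "Y", st)
      )
      expect_lt(max(abs(gains - rr)), 1e-12)
    }
  })
})

test_that("clipped probabilities are bounded and the Z row stays stochastic", {
  withr::with_seed(3, {
    for (rep in 1:200) {
      a <- stats::runif(4, 0, 3)
      params <- suppressWarnings(payoff_params(a[1], a[2], a[3], a[4]))
      cid <- sample(1:5, 1)
      cs <- case_spec(cid, m = if (cid == 2) 2L else 1L)
      st <- random_interior_state()
      cl <- transition_rates(params, cs, st)$clipped
      expect_true(all(cl >= 0 & cl <= 1))
      expect_lte(cl[["pZX"]] + cl[["pZY"]], 1 + 1e-12)
    }
  })
})

test_that("swapping the two opinions swaps the corresponding rates", {
  withr::with_seed(5, {
    for (rep in 1:100) {
      a <- stats::runif(4)
      st <- random_interior_state()
      cs <- case_spec(sample(c(1, 4, 5), 1))
      r1 <- transition_rates(payoff_params(a[1], a[2], a[3], a[4]), cs, st)$raw
      r2 <- transition_rates(payoff_params(a[4], a[3], a[2], a[1]), cs,
                             c(st[2], st[1]))$raw
      expect_equal(r1[["pZX"]], r2[["pZY"]])
      expect_equal(r1[["pXZ"]], r2[["pYZ"]])
    }
  })
})

test_that("micro event probabilities map rewards to agent-level events", {
  p17 <- payoff_params(0.2, 0.2, 0.2, 0.2)
  expect_equal(
    unname(micro_event_probabilities(p17, case_spec(1), 0.9, 0.05)),
    c(0.2, 0.2, 0.2, 0.2)
  )
  # case 4 scales abandonment by the local committed fraction
  p4 <- micro_event_probabilities(p17, case_spec(4), 0.25, 0.25)
  expect_equal(unname(p4), c(0.4, 0.4, 0.2, 0.2))
  # clipping at 1
  p4b <- micro_event_probabilities(payoff_params(0.2, 0.9, 0.9, 0.2),
                                   case_spec(4), 0.25, 0.25)
  expect_equal(p4b[["p1"]], 1)
  # no committed neighbours: the scaled events are impossible
  p5 <- micro_event_probabilities(p17, case_spec(5), 0, 0)
  expect_equal(unname(p5), c(0.2, 0.2, 0, 0))
  expect_error(micro_event_probabilities(p17, case_spec(1), -0.1, 0), "fraction")
  expect_error(micro_event_probabilities(p17, case_spec(1), 0.8, 0.5), "fraction")
})
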
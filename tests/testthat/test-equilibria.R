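test_that("equilibrium search returns the vertices plus the balanced interior point", {
  p17 <- payoff_params(0.2, 0.2, 0.2, 0.2)
  eq <- find_equilibria(p17, case_spec(1))
  expect_setequal(
    eq$label[1:3], c("vertex_X", "vertex_Y", "vertex_Z")
  )
  int <- eq[eq$label == "interior", ]
  expect_equal(nrow(int), 1L)
  expect_equal(int$q, 1, tolerance = 1e-10)
  expect_equal(c(int$x, int$y, int$z), rep(1 / 3, 3), tolerance = 1e-10)

  # dominant X recruitment: closed-form oracle gives q = 4.5, (2/13, 9/13, 2/13)
  p18 <- payoff_params(0.9, 0.2, 0.2, 0.2)
  want <- oracle_case1_interior(0.9, 0.2, 0.2, 0.2)
  expect_equal(want[["q"]], 4.5)
  int18 <- find_equilibria(p18, case_spec(1))
  int18 <- int18[int18$label == "interior", ]
  expect_equal(int18$q, want[["q"]], tolerance = 1e-8)
  expect_equal(c(int18$x, int18$y, int18$z),
               unname(want[c("x", "y", "z")]), tolerance = 1e-10)
  expect_equal(c(int18$x, int18$y), c(2 / 13, 9 / 13), tolerance = 1e-10)
})

test_that("every reported equilibrium has a tiny fixed-point residual", {
  for (params in study_matrices()) {
    for (cs in all_cases()) {
      eq <- suppressWarnings(find_equilibria(params, cs))
      expect_true(all(eq$residual <= 1e-10))
      for (i in seq_len(nrow(eq))) {
        out <- mean_field_step(c(eq$x[i], eq$y[i]), params, cs)
        expect_lte(max(abs(out[1:2] - c(eq$x[i], eq$y[i]))), 1e-10)
      }
    }
  }
})

test_that("numeric and analytic Jacobians agree for the linear-response case", {
  withr::with_seed(19, {
    a <- stats::runif(4)
    params <- payoff_params(a[1], a[2], a[3], a[4])
    for (rep in 1:100) {
      st <- random_interior_state()
      Jn <- jacobian_mean_field(params, case_spec(1), st, h = 1e-6)
      Ja <- jacobian_mean_field(params, case_spec(1), st, method = "analytic")
      Jo <- oracle_case1_jacobian(st[1], st[2], a[1], a[2], a[3], a[4])
      expect_lt(max(abs(Jn - Jo)), 1e-6)
      expect_lt(max(abs(Ja - Jo)), 1e-12)
    }
  })
  expect_error(
    jacobian_mean_field(payoff_params(0.2, 0.2, 0.2, 0.2), case_spec(4),
                        c(0.3, 0.3), method = "analytic"),
    "case 1"
  )
})

test_that("the uncommitted vertex Jacobian equals the recruitment rates plus one", {
  p17 <- payoff_params(0.2, 0.2, 0.2, 0.2)
  J <- jacobian_mean_field(p17, case_spec(1), population_state(0, 0, 1))
  expect_equal(J, diag(c(1.2, 1.2)), tolerance = 1e-8)
  # zero rewards freeze the dynamics everywhere
  p0 <- payoff_params(0, 0, 0, 0)
  withr::with_seed(2, {
    for (rep in 1:10) {
      st <- random_interior_state()
      expect_equal(jacobian_mean_field(p0, case_spec(1), st), diag(2),
                   tolerance = 1e-9)
    }
  })
})

test_that("stability classification follows the spectral radius", {
  p17 <- payoff_params(0.2, 0.2, 0.2, 0.2)
  sz <- classify_stability(p17, case_spec(1), population_state(0, 0, 1))
  expect_equal(sort(sz$moduli), c(1.2, 1.2), tolerance = 1e-7)
  expect_identical(sz$classification, "unstable")
  s0 <- classify_stability(payoff_params(0, 0, 0, 0), case_spec(1),
                           population_state(1, 0, 0))
  expect_identical(s0$classification, "marginal")
  expect_equal(s0$moduli, c(1, 1), tolerance = 1e-9)
  expect_error(
    classify_stability(p17, case_spec(1), population_state(0.5, 0.2)),
    "fixed point"
  )
})

test_that("classification agrees with perturbation simulations", {
  # stable points attract small perturbations; unstable ones let at least
  # one direction escape
  withr::with_seed(101, {
    for (params in study_matrices()) {
      for (cs in all_cases()) {
        ana <- suppressWarnings(equilibrium_analysis(params, cs))
        tbl <- tidy(ana)
        for (i in seq_len(nrow(tbl))) {
          cls <- tbl$classification[i]
          if (cls == "marginal") next
          eqv <- c(tbl$x[i], tbl$y[i])
          escaped <- FALSE
          returned <- TRUE
          for (dir in 1:20) {
            qpt <- random_interior_state()
            start <- (1 - 1e-3) * c(eqv, 1 - sum(eqv)) + 1e-3 * qpt
            tr <- iterate_mean_field(start / sum(start), 500, params, cs)
            dist <- abs(tr$x - eqv[1]) + abs(tr$y - eqv[2])
            if (any(dist > 1e-2)) escaped <- TRUE
            if (dist[length(dist)] > 1e-6) returned <- FALSE
          }
          if (cls == "stable") {
            expect_true(returned,
                        label = sprintf("stable %s (case %d) attracts",
                                        tbl$label[i], cs$case_id))
          } else {
            expect_true(escaped,
                        label = sprintf("unstable %s (case %d) repels",
                                        tbl$label[i], cs$case_id))
          }
        }
      }
    }
  })
})

test_that("dominant-opinion rewards leave at least one consensus vertex stable", {
  p18 <- payoff_params(0.9, 0.2, 0.2, 0.2)
  for (cs in all_cases()) {
    ana <- suppressWarnings(equilibrium_analysis(p18, cs))
    tbl <- tidy(ana)
    vertex_stable <- tbl$classification[tbl$label != "interior"] == "stable"
    expect_true(any(vertex_stable))
  }
})

test_that("tidy, glance and the CSV report expose the analysis", {
  ana <- equilibrium_analysis(payoff_params(0.9, 0.2, 0.2, 0.2), case_spec(1))
  tbl <- tidy(ana)
  expect_true(all(c("label", "x", "y", "z", "q", "lambda1_abs",
                    "lambda2_abs", "classification") %in% names(tbl)))
  g <- glance(ana)
  expect_identical(g$n_equilibria, nrow(tbl))
  expect_identical(g$n_interior, 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_equilibrium_csv(ana, path)
  back <- utils::read.csv(path)
  expect_identical(
    names(back),
    c("case", "a11", "a12", "a21", "a22", "label", "x", "y", "z", "q",
      "lambda1_abs", "lambda2_abs", "classification")
  )
  expect_equal(nrow(back), nrow(tbl))
})
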
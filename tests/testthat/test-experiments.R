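test_that("final decisions are read off the last recorded shares", {
  expect_identical(final_decision(c(1, 0, 0), 0.9), "X")
  expect_identical(final_decision(c(0.34, 0.33, 0.33), 0.9), "mixed")
  expect_identical(final_decision(c(0.1, 0.2, 0.7)), "Z")
  expect_error(final_decision(c(1, 0, 0), 0.2), "threshold")
  tr <- iterate_mean_field(population_state(0.3, 0.35, 0.35), 200,
                           payoff_params(0.9, 0.2, 0.2, 0.2), case_spec(1))
  expect_identical(final_decision(tr), "X")
})

test_that("paired runs share initial conditions and quantify discrepancy", {
  p17 <- payoff_params(0.2, 0.2, 0.2, 0.2)
  # frozen all-uncommitted start: both processes stay put
  cmp0 <- compare_processes(
    p17, case_spec(1), graph_spec = list(type = "er", N = 50, p = 0.3),
    T_steps = 1, seed = 1, initial_opinions = rep(3L, 50)
  )
  expect_true(all(cmp0$discrepancy$dev == 0))
  expect_identical(unname(cmp0$final_decisions), c("Z", "Z"))

  # a single step on a dense complete graph stays within sampling noise
  N <- 1000
  cmp1 <- compare_processes(
    p17, case_spec(1), graph_spec = list(type = "complete", N = N),
    T_steps = 1, seed = 2
  )
  expect_lt(max(cmp1$discrepancy$dev), 3 * sqrt(0.25 / N))

  # matched initial shares between the two trajectories
  traj <- cmp1$trajectories
  first_mf <- traj[traj$source == "mf" & traj$t == 0, ]
  first_abm <- traj[traj$source == "abm" & traj$t == 0, ]
  expect_equal(first_mf[, c("x", "y", "z")], first_abm[, c("x", "y", "z")],
               ignore_attr = TRUE)
  g <- glance(cmp1)
  expect_true(all(c("mean_dev", "max_dev", "agreement") %in% names(g)))
})

test_that("well-mixed agent populations track the mean field closely", {
  p18 <- payoff_params(0.9, 0.2, 0.2, 0.2)
  devs <- vapply(1:3, function(s) {
    cmp <- compare_processes(p18, case_spec(1),
                             graph_spec = list(type = "er", N = 500, p = 0.2),
                             T_steps = 100, seed = s)
    mean(cmp$discrepancy$dev)
  }, numeric(1))
  expect_lt(mean(devs), 0.05)
})

test_that("ratio sweeps are reproducible and record their grid", {
  sw1 <- ratio_sweep(ratio_xz = c(0.5, 1.5), ratio_yz = c(0.5, 1.5),
                     case = case_spec(1),
                     graph_spec = list(type = "er", N = 100, p = 0.2),
                     T_steps = 30, replicates = 2, seed = 42)
  sw2 <- ratio_sweep(ratio_xz = c(0.5, 1.5), ratio_yz = c(0.5, 1.5),
                     case = case_spec(1),
                     graph_spec = list(type = "er", N = 100, p = 0.2),
                     T_steps = 30, replicates = 2, seed = 42)
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))
  expect_equal(nrow(sw1), 4L)
  expect_true(all(sw1$n_reps == 2L))
  expect_true(all(sw1$final_x_fraction >= 0 & sw1$final_x_fraction <= 1))
  expect_error(ratio_sweep(ratio_xz = c(-1, 1), seed = 1), "positive")
  # rewards pushed past 1 are flagged
  sw3 <- ratio_sweep(ratio_xz = 1, ratio_yz = 3, base_a11 = 0.5,
                     base_a22 = 0.5, T_steps = 2, replicates = 1,
                     graph_spec = list(type = "er", N = 50, p = 0.3),
                     seed = 1)
  expect_true(sw3$clip_warning)
})

test_that("small-world agreement cells are proper seeded proportions", {
  ag <- smallworld_agreement(case_id = 1, m = 3, j_values = c(3),
                             N = 60, T_steps = 40, replications = 5,
                             seed = 31)
  expect_true(all(ag$agreement_fraction >= 0 & ag$agreement_fraction <= 1))
  expect_equal(sum(ag$n_reps), 5L)
  runs <- attr(ag, "runs")
  expect_equal(nrow(runs), 5L)
  expect_true(all(runs$reward_ratio ==
                    (runs$a11 * runs$a21) / (runs$a22 * runs$a12)))
  # single replication: the fraction is 0 or 1
  ag1 <- smallworld_agreement(case_id = 1, m = 3, j_values = c(3),
                              N = 60, T_steps = 40, replications = 1,
                              seed = 32)
  expect_true(all(ag1$agreement_fraction %in% c(0, 1)))
  expect_error(
    smallworld_agreement(case_id = 1, m = 3, j_values = c(70), N = 60,
                         replications = 1, seed = 1),
    "below N"
  )
  # same seed, same table
  ag2 <- smallworld_agreement(case_id = 1, m = 3, j_values = c(3),
                              N = 60, T_steps = 40, replications = 5,
                              seed = 31)
  expect_identical(as.data.frame(ag), as.data.frame(ag2))
})

test_that("autoplot methods return ggplot objects for each result type", {
  p18 <- payoff_params(0.9, 0.2, 0.2, 0.2)
  tr <- iterate_mean_field(population_state(0.3, 0.3, 0.4), 20, p18, case_spec(1))
  expect_s3_class(autoplot(tr), "ggplot")
  pp <- phase_portrait(p18, case_spec(1), 5)
  expect_s3_class(autoplot(pp), "ggplot")
  cmp <- compare_processes(p18, case_spec(1),
                           graph_spec = list(type = "er", N = 60, p = 0.3),
                           T_steps = 10, seed = 3)
  expect_s3_class(autoplot(cmp), "ggplot")
  sw <- ratio_sweep(ratio_xz = c(0.5, 1.5), ratio_yz = c(0.5, 1.5),
                    graph_spec = list(type = "er", N = 50, p = 0.3),
                    T_steps = 5, replicates = 1, seed = 9)
  expect_s3_class(autoplot(sw), "ggplot")
  ag <- smallworld_agreement(case_id = 1, m = 3, j_values = 3, N = 50,
                             T_steps = 10, replications = 2, seed = 10)
  expect_s3_class(autoplot(ag), "ggplot")
  expect_s3_class(autoplot(equilibrium_analysis(p18, case_spec(1))), "ggplot")
})
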
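test_that("transition matrix rows assemble from the published inputs", {
  cfg <- default_base_case()
  P <- build_transition_matrix(cfg, "intervention")
  s <- health_states()
  expect_equal(dimnames(P), list(s, s))
  expect_equal(rowSums(P), setNames(rep(1, 9), s), tolerance = 1e-12)
  expect_true(all(P >= 0 & P <= 1))
  # within-range stay is the row-normalisation remainder of the two exits
  expect_equal(P["WithinRange", "WithinRange"], 1 - 0.0225 - 0.0191)
  # absorbing death
  expect_equal(unname(P["Death", ]), c(rep(0, 8), 1))
  # recovery mortality is scaled by the excess-mortality risk ratio
  expect_equal(P["RecoveryPostTE", "Death"], 0.00147 * 2.25)
  expect_equal(P["RecoveryPostBleedOrReop", "Death"], 0.00147 * 1.5)
  # event rows: explicit exits, recurrence on the diagonal, remainder recovers
  expect_equal(P["TE", "TE"], 0.08825)
  expect_equal(P["TE", "RecoveryPostTE"],
               1 - 0.00228 - 0.00033 - 0.00374 - 0.08825)
  expect_equal(P["Bleeding", "RecoveryPostBleedOrReop"],
               1 - 0.00059 - 0.00033 - 0.01078 - 0.02049)
  expect_equal(P["Reoperation", "RecoveryPostBleedOrReop"],
               1 - 0.00014 - 0.00028 - 0.00035 - 0.00033)
  # no pathway from recovery back to the INR states (quasi-absorbing)
  expect_equal(unname(P["RecoveryPostTE", c("WithinRange", "BelowRange",
                                            "AboveRange")]), rep(0, 3))
  # the control arm differs only in the INR block
  Pc <- build_transition_matrix(cfg, "control")
  expect_equal(Pc["WithinRange", "BelowRange"], 0.0741)
  expect_equal(Pc[4:9, ], P[4:9, ])
})

test_that("infeasible parameter combinations are rejected by row name", {
  cfg <- default_base_case()
  cfg <- set_parameter(cfg, "p_te_to_te", 0.999)
  expect_error(build_transition_matrix(cfg, "intervention"), "TE")
})

test_that("propagation matches the matrix-power oracle", {
  # identity chain: nothing moves
  P <- diag(3)
  expect_equal(propagate(P, c(0.2, 0.3, 0.5), 7),
               matrix(rep(c(0.2, 0.3, 0.5), each = 8), 8, 3),
               ignore_attr = TRUE)
  # symmetric two-state toy
  P2 <- matrix(0.5, 2, 2)
  expect_equal(unname(propagate(P2, c(1, 0), 1)[2, ]), c(0.5, 0.5))
  # one base-case cycle equals the hand matrix-vector product
  cfg <- default_base_case()
  Pi <- build_transition_matrix(cfg, "intervention")
  init <- initial_distribution(cfg, "intervention")
  tr <- propagate(Pi, init, 1)
  expect_equal(unname(tr[2, ]), as.vector(init %*% Pi), tolerance = 1e-15)
  # property: agreement with naive repeated matrix powers on random chains
  set.seed(41)
  for (rep in 1:5) {
    P9 <- random_stochastic_matrix(9)
    init9 <- c(1, rep(0, 8))
    expect_equal(unname(propagate(P9, init9, 30)),
                 propagate_oracle(P9, init9, 30), tolerance = 1e-12)
  }
})

test_that("mass is conserved and death only accumulates over the horizon", {
  cfg <- default_base_case()
  for (arm in c("intervention", "control")) {
    P <- build_transition_matrix(cfg, arm)
    tr <- propagate(P, initial_distribution(cfg, arm),
                    cfg$settings$horizon_cycles)
    expect_true(all(abs(rowSums(tr) - 1) < 1e-9))
    expect_true(all(diff(tr[, "Death"]) >= -1e-15))
    expect_true(all(tr >= 0))
  }
})

test_that("outcome accumulation reproduces hand-computable limits", {
  # a single alive state, utility 1, no discounting: 12 monthly cycles = 1 QALY
  cfg <- no_event_config(horizon = 12, hcc = FALSE)
  cfg <- set_parameter(cfg, "u_within_range", 1)
  cfg <- set_parameter(cfg, "discount_rate_qaly", 0)
  for (nm in c("p_within_to_below_intervention",
               "p_within_to_above_intervention"))
    cfg <- set_parameter(cfg, nm, 0)
  out <- run_arm(cfg, "intervention")
  expect_equal(out$total_qaly, 1, tolerance = 1e-12)
  # cohort parked in Bleeding for one undiscounted cycle costs one bleeding event
  cfg1 <- default_base_case()
  cfg1$settings$horizon_cycles <- 1L
  cfg1$settings$half_cycle_correction <- FALSE
  cfg1 <- set_parameter(cfg1, "discount_rate_cost", 0)
  P <- build_transition_matrix(cfg1, "intervention")
  trace <- matrix(0, 2, 9, dimnames = list(0:1, health_states()))
  trace[1, "Bleeding"] <- 1
  trace[2, ] <- as.vector(trace[1, ] %*% P)
  out1 <- accumulate_outcomes(trace, cfg1, matrix = P)
  expect_equal(out1$total_cost, 2777.78)
  # persistent 0.987-utility state, 3.5% annual discount, 480 cycles, no
  # half-cycle correction: the geometric-series closed form
  cfg2 <- no_event_config(horizon = 480, hcc = FALSE)
  out2 <- run_arm(cfg2, "intervention")
  expect_equal(out2$total_qaly, geometric_qaly_oracle(0.987, 0.035, 480),
               tolerance = 1e-10)
  expect_equal(out2$total_cost, 0)
  # with half-cycle correction and constant occupancy the total is unchanged
  cfg3 <- no_event_config(horizon = 480, hcc = TRUE)
  expect_equal(run_arm(cfg3, "intervention")$total_qaly, out2$total_qaly,
               tolerance = 1e-10)
})

test_that("discounting and event risks move totals in the expected direction", {
  cfg <- default_base_case()
  base <- run_arm(cfg, "control")
  expect_lte(base$total_qaly, base$undiscounted_qaly)
  expect_lte(base$total_cost, base$undiscounted_cost)
  expect_lte(base$total_qaly, cfg$settings$horizon_cycles / 12)
  # raising an event risk never increases QALYs
  worse <- set_parameter(cfg, "p_above_to_bleeding", 0.05)
  expect_lt(run_arm(worse, "control")$total_qaly, base$total_qaly)
  # raising a discount rate never increases discounted totals
  disc <- set_parameter(cfg, "discount_rate_qaly", 0.06)
  expect_lt(run_arm(disc, "control")$total_qaly, base$total_qaly)
  disc_c <- set_parameter(cfg, "discount_rate_cost", 0.06)
  expect_lt(run_arm(disc_c, "control")$total_cost, base$total_cost)
})

test_that("per-entry and per-cycle event costing agree closely at base case", {
  # event-state stay probabilities are at most 0.09, so charging per cycle of
  # occupancy and charging once per entry should differ only marginally
  cfg <- default_base_case()
  per_cycle <- run_arm(cfg, "control")$total_cost
  cfg$settings$cost_timing <- "per_entry"
  per_entry <- run_arm(cfg, "control")$total_cost
  expect_gt(per_entry, 0)
  expect_lt(abs(per_entry - per_cycle) / per_cycle, 0.05)
})

test_that("trace exports as a deterministic CSV", {
  cfg <- default_base_case()
  cfg$settings$horizon_cycles <- 5L
  out <- run_arm(cfg, "intervention")
  tmp <- tempfile(fileext = ".csv")
  write_trace_csv(out$trace, tmp)
  df <- read.csv(tmp, check.names = FALSE)
  expect_equal(names(df), c("cycle", health_states()))
  expect_equal(nrow(df), 6)
  expect_equal(df$WithinRange, unname(out$trace[, "WithinRange"]))
  unlink(tmp)
})
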
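# Shared helpers: independent oracles and small constructors used across the
# suite. Each oracle is a deliberately naive re-derivation, kept independent
# of the package's own code paths.

# minimal arm-outcome stub for incremental arithmetic tests
make_outcome <- function(cost, qaly) {
  structure(list(total_cost = cost, total_qaly = qaly,
                 undiscounted_cost = cost, undiscounted_qaly = qaly,
                 life_years = qaly, trace = NULL),
            class = "cea_arm_outcome")
}

# brute-force cohort propagation: repeated explicit matrix powers
propagate_oracle <- function(P, init, n_cycles) {
  out <- matrix(0, n_cycles + 1, length(init))
  Pt <- diag(length(init))
  for (t in 0:n_cycles) {
    out[t + 1, ] <- as.vector(init %*% Pt)
    Pt <- Pt %*% P
  }
  out
}

# random valid stochastic matrix with an absorbing final state
random_stochastic_matrix <- function(n = 9) {
  P <- matrix(stats::rexp(n * n), n, n)
  P <- P / rowSums(P)
  P[n, ] <- c(rep(0, n - 1), 1)
  P
}

# fine-grid numerical integration of time-in-range for a piecewise linear
# INR trajectory (step in days)
ttr_grid_oracle <- function(day, inr, lo = 2.5, hi = 3.5, step = 0.001) {
  grid <- seq(day[1], day[length(day)], by = step)
  y <- stats::approx(day, inr, xout = grid)$y
  c(ttr = 100 * mean(y >= lo & y <= hi),
    below = 100 * mean(y < lo),
    above = 100 * mean(y > hi))
}

# closed-form discounted QALY total for a cohort that never leaves states of
# utility u: (u / 12) * sum_{t=0}^{H-1} (1 + r)^(-t/12)
geometric_qaly_oracle <- function(u, r, n_cycles) {
  a <- (1 + r)^(-1 / 12)
  (u / 12) * (1 - a^n_cycles) / (1 - a)
}

# config with every event pathway switched off: the cohort circulates in the
# three INR states forever
no_event_config <- function(horizon = 480, hcc = FALSE) {
  cfg <- default_base_case()
  for (nm in c("p_above_to_bleeding", "p_below_to_te"))
    cfg <- set_parameter(cfg, nm, 0)
  cfg$settings$horizon_cycles <- as.integer(horizon)
  cfg$settings$half_cycle_correction <- hcc
  cfg
}
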
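# Markov cohort engine: per-arm transition matrix assembly, cohort
# propagation, and discounted half-cycle-corrected accumulation of costs and
# QALYs.

#' Build the per-arm 9x9 transition matrix
#'
#' Assembles the per-cycle transition matrix over the canonical state order
#' of [health_states()]. The three no-event INR states exchange mass per the
#' arm-specific band transition probabilities and feed the event states via
#' the arm-independent risks (above-range to bleeding, below-range to TE).
#' Event-state rows use the published recurrence/death probabilities with the
#' remaining mass flowing to the matching recovery state; recovery rows carry
#' recurrent-event risks and a mortality probability scaled by the
#' excess-mortality risk ratio of the preceding event class (major TE, or
#' major bleeding/reoperation). Death is absorbing.
#'
#' Probabilities are clamped into \[0, 1\] before assembly (sensitivity
#' extremes can exceed 1); a negative stay-probability remainder in any row
#' is an infeasible-parameter error naming the row.
#'
#' @param config A `cea_config`.
#' @param arm `"intervention"` or `"control"`.
#' @return A 9x9 numeric matrix with `dimnames` set to the state names and an
#'   `arm` attribute; every row sums to 1.
#' @export
#' @examples
#' P <- build_transition_matrix(default_base_case(), "intervention")
#' rowSums(P)
build_transition_matrix <- function(config, arm = c("intervention", "control")) {
  arm <- match.arg(arm)
  s <- .S
  cl <- function(nm) .clamp01(.pv(config, nm), nm)
  P <- matrix(0, 9, 9, dimnames = list(health_states(), health_states()))
  fill_row <- function(P, from, to, p) {
    P[from, to] <- p
    stay <- 1 - sum(p)
    if (stay < -1e-12)
      stop("infeasible parameters: outgoing probabilities from state '",
           health_states()[from], "' sum to ", sum(p), " > 1", call. = FALSE)
    P[from, from] <- P[from, from] + max(stay, 0)
    P
  }
  P <- fill_row(P, s$W, c(s$B, s$A),
                c(cl(paste0("p_within_to_below_", arm)),
                  cl(paste0("p_within_to_above_", arm))))
  P <- fill_row(P, s$B, c(s$W, s$TE),
                c(cl(paste0("p_below_to_within_", arm)), cl("p_below_to_te")))
  P <- fill_row(P, s$A, c(s$W, s$BL),
                c(cl(paste0("p_above_to_within_", arm)),
                  cl("p_above_to_bleeding")))
  # event states: listed exits, explicit recurrence (stay), remainder recovers
  event_row <- function(P, from, to_bl, to_te, to_re, p_death, p_stay, rec) {
    p <- c(to_bl, to_te, to_re, p_death, p_stay)
    if (sum(p) > 1 + 1e-12)
      stop("infeasible parameters: outgoing probabilities from state '",
           health_states()[from], "' sum to ", sum(p), " > 1", call. = FALSE)
    P[from, s$BL] <- P[from, s$BL] + to_bl
    P[from, s$TE] <- P[from, s$TE] + to_te
    P[from, s$RE] <- P[from, s$RE] + to_re
    P[from, s$D]  <- p_death
    P[from, from] <- P[from, from] + p_stay
    P[from, rec]  <- max(1 - sum(p), 0)
    P
  }
  P <- event_row(P, s$TE, cl("p_te_to_bleeding"), 0, cl("p_te_to_reoperation"),
                 cl("p_te_to_death"), cl("p_te_to_te"), s$R_TE)
  P <- event_row(P, s$BL, 0, cl("p_bleeding_to_te"),
                 cl("p_bleeding_to_reoperation"), cl("p_bleeding_to_death"),
                 cl("p_bleeding_to_bleeding"), s$R_BR)
  P <- event_row(P, s$RE, cl("p_reop_to_bleeding"), cl("p_reop_to_te"), 0,
                 cl("p_reop_to_death"), cl("p_reop_to_reop"), s$R_BR)
  # recovery states: recurrent events plus risk-ratio-scaled mortality
  for (rec in c(s$R_TE, s$R_BR)) {
    rr <- .pv(config, if (rec == s$R_TE) "rr_death_major_te"
                      else "rr_death_major_bleeding")
    p_death <- .clamp01(cl("p_recovery_to_death") * rr, "recovery mortality")
    P <- fill_row(P, rec, c(s$TE, s$BL, s$RE, s$D),
                  c(cl("p_recovery_to_te"), cl("p_recovery_to_bleeding"),
                    cl("p_recovery_to_reoperation"), p_death))
  }
  P[s$D, s$D] <- 1
  stopifnot(all(abs(rowSums(P) - 1) < 1e-12))
  attr(P, "arm") <- arm
  P
}

#' Initial cohort distribution for an arm
#'
#' Places the arm's initial proportions in the three no-event INR states
#' (zero elsewhere). Proportions are clamped into \[0, 1\] and renormalised
#' to sum to 1 when a sensitivity extreme has perturbed them.
#'
#' @param config A `cea_config`.
#' @param arm `"intervention"` or `"control"`.
#' @return Length-9 numeric vector summing to 1, named by state.
#' @export
initial_distribution <- function(config, arm = c("intervention", "control")) {
  arm <- match.arg(arm)
  p <- vapply(c("init_within_", "init_below_", "init_above_"),
              function(pre) .clamp01(.pv(config, paste0(pre, arm)),
                                     paste0(pre, arm)),
              numeric(1))
  if (sum(p) <= 0) stop("initial proportions sum to zero", call. = FALSE)
  x <- c(p / sum(p), rep(0, 6))
  names(x) <- health_states()
  x
}

#' Propagate a cohort through the Markov chain
#'
#' Row `t + 1` of the returned trace is row `t` right-multiplied by the
#' transition matrix; row 1 is the initial distribution (cycle 0).
#'
#' @param matrix A square transition matrix (rows summing to 1).
#' @param initial Initial state distribution (sums to 1).
#' @param n_cycles Number of cycles to simulate (>= 1).
#' @return An `(n_cycles + 1) x n_states` matrix of cohort occupancy
#'   fractions, one row per cycle 0..n_cycles, with a `cycle` rowname.
#' @export
#' @examples
#' P <- build_transition_matrix(default_base_case(), "control")
#' tr <- propagate(P, initial_distribution(default_base_case(), "control"), 12)
#' rowSums(tr)
propagate <- function(matrix, initial, n_cycles) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            length(initial) == nrow(matrix), n_cycles >= 1)
  if (abs(sum(initial) - 1) > 1e-9)
    stop("initial distribution must sum to 1", call. = FALSE)
  trace <- base::matrix(0, n_cycles + 1, nrow(matrix),
                        dimnames = list(0:n_cycles, colnames(matrix)))
  trace[1, ] <- initial
  for (t in seq_len(n_cycles))
    trace[t + 1, ] <- as.vector(trace[t, ] %*% matrix)
  trace
}

# per-state utility and cost vectors in canonical order; the out-of-range
# INR states share the within-range utility (out-of-range INR is
# asymptomatic per se), the two recovery sub-states share u_recovery
.utility_vector <- function(config) {
  u <- .pv(config, "u_within_range")
  c(u, u, u,
    .pv(config, "u_bleeding"), .pv(config, "u_te"), .pv(config, "u_reoperation"),
    .pv(config, "u_recovery"), .pv(config, "u_recovery"), 0)
}

.cost_vector <- function(config) {
  c(0, 0, 0, .pv(config, "c_bleeding"), .pv(config, "c_te"),
    .pv(config, "c_reoperation"), 0, 0, 0)
}

#' Accumulate discounted costs and QALYs over a trace
#'
#' For each cycle `t` (0-based), the effective occupancy is the trapezoidal
#' mean of the cycle-start and cycle-end rows when half-cycle correction is
#' on, else the cycle-start row. The QALY increment is the utility-weighted
#' occupancy times the cycle length in years, discounted by
#' `(1 + r_qaly)^(-t * cycle_length / 12)`; the cost increment applies the
#' per-cycle event-state costs (bleeding, TE, reoperation) with the cost
#' discount rate. With `cost_timing = "per_entry"` the event cost is instead
#' charged once per entry into the event state.
#'
#' @param trace Occupancy trace from [propagate()]; must span the configured
#'   horizon.
#' @param config A `cea_config`.
#' @param matrix The transition matrix that produced the trace; only needed
#'   for `per_entry` costing (to separate entries from stays).
#' @return An object of class `cea_arm_outcome`: list with `total_cost`,
#'   `total_qaly`, their undiscounted counterparts, `life_years`, and the
#'   trace.
#' @export
accumulate_outcomes <- function(trace, config, matrix = NULL) {
  st <- config$settings
  H <- st$horizon_cycles
  if (nrow(trace) != H + 1)
    stop("trace has ", nrow(trace) - 1, " cycles but the configured horizon is ",
         H, call. = FALSE)
  cyc_years <- st$cycle_length_months / 12
  rq <- .pv(config, "discount_rate_qaly")
  rc <- .pv(config, "discount_rate_cost")
  u <- .utility_vector(config)
  cs <- .cost_vector(config)
  per_entry <- identical(st$cost_timing, "per_entry")
  if (per_entry && is.null(matrix))
    stop("per-entry costing needs the transition matrix", call. = FALSE)
  alive <- seq_len(8)
  t0 <- 0:(H - 1)
  dq <- (1 + rq)^(-t0 * cyc_years)
  dc <- (1 + rc)^(-t0 * cyc_years)
  occ <- if (isTRUE(st$half_cycle_correction))
    (trace[1:H, , drop = FALSE] + trace[2:(H + 1), , drop = FALSE]) / 2
  else trace[1:H, , drop = FALSE]
  qaly_cycle <- as.vector(occ %*% u) * cyc_years
  cost_cycle <- if (!per_entry) as.vector(occ %*% cs) else {
    # entries into an event state at the end of cycle t: next-cycle occupancy
    # minus the mass that stayed put
    stay <- diag(matrix)
    entries <- trace[2:(H + 1), , drop = FALSE] -
      sweep(trace[1:H, , drop = FALSE], 2, stay, "*")
    as.vector(pmax(entries, 0) %*% cs)
  }
  ly_cycle <- as.vector(occ[, alive, drop = FALSE] %*% rep(1, 8)) * cyc_years
  structure(list(
    total_cost = sum(cost_cycle * dc),
    total_qaly = sum(qaly_cycle * dq),
    undiscounted_cost = sum(cost_cycle),
    undiscounted_qaly = sum(qaly_cycle),
    life_years = sum(ly_cycle),
    trace = trace), class = "cea_arm_outcome")
}

#' @export
print.cea_arm_outcome <- function(x, ...) {
  cat(sprintf("<cea_arm_outcome> %.4f QALYs, %.2f USD (discounted); %.2f life-years\n",
              x$total_qaly, x$total_cost, x$life_years))
  invisible(x)
}

#' Run one arm of the cohort model
#'
#' Convenience wrapper: build the arm's transition matrix, propagate the
#' initial cohort over the configured horizon, and accumulate outcomes.
#'
#' @param config A `cea_config`.
#' @param arm `"intervention"` or `"control"`.
#' @return A `cea_arm_outcome` (see [accumulate_outcomes()]).
#' @export
#' @examples
#' run_arm(default_base_case(), "intervention")
run_arm <- function(config, arm = c("intervention", "control")) {
  arm <- match.arg(arm)
  P <- build_transition_matrix(config, arm)
  trace <- propagate(P, initial_distribution(config, arm),
                     config$settings$horizon_cycles)
  out <- accumulate_outcomes(trace, config, matrix = P)
  out$arm <- arm
  out
}

#' Run both arms and the incremental comparison
#'
#' @param config A `cea_config`.
#' @param validate Re-validate the config first? The sensitivity driver
#'   disables this: a pinned extreme may sit outside base-case invariants
#'   (e.g. a published upper bound above 1) and is clamped/renormalised at
#'   matrix-build time instead.
#' @return A list of class `cea_model_result` with elements `intervention`
#'   and `control` (each a `cea_arm_outcome`) and `incremental` (see
#'   [compute_icer()]).
#' @export
#' @examples
#' res <- run_model(default_base_case())
#' res$incremental
run_model <- function(config, validate = TRUE) {
  if (validate) validate_config(config)
  intervention <- run_arm(config, "intervention")
  control <- run_arm(config, "control")
  structure(list(intervention = intervention, control = control,
                 incremental = compute_icer(intervention, control)),
            class = "cea_model_result")
}

#' @export
print.cea_model_result <- function(x, ...) {
  cat("Markov cohort cost-utility results (discounted, per patient)\n")
  cat(sprintf("  intervention: %8.2f USD  %7.4f QALYs\n",
              x$intervention$total_cost, x$intervention$total_qaly))
  cat(sprintf("  control:      %8.2f USD  %7.4f QALYs\n",
              x$control$total_cost, x$control$total_qaly))
  print(x$incremental)
  invisible(x)
}

#' Export an occupancy trace as CSV
#'
#' One row per cycle, columns in the canonical state order, preceded by a
#' `cycle` column.
#'
#' @param trace Trace matrix from [propagate()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(cycle = as.integer(rownames(trace)), trace,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
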
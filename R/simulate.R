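# Synthetic patient-level INR trajectories. The generator emulates the
# anticoagulation clinic's visit structure: roughly monthly visits whose INR
# band occupancy follows the arm's three-band transition probabilities, with
# the observed INR drawn from the occupied band. It exists so the TTR
# endpoint and the transition-probability inputs can be exercised and
# validated without patient-level trial data.

#' Specification for a synthetic INR cohort
#'
#' @param config A `cea_config` supplying the arm's initial proportions and
#'   band transition probabilities.
#' @param arm `"intervention"` or `"control"`.
#' @param n_patients Number of patients (>= 1).
#' @param n_months Follow-up length in months (default 12, the trial's
#'   one-year follow-up), giving `n_months + 1` visits per patient.
#' @param visit_jitter_days Uniform integer jitter (+/- days) around the
#'   30-day visit grid; default 3, small enough never to reorder visits.
#' @param seed Integer seed; identical specs yield bit-identical cohorts.
#' @param band_edges Numeric vector `(min, low, high, max)` delimiting the
#'   below/within/above sampling intervals on the INR axis; defaults to
#'   `c(1.2, 2.5, 3.5, 6.0)` (display-range caps for the unbounded tails).
#' @return Object of class `cea_sim_spec`.
#' @export
simulation_spec <- function(config, arm = c("intervention", "control"),
                            n_patients, n_months = 12, visit_jitter_days = 3,
                            seed = 1L, band_edges = c(1.2, 2.5, 3.5, 6.0)) {
  arm <- match.arg(arm)
  validate_config(config)
  stopifnot(n_patients >= 1, n_months >= 1, visit_jitter_days >= 0,
            length(band_edges) == 4, all(diff(band_edges) > 0))
  structure(list(
    arm = arm,
    init = local({
      p <- c(.pv(config, paste0("init_within_", arm)),
             .pv(config, paste0("init_below_", arm)),
             .pv(config, paste0("init_above_", arm)))
      p / sum(p)
    }),
    bands = .band_matrix(config, arm),
    n_patients = as.integer(n_patients),
    n_months = as.integer(n_months),
    visit_jitter_days = as.integer(visit_jitter_days),
    band_edges = band_edges,
    seed = as.integer(seed)), class = "cea_sim_spec")
}

# 3x3 chain over bands (within, below, above); stay = remainder. This is the
# no-event marginal of the cohort model's INR block: the small event exits
# are folded into the stay probability, since the generator emulates patients
# who remain under clinic follow-up.
.band_matrix <- function(config, arm) {
  p_wb <- .pv(config, paste0("p_within_to_below_", arm))
  p_wa <- .pv(config, paste0("p_within_to_above_", arm))
  p_bw <- .pv(config, paste0("p_below_to_within_", arm))
  p_aw <- .pv(config, paste0("p_above_to_within_", arm))
  m <- matrix(c(1 - p_wb - p_wa, p_wb, p_wa,
                p_bw, 1 - p_bw, 0,
                p_aw, 0, 1 - p_aw),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("within", "below", "above"),
                              c("within", "below", "above")))
  stopifnot(all(m >= 0))
  m
}

#' Simulate a cohort of INR trajectories
#'
#' Per patient: the initial band is drawn from the arm's initial
#' proportions; the band then evolves visit-to-visit by the arm's three-band
#' transition chain. Visit `t` falls on day `30 t` plus uniform integer
#' jitter (day 0 is fixed); the observed INR is drawn uniformly from the
#' occupied band's interval. Deterministic given the spec's seed; the RNG
#' state of the session is left untouched.
#'
#' @param spec A `cea_sim_spec` from [simulation_spec()].
#' @return Object of class `cea_trajectories`: list with `measurements` (long
#'   data frame `patient_id`, `day`, `inr`), `bands` (matrix of hidden band
#'   states, patients x visits, retained for validation), and `spec`.
#' @export
#' @examples
#' spec <- simulation_spec(default_base_case(), "intervention",
#'                         n_patients = 5, seed = 42)
#' head(simulate_cohort(spec)$measurements)
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cea_sim_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  n_visits <- spec$n_months + 1L
  bands <- matrix(0L, spec$n_patients, n_visits)
  e <- spec$band_edges
  lo_by_band <- c(within = e[2], below = e[1], above = e[3])
  hi_by_band <- c(within = e[3], below = e[2], above = e[4])
  day_mat <- matrix(0L, spec$n_patients, n_visits)
  inr_mat <- matrix(0, spec$n_patients, n_visits)
  for (i in seq_len(spec$n_patients)) {
    b <- integer(n_visits)
    b[1] <- sample.int(3L, 1L, prob = spec$init)
    for (t in 2:n_visits)
      b[t] <- sample.int(3L, 1L, prob = spec$bands[b[t - 1], ])
    jitter <- c(0L, sample.int(2L * spec$visit_jitter_days + 1L,
                               n_visits - 1L, replace = TRUE) -
                  spec$visit_jitter_days - 1L)
    bands[i, ] <- b
    day_mat[i, ] <- 30L * (seq_len(n_visits) - 1L) + jitter
    inr_mat[i, ] <- stats::runif(n_visits, lo_by_band[b], hi_by_band[b])
  }
  measurements <- data.frame(
    patient_id = rep(seq_len(spec$n_patients), each = n_visits),
    day = as.vector(t(day_mat)),
    inr = as.vector(t(inr_mat)))
  structure(list(measurements = measurements, bands = bands, spec = spec),
            class = "cea_trajectories")
}

#' @export
print.cea_trajectories <- function(x, ...) {
  cat(sprintf("<cea_trajectories> %d patients x %d visits (%s arm, seed %d)\n",
              x$spec$n_patients, x$spec$n_months + 1, x$spec$arm,
              x$spec$seed))
  invisible(x)
}

#' Estimate band transition probabilities from trajectories
#'
#' Maximum-likelihood estimates of the four arm-level INR band transition
#' probabilities: observed transition counts divided by source-band
#' exposures, with binomial standard errors. Uses the retained hidden band
#' sequences when available, else infers bands from the observed INR values
#' (equivalent, since the bands partition the INR axis).
#'
#' @param trajset A `cea_trajectories`, or a long data frame
#'   (`patient_id`, `day`, `inr`) in which case bands are inferred using
#'   `range_low`/`range_high`.
#' @param range_low,range_high Band edges for inference from raw INR.
#' @return Data frame with one row per estimated transition: `parameter`
#'   (named after the catalogue entries, without the arm suffix), `estimate`,
#'   `se`, `n_transitions`, `n_exposures`. Transitions out of a never-visited
#'   band have `NA` estimates.
#' @export
estimate_transition_probs <- function(trajset, range_low = 2.5,
                                      range_high = 3.5) {
  if (inherits(trajset, "cea_trajectories")) {
    bands <- trajset$bands
  } else {
    df <- trajset
    fid <- factor(df$patient_id, levels = unique(df$patient_id))
    chunks <- split(df[c("day", "inr")], fid)
    n_visits <- max(vapply(chunks, nrow, integer(1)))
    bands <- matrix(NA_integer_, length(chunks), n_visits)
    for (k in seq_along(chunks)) {
      sub <- chunks[[k]]
      inr <- sub$inr[order(sub$day)]
      b <- ifelse(inr < range_low, 2L, ifelse(inr > range_high, 3L, 1L))
      bands[k, seq_along(b)] <- b
    }
  }
  from <- as.vector(bands[, -ncol(bands), drop = FALSE])
  to <- as.vector(bands[, -1, drop = FALSE])
  keep <- !is.na(from) & !is.na(to)
  from <- from[keep]; to <- to[keep]
  est_one <- function(src, dst, name) {
    n_src <- sum(from == src)
    n_move <- sum(from == src & to == dst)
    p <- if (n_src == 0) NA_real_ else n_move / n_src
    se <- if (n_src == 0) NA_real_ else sqrt(p * (1 - p) / n_src)
    data.frame(parameter = name, estimate = p, se = se,
               n_transitions = n_move, n_exposures = n_src,
               stringsAsFactors = FALSE)
  }
  rbind(est_one(1L, 2L, "p_within_to_below"),
        est_one(1L, 3L, "p_within_to_above"),
        est_one(2L, 1L, "p_below_to_within"),
        est_one(3L, 1L, "p_above_to_within"))
}

#' Contrast two simulated arms on the TTR endpoint
#'
#' Scores every trajectory with [rosendaal_ttr()] and summarises each arm
#' (median/IQR TTR, control-category proportions), reporting whether the
#' intervention arm's median TTR exceeds the control arm's.
#'
#' @param intervention,control `cea_trajectories` objects.
#' @param range_low,range_high Therapeutic band edges.
#' @return List with `intervention` and `control` cohort summaries (see
#'   [cohort_ttr_summary()]) and `intervention_better` (logical).
#' @export
arm_contrast_check <- function(intervention, control, range_low = 2.5,
                               range_high = 3.5) {
  stopifnot(inherits(intervention, "cea_trajectories"),
            inherits(control, "cea_trajectories"))
  summarise <- function(ts) {
    per <- ttr_by_patient(ts$measurements, range_low, range_high)
    cohort_ttr_summary(per$ttr_percent)
  }
  si <- summarise(intervention)
  sc <- summarise(control)
  list(intervention = si, control = sc,
       intervention_better = si$median > sc$median)
}
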
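# Model parameter set: every ranged input of the published cost-effectiveness
# table (base case, low, high), plus the fixed run settings (cycle length,
# horizon, discounting flags, INR band edges).

# name, base, low, high for every ranged input; the single source of truth.
.table1 <- local({
  m <- matrix(c(
    # initial cohort proportions over the three no-event INR states
    "init_within_intervention",      0.9942,  0.8948,  1.0937,
    "init_below_intervention",       0.0029,  0.0026,  0.0032,
    "init_above_intervention",       0.0029,  0.0026,  0.0032,
    "init_within_control",           0.9855,  0.8869,  1.0840,
    "init_below_control",            0.0058,  0.0052,  0.0063,
    "init_above_control",            0.0087,  0.0079,  0.0096,
    # per-arm INR band transition probabilities (per 1-month cycle)
    "p_within_to_below_intervention", 0.0225, 0.0203,  0.0248,
    "p_within_to_above_intervention", 0.0191, 0.0172,  0.0210,
    "p_below_to_within_intervention", 0.4263, 0.3837,  0.4689,
    "p_above_to_within_intervention", 0.5712, 0.5141,  0.6283,
    "p_within_to_below_control",      0.0741, 0.0667,  0.0815,
    "p_within_to_above_control",      0.0383, 0.0345,  0.0421,
    "p_below_to_within_control",      0.1589, 0.1430,  0.1748,
    "p_above_to_within_control",      0.2910, 0.2619,  0.3201,
    # arm-independent event risks from the out-of-range states
    "p_above_to_bleeding",            0.0115, 0.0104,  0.0127,
    "p_below_to_te",                  0.0023, 0.0021,  0.0025,
    # event-state transitions
    "p_te_to_bleeding",               0.00228, 0.00205, 0.00251,
    "p_te_to_reoperation",            0.00033, 0.00030, 0.00037,
    "p_te_to_death",                  0.00374, 0.00337, 0.00412,
    "p_te_to_te",                     0.08825, 0.07942, 0.09707,
    "p_bleeding_to_te",               0.00059, 0.00053, 0.00064,
    "p_bleeding_to_reoperation",      0.00033, 0.00030, 0.00037,
    "p_bleeding_to_death",            0.01078, 0.00971, 0.01186,
    "p_bleeding_to_bleeding",         0.02049, 0.01844, 0.02254,
    "p_reop_to_te",                   0.00014, 0.00012, 0.00015,
    "p_reop_to_bleeding",             0.00028, 0.00025, 0.00031,
    "p_reop_to_death",                0.00035, 0.00031, 0.00038,
    "p_reop_to_reop",                 0.00033, 0.00030, 0.00037,
    # recovery-state transitions (recurrent events and background mortality)
    "p_recovery_to_te",               0.00059, 0.00025, 0.00109,
    "p_recovery_to_bleeding",         0.00228, 0.00109, 0.00532,
    "p_recovery_to_reoperation",      0.00033, 0.00017, 0.00075,
    "p_recovery_to_death",            0.00147, 0.00131, 0.00163,
    # excess mortality after a major event, multiplying recovery mortality
    "rr_death_major_te",              2.25,    1.75,    2.75,
    "rr_death_major_bleeding",        1.5,     1.0,     2.0,
    # utilities
    "u_within_range",                 0.987,   0.967,   0.998,
    "u_bleeding",                     0.54,    0.44,    0.74,
    "u_te",                           0.45,    0.35,    0.55,
    "u_reoperation",                  0.45,    0.35,    0.75,
    "u_recovery",                     0.668,   0.61,    0.76,
    # event costs, USD
    "c_bleeding",                     2777.78,  2500.00,  3055.56,
    "c_te",                           2314.81,  2083.33,  2546.30,
    "c_reoperation",                  16203.70, 14583.33, 17824.07,
    # annual discount rates
    "discount_rate_cost",             0.035,   0.02,    0.06,
    "discount_rate_qaly",             0.035,   0.02,    0.06
  ), ncol = 4, byrow = TRUE)
  data.frame(name = m[, 1],
             base = as.numeric(m[, 2]),
             low  = as.numeric(m[, 3]),
             high = as.numeric(m[, 4]),
             stringsAsFactors = FALSE)
})

.default_settings <- function() {
  list(cycle_length_months = 1L,
       horizon_cycles = 540L,
       half_cycle_correction = TRUE,
       cost_timing = "per_cycle",
       inr_range_low = 2.5,
       inr_range_high = 3.5)
}

#' Construct a single ranged parameter value
#'
#' @param base Base-case value.
#' @param low,high Range endpoints used by the one-way sensitivity analysis;
#'   default to `base` (a degenerate range).
#' @return An object of class `cea_par` with fields `base`, `low`, `high`.
#' @export
parameter_value <- function(base, low = base, high = base) {
  stopifnot(is.numeric(base), is.numeric(low), is.numeric(high),
            length(base) == 1L, length(low) == 1L, length(high) == 1L)
  if (low > base + 1e-12 || base > high + 1e-12)
    stop("parameter range must satisfy low <= base <= high", call. = FALSE)
  structure(list(base = base, low = low, high = high), class = "cea_par")
}

#' @export
print.cea_par <- function(x, ...) {
  cat(sprintf("%g [%g, %g]\n", x$base, x$low, x$high))
  invisible(x)
}

#' Base-case model configuration
#'
#' Returns the packaged base-case parameter set: every ranged model input
#' (initial cohort proportions per arm, per-arm INR band transition
#' probabilities, arm-independent event risks, event-state and recovery-state
#' transition probabilities, excess-mortality risk ratios, utilities, event
#' costs and annual discount rates) with its base/low/high values, plus the
#' fixed run settings.
#'
#' The run settings default to 1-month cycles over a 540-cycle (45-year)
#' lifetime horizon with trapezoidal half-cycle correction, per-cycle event
#' costing, and a therapeutic INR band of 2.5--3.5.
#'
#' @return An object of class `cea_config`: a list with elements `params`
#'   (named list of [parameter_value()] objects) and `settings`.
#' @seealso [load_config()], [parameter_catalog()], [set_parameter()]
#' @export
#' @examples
#' cfg <- default_base_case()
#' cfg$params$p_within_to_below_intervention$base
default_base_case <- function() {
  params <- lapply(seq_len(nrow(.table1)), function(i)
    parameter_value(.table1$base[i], .table1$low[i], .table1$high[i]))
  names(params) <- .table1$name
  cfg <- structure(list(params = params, settings = .default_settings()),
                   class = "cea_config")
  validate_config(cfg)
  cfg
}

#' @export
print.cea_config <- function(x, ...) {
  cat(sprintf("<cea_config> %d ranged parameters\n", length(x$params)))
  s <- x$settings
  cat(sprintf("  horizon: %d cycles of %d month(s), half-cycle correction %s\n",
              s$horizon_cycles, s$cycle_length_months,
              if (isTRUE(s$half_cycle_correction)) "on" else "off"))
  cat(sprintf("  therapeutic INR band: [%g, %g]; event costs charged %s\n",
              s$inr_range_low, s$inr_range_high, s$cost_timing))
  invisible(x)
}

# params whose base/low/high must lie in [0, 1]
.prob_params <- function() {
  n <- .table1$name
  n[startsWith(n, "p_") | startsWith(n, "u_") | startsWith(n, "init_") |
      startsWith(n, "discount_")]
}

#' Validate a model configuration
#'
#' Checks completeness (every packaged parameter present), range ordering
#' (low <= base <= high), probability/utility bounds, that each arm's initial
#' proportions sum to 1, that per-state outgoing base-case probabilities sum
#' to below 1, and the run settings.
#'
#' @param config A `cea_config` object.
#' @return The config, invisibly, if valid; otherwise an error naming the
#'   offending parameter or state row.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "cea_config"))
    stop("not a cea_config object", call. = FALSE)
  missing <- setdiff(.table1$name, names(config$params))
  if (length(missing))
    stop("config is missing required parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (nm in names(config$params)) {
    p <- config$params[[nm]]
    if (!inherits(p, "cea_par"))
      stop("parameter '", nm, "' is not a parameter_value()", call. = FALSE)
    vals <- c(p$base, p$low, p$high)
    if (any(!is.finite(vals)))
      stop("parameter '", nm, "' has non-finite values", call. = FALSE)
    if (nm %in% .prob_params()) {
      # SA high values may exceed 1 (they are clamped at use time), but the
      # base case itself must be a valid probability/utility
      if (p$base < 0 || p$base > 1)
        stop("parameter '", nm, "' base value ", p$base,
             " is outside [0, 1]", call. = FALSE)
      if (p$low < 0)
        stop("parameter '", nm, "' low value is negative", call. = FALSE)
    }
    if (startsWith(nm, "c_") && p$low < 0)
      stop("cost parameter '", nm, "' must be non-negative", call. = FALSE)
    if (startsWith(nm, "rr_") && p$low < 1)
      stop("risk ratio '", nm, "' must be >= 1", call. = FALSE)
  }
  pb <- function(nm) config$params[[nm]]$base
  for (arm in c("intervention", "control")) {
    s <- pb(paste0("init_within_", arm)) + pb(paste0("init_below_", arm)) +
      pb(paste0("init_above_", arm))
    if (abs(s - 1) > 1e-9)
      stop("initial proportions for the ", arm, " arm sum to ", s,
           ", not 1", call. = FALSE)
    rows <- list(
      WithinRange = pb(paste0("p_within_to_below_", arm)) +
        pb(paste0("p_within_to_above_", arm)),
      BelowRange = pb(paste0("p_below_to_within_", arm)) + pb("p_below_to_te"),
      AboveRange = pb(paste0("p_above_to_within_", arm)) +
        pb("p_above_to_bleeding"))
    for (rn in names(rows))
      if (rows[[rn]] > 1)
        stop("outgoing probabilities from state ", rn, " (", arm,
             " arm) sum to ", rows[[rn]], " > 1", call. = FALSE)
  }
  for (row in list(
    c("TE", "p_te_to_bleeding", "p_te_to_reoperation", "p_te_to_death",
      "p_te_to_te"),
    c("Bleeding", "p_bleeding_to_te", "p_bleeding_to_reoperation",
      "p_bleeding_to_death", "p_bleeding_to_bleeding"),
    c("Reoperation", "p_reop_to_te", "p_reop_to_bleeding", "p_reop_to_death",
      "p_reop_to_reop"))) {
    s <- sum(vapply(row[-1], pb, numeric(1)))
    if (s > 1)
      stop("outgoing probabilities from state ", row[1], " sum to ", s,
           " > 1", call. = FALSE)
  }
  st <- config$settings
  if (!is.numeric(st$horizon_cycles) || st$horizon_cycles < 1)
    stop("horizon_cycles must be >= 1", call. = FALSE)
  if (pb("discount_rate_cost") >= 1 || pb("discount_rate_qaly") >= 1)
    stop("annual discount rates must be below 1", call. = FALSE)
  if (st$inr_range_low >= st$inr_range_high)
    stop("inr_range_low must be below inr_range_high", call. = FALSE)
  if (!st$cost_timing %in% c("per_cycle", "per_entry"))
    stop("cost_timing must be 'per_cycle' or 'per_entry'", call. = FALSE)
  invisible(config)
}

#' Load a model configuration from JSON or YAML
#'
#' The file holds a flat mapping from parameter names (as listed by
#' [parameter_catalog()]) to either a single number (degenerate range) or an
#' object/mapping with `base`, `low`, `high` fields, plus an optional
#' `settings` block. Parameters absent from the file fall back to the
#' packaged base case with a warning.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `cea_config`.
#' @seealso [write_config()] for the inverse.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config format '", ext, "' (use json or yaml)",
         call. = FALSE))
  cfg <- default_base_case()
  given <- setdiff(names(raw), "settings")
  unknown <- setdiff(given, .table1$name)
  if (length(unknown))
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(.table1$name, given)
  if (length(absent))
    warning(length(absent), " parameter(s) not in config file; ",
            "falling back to packaged base-case values", call. = FALSE)
  for (nm in given) {
    v <- raw[[nm]]
    cfg$params[[nm]] <- if (is.list(v)) {
      if (is.null(v$base)) stop("parameter '", nm, "' lacks a 'base' field",
                                call. = FALSE)
      parameter_value(v$base,
                      if (is.null(v$low)) v$base else v$low,
                      if (is.null(v$high)) v$base else v$high)
    } else parameter_value(as.numeric(v))
  }
  if (!is.null(raw$settings))
    cfg$settings <- utils::modifyList(cfg$settings, raw$settings)
  cfg$settings$horizon_cycles <- as.integer(cfg$settings$horizon_cycles)
  validate_config(cfg)
  cfg
}

#' Write a model configuration to JSON or YAML
#'
#' @param config A `cea_config`.
#' @param path Destination path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  flat <- lapply(config$params, function(p)
    list(base = p$base, low = p$low, high = p$high))
  flat$settings <- config$settings
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    yaml = ,
    yml  = yaml::write_yaml(flat, path),
    stop("unsupported config format '", ext, "'", call. = FALSE))
  invisible(path)
}

#' Enumerate every ranged parameter
#'
#' Flat catalogue of all model inputs carrying a low/high range, in the
#' stable order used by the sensitivity-analysis driver and the tornado
#' output.
#'
#' @param config A `cea_config`.
#' @return A data frame with columns `name`, `base`, `low`, `high`.
#' @export
#' @examples
#' head(parameter_catalog(default_base_case()))
parameter_catalog <- function(config) {
  validate_config(config)
  data.frame(
    name = names(config$params),
    base = vapply(config$params, function(p) p$base, numeric(1)),
    low  = vapply(config$params, function(p) p$low, numeric(1)),
    high = vapply(config$params, function(p) p$high, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Set one parameter's point value
#'
#' Replaces the base value of a named parameter (collapsing its range to the
#' new value), as the one-way sensitivity driver does when pinning a
#' parameter at an extreme.
#'
#' @param config A `cea_config`.
#' @param name A parameter name from [parameter_catalog()].
#' @param value New point value.
#' @return The modified config (not revalidated: SA extremes may lie outside
#'   base-case invariants, e.g. initial proportions no longer summing to 1;
#'   such values are clamped/renormalised at matrix-build time).
#' @export
set_parameter <- function(config, name, value) {
  if (!name %in% names(config$params))
    stop("unknown parameter: ", name, call. = FALSE)
  config$params[[name]] <- parameter_value(value)
  config
}

# base value lookup used throughout the engine
.pv <- function(config, name) config$params[[name]]$base

# clamp probabilities to [0, 1]; SA highs may exceed 1 (e.g. an initial
# proportion upper bound of 1.0937), which is meaningless as a probability
.clamp01 <- function(x, what = NULL) {
  if (x < 0 || x > 1) {
    if (!is.null(what))
      message("clamping ", what, " = ", x, " into [0, 1]")
    x <- min(max(x, 0), 1)
  }
  x
}
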
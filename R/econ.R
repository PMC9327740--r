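# Incremental cost-effectiveness: ICER/dominance, willingness-to-pay
# classification, one-way (tornado) sensitivity analysis, and the
# within-range retention-reduction scenario.

#' Incremental cost-effectiveness of intervention vs control
#'
#' Differences are intervention minus control. The ICER is
#' `delta_cost / delta_qaly`, undefined when `delta_qaly` is 0. Dominance:
#' `intervention-dominant` when the intervention costs less and yields more
#' QALYs, `control-dominant` when the reverse holds on both axes, otherwise
#' `trade-off`.
#'
#' @param intervention,control `cea_arm_outcome` objects from the same
#'   configuration and horizon.
#' @return Object of class `cea_incremental`: list with `delta_cost`,
#'   `delta_qaly`, `icer` (`NA` when undefined), and `dominance`.
#' @export
#' @examples
#' res <- run_model(default_base_case())
#' res$incremental$icer
compute_icer <- function(intervention, control) {
  stopifnot(inherits(intervention, "cea_arm_outcome"),
            inherits(control, "cea_arm_outcome"))
  dc <- intervention$total_cost - control$total_cost
  dq <- intervention$total_qaly - control$total_qaly
  icer <- if (dq == 0) NA_real_ else dc / dq
  dominance <- if (dc < 0 && dq > 0) "intervention-dominant"
  else if (dc > 0 && dq < 0) "control-dominant"
  else "trade-off"
  structure(list(delta_cost = dc, delta_qaly = dq, icer = icer,
                 dominance = dominance), class = "cea_incremental")
}

#' @export
print.cea_incremental <- function(x, ...) {
  cat(sprintf("  difference:   %8.2f USD  %7.4f QALYs  ICER %s  [%s]\n",
              x$delta_cost, x$delta_qaly,
              if (is.na(x$icer)) "undefined" else sprintf("%.4f", x$icer),
              x$dominance))
  invisible(x)
}

#' Classify an incremental result against a willingness-to-pay threshold
#'
#' Follows the WHO convention: a dominant intervention is `cost-saving`;
#' otherwise an ICER at or below 1x GDP/capita per QALY is
#' `very cost-effective`, at or below 3x GDP/capita `cost-effective`, and
#' anything above `not cost-effective`. A control-dominated intervention
#' (more costly, fewer QALYs) is `not cost-effective`.
#'
#' @param result A `cea_incremental`.
#' @param gdp_per_capita GDP per capita in USD (> 0); the 1x/3x thresholds
#'   are derived from it.
#' @return One of `"cost-saving"`, `"very cost-effective"`,
#'   `"cost-effective"`, `"not cost-effective"`.
#' @export
#' @examples
#' res <- run_model(default_base_case())
#' classify_threshold(res$incremental, gdp_per_capita = 3000)
classify_threshold <- function(result, gdp_per_capita) {
  stopifnot(inherits(result, "cea_incremental"))
  if (!is.numeric(gdp_per_capita) || gdp_per_capita <= 0)
    stop("gdp_per_capita must be a positive number", call. = FALSE)
  if (result$dominance == "intervention-dominant") return("cost-saving")
  if (result$dominance == "control-dominant") return("not cost-effective")
  if (is.na(result$icer)) {
    # equal QALYs: decide by cost alone
    if (result$delta_cost < 0) return("cost-saving")
    if (result$delta_cost == 0) return("very cost-effective")
    stop("ICER undefined (equal QALYs) with higher cost: not classifiable ",
         "on a per-QALY threshold", call. = FALSE)
  }
  if (result$delta_qaly > 0) {
    # delta_cost >= 0 here (else dominant); icer >= 0
    if (result$icer <= gdp_per_capita) return("very cost-effective")
    if (result$icer <= 3 * gdp_per_capita) return("cost-effective")
    return("not cost-effective")
  }
  # fewer QALYs at lower cost: treat as not cost-effective unless savings per
  # QALY forgone exceed the 3x threshold (standard south-west quadrant rule)
  if (abs(result$icer) >= 3 * gdp_per_capita) "cost-effective"
  else "not cost-effective"
}

#' One-way sensitivity analysis (tornado)
#'
#' For every catalogued parameter, re-runs both arms with that single
#' parameter pinned at its low and then its high value (all others at base)
#' and records the resulting ICER and dominance label. Entries are sorted by
#' descending ICER span. An infeasible extreme (negative row remainder after
#' clamping) flags the entry instead of aborting the analysis.
#'
#' @param config A `cea_config` with ranges.
#' @param gdp_per_capita Optional GDP per capita; when supplied, threshold
#'   classifications at each extreme are added.
#' @return A data frame of class `cea_tornado`: one row per parameter with a
#'   non-degenerate range unless `keep_degenerate`, columns `parameter`,
#'   `low`, `high`, `icer_at_low`, `icer_at_high`, `span`, `dominance_at_low`,
#'   `dominance_at_high` (plus `class_at_low`/`class_at_high` with a GDP).
#' @param keep_degenerate Keep parameters whose range has collapsed to the
#'   base value (span 0)? Default `TRUE`, so the tornado enumerates the full
#'   catalogue.
#' @export
one_way_sensitivity <- function(config, gdp_per_capita = NULL,
                                keep_degenerate = TRUE) {
  validate_config(config)
  cat_df <- parameter_catalog(config)
  eval_extreme <- function(name, value) {
    cfg <- set_parameter(config, name, value)
    res <- tryCatch(suppressMessages(run_model(cfg, validate = FALSE))$incremental,
                    error = function(e) e)
    if (inherits(res, "error"))
      return(list(icer = NA_real_, dominance = "infeasible",
                  class = "infeasible"))
    list(icer = res$icer, dominance = res$dominance,
         class = if (is.null(gdp_per_capita)) NA_character_
                 else classify_threshold(res, gdp_per_capita))
  }
  rows <- lapply(seq_len(nrow(cat_df)), function(i) {
    lo <- eval_extreme(cat_df$name[i], cat_df$low[i])
    hi <- eval_extreme(cat_df$name[i], cat_df$high[i])
    data.frame(parameter = cat_df$name[i],
               low = cat_df$low[i], high = cat_df$high[i],
               icer_at_low = lo$icer, icer_at_high = hi$icer,
               span = abs(hi$icer - lo$icer),
               dominance_at_low = lo$dominance,
               dominance_at_high = hi$dominance,
               class_at_low = lo$class, class_at_high = hi$class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!keep_degenerate)
    out <- out[out$low != out$high, , drop = FALSE]
  if (is.null(gdp_per_capita))
    out$class_at_low <- out$class_at_high <- NULL
  out <- out[order(-out$span, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cea_tornado", "data.frame")
  out
}

#' Within-range retention-reduction scenario
#'
#' Cuts the intervention arm's probability of remaining in the therapeutic
#' range by a relative `fraction`; the freed probability mass is
#' redistributed to the two exit transitions (to below- and above-range)
#' proportionally to their base values. The model is re-run and the
#' incremental result returned.
#'
#' @param config A `cea_config`.
#' @param fraction Relative reduction of the within-range stay probability,
#'   in \[0, 1).
#' @return A `cea_incremental` (see [compute_icer()]), with the scenario
#'   config attached as attribute `config`.
#' @export
#' @examples
#' retention_reduction_scenario(default_base_case(), 0.10)
retention_reduction_scenario <- function(config, fraction) {
  validate_config(config)
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)", call. = FALSE)
  p_wb <- .pv(config, "p_within_to_below_intervention")
  p_wa <- .pv(config, "p_within_to_above_intervention")
  stay <- 1 - p_wb - p_wa
  if (stay <= 0) stop("within-range stay probability is not positive",
                      call. = FALSE)
  freed <- stay * fraction
  exits <- p_wb + p_wa
  if (exits <= 0) stop("no exit transitions to absorb the freed mass",
                       call. = FALSE)
  cfg <- set_parameter(config, "p_within_to_below_intervention",
                       p_wb + freed * p_wb / exits)
  cfg <- set_parameter(cfg, "p_within_to_above_intervention",
                       p_wa + freed * p_wa / exits)
  res <- run_model(cfg)$incremental
  attr(res, "config") <- cfg
  res
}
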
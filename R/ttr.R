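# Rosendaal time-in-therapeutic-range: linear interpolation of INR between
# successive measurements, apportioning calendar time to in-, below- and
# above-range.

#' Rosendaal time in therapeutic range
#'
#' Linearly interpolates the INR between consecutive measurements and
#' computes the fraction of the observed span (first to last measurement
#' day) during which the interpolated INR lies inside the therapeutic band
#' (boundaries inclusive), below it, and above it. Crossing points are
#' computed analytically per segment, so the result is exact for piecewise
#' linear trajectories.
#'
#' @param day Numeric vector of measurement days (strictly increasing,
#'   >= 0). Alternatively a data frame with columns `day` and `inr`.
#' @param inr Positive INR values, one per day; ignored when `day` is a
#'   data frame.
#' @param range_low,range_high Therapeutic band edges (default 2.5 and 3.5,
#'   the target band for mechanical mitral valve prostheses).
#' @param max_gap_days Segments between measurements further apart than this
#'   are dropped from both numerator and denominator. Default `Inf` (no
#'   exclusion): clinic visit intervals legitimately stretch when the INR is
#'   stable.
#' @return Object of class `ttr_result`: list with `ttr_percent`,
#'   `percent_below`, `percent_above` (summing to 100), `total_days`,
#'   `category` (see [categorize_ttr()]), and `n_measurements`.
#' @export
#' @examples
#' rosendaal_ttr(c(0, 30), c(2.0, 3.0))   # crosses 2.5 at day 15 -> 50%
rosendaal_ttr <- function(day, inr = NULL, range_low = 2.5, range_high = 3.5,
                          max_gap_days = Inf) {
  if (is.data.frame(day)) {
    inr <- day$inr
    day <- day$day
  }
  if (length(day) != length(inr))
    stop("day and inr must have equal length", call. = FALSE)
  if (length(day) < 2)
    stop("at least 2 INR measurements are required for a TTR", call. = FALSE)
  if (any(!is.finite(day)) || any(!is.finite(inr)))
    stop("day and inr must be finite", call. = FALSE)
  if (any(diff(day) <= 0))
    stop("measurement days must be strictly increasing", call. = FALSE)
  if (any(inr <= 0)) stop("INR values must be positive", call. = FALSE)
  if (range_low >= range_high)
    stop("range_low must be below range_high", call. = FALSE)

  n <- length(day)
  t_in <- 0; t_below <- 0; t_above <- 0; excluded <- 0
  for (i in seq_len(n - 1)) {
    dt <- day[i + 1] - day[i]
    if (dt > max_gap_days) {
      excluded <- excluded + dt
      next
    }
    y0 <- inr[i]; y1 <- inr[i + 1]
    if (y0 == y1) {
      if (y0 < range_low) t_below <- t_below + dt
      else if (y0 > range_high) t_above <- t_above + dt
      else t_in <- t_in + dt
    } else {
      ylo <- min(y0, y1); yhi <- max(y0, y1)
      # time is proportional to the INR measure swept, segment slope is linear
      frac <- function(a, b) max(0, min(b, yhi) - max(a, ylo)) / (yhi - ylo)
      t_below <- t_below + dt * frac(-Inf, range_low)
      t_in <- t_in + dt * frac(range_low, range_high)
      t_above <- t_above + dt * frac(range_high, Inf)
    }
  }
  total <- day[n] - day[1] - excluded
  if (total <= 0)
    stop("no assessable time remains after gap exclusion", call. = FALSE)
  res <- structure(list(
    ttr_percent = 100 * t_in / total,
    percent_below = 100 * t_below / total,
    percent_above = 100 * t_above / total,
    total_days = total,
    category = categorize_ttr(100 * t_in / total),
    n_measurements = n), class = "ttr_result")
  res
}

#' @export
print.ttr_result <- function(x, ...) {
  cat(sprintf("TTR %.2f%% (below %.2f%%, above %.2f%%) over %g days [%s]\n",
              x$ttr_percent, x$percent_below, x$percent_above, x$total_days,
              x$category))
  invisible(x)
}

#' Bin a TTR percentage into anticoagulation-control categories
#'
#' `<65%` marks poor control (the NICE threshold); 65 and 75 fall in the
#' middle bin, matching the strict `<65%` / `>75%` labels.
#'
#' @param ttr_percent TTR in \[0, 100\] (vectorised).
#' @return Character vector over `{"<65%", "65%-75%", ">75%"}`.
#' @export
#' @examples
#' categorize_ttr(c(64.99, 65, 75, 96.8))
categorize_ttr <- function(ttr_percent) {
  if (any(!is.finite(ttr_percent)) || any(ttr_percent < 0) ||
      any(ttr_percent > 100))
    stop("ttr_percent must lie in [0, 100]", call. = FALSE)
  ifelse(ttr_percent < 65, "<65%",
         ifelse(ttr_percent <= 75, "65%-75%", ">75%"))
}

#' Cohort TTR summary
#'
#' Median and interquartile range of per-patient TTR (linear-interpolation
#' quantile convention) and counts/percentages per control category.
#'
#' @param results A list of `ttr_result` objects, or a numeric vector of TTR
#'   percentages.
#' @return List with `n`, `median`, `q25`, `q75`, and `categories` (data
#'   frame with `category`, `count`, `percent`).
#' @export
cohort_ttr_summary <- function(results) {
  ttr <- if (is.numeric(results)) results
  else vapply(results, function(r) {
    if (!inherits(r, "ttr_result")) stop("expected ttr_result objects",
                                         call. = FALSE)
    r$ttr_percent
  }, numeric(1))
  if (length(ttr) == 0) stop("empty TTR collection", call. = FALSE)
  q <- stats::quantile(ttr, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  cats <- factor(categorize_ttr(ttr), levels = c("<65%", "65%-75%", ">75%"))
  tab <- table(cats)
  list(n = length(ttr), median = q[2], q25 = q[1], q75 = q[3],
       categories = data.frame(category = names(tab),
                               count = as.integer(tab),
                               percent = 100 * as.integer(tab) / length(ttr),
                               stringsAsFactors = FALSE))
}

#' Per-patient TTR from a long-format table
#'
#' @param df Data frame with columns `patient_id`, `day`, `inr` (the format
#'   written by [simulate_cohort()] exports and consumed by the CLI).
#' @param range_low,range_high Therapeutic band edges.
#' @return Data frame with one row per patient: `patient_id`, `ttr_percent`,
#'   `percent_below`, `percent_above`, `total_days`, `n_measurements`,
#'   `category`.
#' @export
ttr_by_patient <- function(df, range_low = 2.5, range_high = 3.5) {
  need <- c("patient_id", "day", "inr")
  if (!all(need %in% names(df)))
    stop("input must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  chunks <- split(df[c("day", "inr")],
                  factor(df$patient_id, levels = unique(df$patient_id)))
  rows <- lapply(names(chunks), function(id) {
    sub <- chunks[[id]]
    o <- order(sub$day)
    r <- rosendaal_ttr(sub$day[o], sub$inr[o], range_low, range_high)
    data.frame(patient_id = id, ttr_percent = r$ttr_percent,
               percent_below = r$percent_below,
               percent_above = r$percent_above, total_days = r$total_days,
               n_measurements = r$n_measurements, category = r$category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # preserve the input's id type where possible
  if (is.numeric(df$patient_id)) out$patient_id <- as.numeric(out$patient_id)
  out
}
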
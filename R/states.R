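#' Canonical health-state enumeration
#'
#' The cohort model distinguishes nine mutually exclusive health states: the
#' three no-event anticoagulation states defined by the INR band
#' (`WithinRange`: 2.5--3.5, `BelowRange`: < 2.5, `AboveRange`: > 3.5), three
#' acute event states (`Bleeding` = major bleeding requiring hospitalisation
#' or transfusion, `TE` = thromboembolism with morbidity, `Reoperation`),
#' two post-event recovery states (split by the preceding event so that the
#' excess-mortality risk ratios after major TE and after major bleeding or
#' reoperation have distinct homes), and absorbing `Death`.
#'
#' The order returned here is the canonical column/row order used by every
#' matrix, trace and CSV export in the package.
#'
#' @return Character vector of the nine state names, in canonical order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("WithinRange", "BelowRange", "AboveRange",
    "Bleeding", "TE", "Reoperation",
    "RecoveryPostTE", "RecoveryPostBleedOrReop", "Death")
}

# indices used internally; kept in one place so row assembly stays readable
.S <- list(W = 1L, B = 2L, A = 3L, BL = 4L, TE = 5L, RE = 6L,
           R_TE = 7L, R_BR = 8L, D = 9L)
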
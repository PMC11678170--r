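#' Maintenance dosing regimen
#'
#' A regimen is a dose amount (mg) administered subcutaneously once every
#' `interval` weeks ("qNw"). Intervals are converted to days as exactly
#' `7 * interval`.
#'
#' @param dose dose amount in mg (150 or 300 on the MIPD candidate grid;
#'   free-valued doses are allowed for simulation).
#' @param interval dosing interval in weeks.
#' @return An object of class `regimen` with fields `dose`, `interval`,
#'   `interval_days` and `label` (e.g. `"300 q4w"`).
#' @examples
#' regimen(300, 5)
#' @export
regimen <- function(dose, interval) {
  if (!is.numeric(dose) || length(dose) != 1 || dose <= 0)
    stop("dose must be a single positive number (mg)")
  if (!is.numeric(interval) || length(interval) != 1 || interval <= 0)
    stop("interval must be a single positive number (weeks)")
  structure(list(dose = dose, interval = interval,
                 interval_days = 7 * interval,
                 label = sprintf("%g q%gw", dose, interval)),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Regimen: %s mg SC every %g weeks (%g doses/year label basis)\n",
              x$dose, x$interval, round(365 / x$interval_days, 1)))
  invisible(x)
}

#' @export
format.regimen <- function(x, ...) x$label

#' Parse a regimen label
#'
#' Inverse of the `"DOSE qNw"` label convention, e.g. `"300 q4w"`.
#'
#' @param label character label.
#' @return A [regimen()] object.
#' @export
parse_regimen <- function(label) {
  m <- regmatches(label, regexec("^\\s*(\\d+(?:\\.\\d+)?)\\s*q(\\d+(?:\\.\\d+)?)w\\s*$",
                                 label))[[1]]
  if (length(m) != 3)
    stop(sprintf("cannot parse regimen label '%s' (expected e.g. '300 q4w')",
                 label))
  regimen(as.numeric(m[2]), as.numeric(m[3]))
}

#' Dose events implied by a regimen
#'
#' Expands a maintenance regimen into explicit subcutaneous dose events:
#' `n_cycles` administrations starting at `start` and spaced by the regimen
#' interval.
#'
#' @param reg a [regimen()] object.
#' @param n_cycles number of administrations.
#' @param start time of the first dose (days).
#' @return A data frame with columns `time` (days) and `amount` (mg).
#' @export
regimen_doses <- function(reg, n_cycles, start = 0) {
  stopifnot(inherits(reg, "regimen"), n_cycles >= 1)
  data.frame(time = start + (seq_len(n_cycles) - 1) * reg$interval_days,
             amount = reg$dose)
}

#' Dose event table constructor
#'
#' Validates an arbitrary dosing history (time in days since first dose,
#' amount in mg, subcutaneous route implied).
#'
#' @param time numeric vector of administration times (days, >= 0).
#' @param amount numeric vector of dose amounts (mg, > 0), recycled.
#' @return A sorted data frame with columns `time` and `amount`.
#' @export
dose_events <- function(time, amount) {
  if (any(time < 0)) stop("dose times must be non-negative")
  if (any(amount <= 0)) stop("dose amounts must be positive")
  d <- data.frame(time = time, amount = rep_len(amount, length(time)))
  d[order(d$time), , drop = FALSE]
}
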
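#' Pharmacodynamic parameter set (indirect-response PASI model)
#'
#' Parameters of the turnover model for the PASI score: psoriatic lesions are
#' produced at a zero-order rate `kin` and remit at a first-order rate
#' `kout`; the drug inhibits `kin` through an Imax model,
#' `kin * (1 - Imax * C / (IC50 + C))`, with the inhibition attenuated by a
#' tolerance mediator in tolerance-active patients. A chain of four prePASI
#' transit compartments (rate `ktr`, set equal to `kout` so that `kout`
#' remains the single PD rate constant) delays the drug effect relative to
#' exposure. `kin` is not free: it is derived from stationarity at baseline,
#' `kin = kout * pasi_base`.
#'
#' Defaults are the published population estimates: `kout` 0.11/day,
#' `kout_tol` 0.003/day, `imax` 1.19 (values above 1 are permitted; the
#' production term is floored at zero), `ic50` 9.35 mg/L (fixed to a
#' published value). The tolerance drive `slp` (input to the first mediator
#' compartment, `SLP * C(t)`) has no published magnitude; it defaults to 0
#' (tolerance off) and must be set for tolerance-active patients.
#'
#' @param kout first-order lesion remission rate (1/day).
#' @param imax maximum inhibition of lesion production (unitless, >= 0).
#' @param ic50 concentration of half-maximal inhibition (mg/L).
#' @param slp linear tolerance-driving slope (L/mg/day); 0 disables the
#'   tolerance mechanism.
#' @param kout_tol first-order tolerance remission rate (1/day).
#' @param pasi_base individual baseline PASI (unitless, >= 0).
#' @return An object of class `pd_parameters`: named list with the arguments
#'   plus the derived `kin` and `ktr`.
#' @examples
#' pd_parameters(pasi_base = 11.6)$kin  # 0.11 * 11.6
#' @export
pd_parameters <- function(kout = 0.11, imax = 1.19, ic50 = 9.35,
                          slp = 0, kout_tol = 0.003, pasi_base = 11.6) {
  if (kout <= 0) stop("kout must be strictly positive")
  if (ic50 <= 0) stop("ic50 must be strictly positive")
  if (imax < 0) stop("imax must be non-negative")
  if (slp < 0) stop("slp must be non-negative")
  if (kout_tol <= 0) stop("kout_tol must be strictly positive")
  if (pasi_base < 0) stop("pasi_base must be non-negative")
  structure(list(kout = kout, ktr = kout, kin = kout * pasi_base,
                 imax = imax, ic50 = ic50, slp = slp, kout_tol = kout_tol,
                 pasi_base = pasi_base),
            class = "pd_parameters")
}

#' @export
print.pd_parameters <- function(x, ...) {
  cat("Indirect-response PASI parameters\n")
  cat(sprintf("  kout %.4g 1/day, Imax %.4g, IC50 %.4g mg/L, baseline PASI %.4g\n",
              x$kout, x$imax, x$ic50, x$pasi_base))
  cat(sprintf("  tolerance: SLP %.4g, kout_tol %.4g 1/day (%s)\n",
              x$slp, x$kout_tol, if (x$slp > 0) "active" else "off"))
  invisible(x)
}

#' Fractional inhibition multiplier acting on lesion production
#'
#' Computes `max(0, 1 - (Imax * C / (IC50 + C)) / (1 + M3))`, the factor by
#' which drug exposure reduces the zero-order lesion production rate `kin`.
#' `M3` is the third tolerance mediator state; with `M3 = 0` the attenuation
#' `1/(1 + M3)` is 1. Because the published Imax estimate (1.19) exceeds 1,
#' the raw term can cross zero at high concentration; the floor encodes that
#' lesion production cannot run backwards.
#'
#' @param conc drug concentration (mg/L), vectorised.
#' @param imax maximum inhibition.
#' @param ic50 half-maximal concentration (mg/L).
#' @param m3 tolerance mediator level (>= 0), scalar or same length as
#'   `conc`.
#' @return Multiplier in `[0, 1]`, same length as `conc`.
#' @examples
#' inhibition_multiplier(9.35, imax = 1.19, ic50 = 9.35)  # 1 - 1.19/2
#' @export
inhibition_multiplier <- function(conc, imax = 1.19, ic50 = 9.35, m3 = 0) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  pmax(0, 1 - (imax * conc / (ic50 + conc)) / (1 + m3))
}

#' Individual parameter set
#'
#' Bundles one patient's weight-scaled PK parameters, PD parameters, the
#' realized log-scale random effects they were built from, and the tolerance
#' flag. See [sample_individual()] for the population construction.
#'
#' @param pk a [pk_parameters()] object (already weight-scaled).
#' @param pd a [pd_parameters()] object.
#' @param weight body weight (kg).
#' @param etas named numeric vector of realized random effects (log scale);
#'   may be empty for a typical individual.
#' @param tolerance_active logical; whether the tolerance mechanism is on.
#' @return An object of class `individual_parameters`.
#' @export
individual_parameters <- function(pk, pd, weight,
                                  etas = numeric(0),
                                  tolerance_active = FALSE) {
  stopifnot(inherits(pk, "pk_parameters"), inherits(pd, "pd_parameters"))
  structure(list(pk = pk, pd = pd, weight = weight, etas = etas,
                 tolerance_active = isTRUE(tolerance_active)),
            class = "individual_parameters")
}

#' @export
print.individual_parameters <- function(x, ...) {
  cat(sprintf("Individual PK/PD parameters (weight %.1f kg, tolerance %s)\n",
              x$weight, if (x$tolerance_active) "active" else "off"))
  print(x$pk)
  print(x$pd)
  if (length(x$etas))
    cat("  etas:", paste(sprintf("%s=%.3f", names(x$etas), x$etas),
                         collapse = ", "), "\n")
  invisible(x)
}
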
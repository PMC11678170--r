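#' Pharmacokinetic parameter set
#'
#' Constructs the parameter set of the two-compartment disposition model with
#' first-order subcutaneous absorption used for secukinumab. Default values
#' are the published typical values for patients with moderate-to-severe
#' plaque psoriasis: clearance 0.19 L/day, central volume 3.61 L, peripheral
#' volume 2.87 L, terminal half-life 27 days. The intercompartmental
#' clearance `q` is not printed in the source model summaries, so by default
#' it is calibrated so that the terminal half-life is exactly `t_half` days
#' (see [calibrate_q_to_half_life()]). Absorption rate (`ka`) and absolute
#' bioavailability (`f`) are not reported either; the defaults below are
#' package assumptions typical of subcutaneous monoclonal antibodies and can
#' be overridden.
#'
#' @param ka first-order absorption rate constant (1/day).
#' @param f absolute bioavailability, in (0, 1].
#' @param cl clearance (L/day).
#' @param v2 central volume of distribution (L).
#' @param v3 peripheral volume of distribution (L).
#' @param q intercompartmental clearance (L/day), or `NULL` to calibrate it
#'   to `t_half`.
#' @param t_half target terminal half-life (days) used only when `q` is
#'   `NULL`.
#'
#' @return An object of class `pk_parameters`: a named list with elements
#'   `ka`, `f`, `cl`, `v2`, `v3`, `q`.
#' @examples
#' pk <- pk_parameters()
#' terminal_half_life(pk)
#' @export
pk_parameters <- function(ka = 0.18, f = 0.73, cl = 0.19, v2 = 3.61,
                          v3 = 2.87, q = NULL, t_half = 27) {
  stopifnot(is.numeric(ka), is.numeric(f), is.numeric(cl),
            is.numeric(v2), is.numeric(v3))
  if (ka <= 0 || f <= 0 || v2 <= 0 || cl < 0 || v3 < 0)
    stop("PK parameters must be positive (cl and v3 may be zero)")
  if (f > 1) stop("bioavailability f must not exceed 1")
  if (is.null(q)) q <- calibrate_q_to_half_life(cl, v2, v3, t_half)
  if (q < 0) stop("intercompartmental clearance q must be non-negative")
  structure(list(ka = ka, f = f, cl = cl, v2 = v2, v3 = v3, q = q),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("Two-compartment PK parameters (SC, first-order absorption)\n")
  cat(sprintf("  ka %.4g 1/day, F %.3g, CL %.4g L/day, V2 %.4g L, V3 %.4g L, Q %.4g L/day\n",
              x$ka, x$f, x$cl, x$v2, x$v3, x$q))
  cat(sprintf("  terminal half-life %.2f days\n", terminal_half_life(x)))
  invisible(x)
}

#' Allometric body-weight scaling of PK parameters
#'
#' Scales clearance and central volume by body weight using power functions
#' centred at a reference weight: `CL_i = CL * (WT/ref)^exp_cl` and
#' `V2_i = V2 * (WT/ref)^exp_v2`. The retained covariate model uses exponent
#' 0.8 on clearance and 1 on the central volume. Absorption, bioavailability,
#' peripheral volume and intercompartmental clearance are unchanged.
#'
#' @param pk a [pk_parameters()] object holding typical values.
#' @param weight individual body weight (kg).
#' @param ref_weight centering weight (kg); 70 kg by default.
#' @param exp_cl allometric exponent on clearance.
#' @param exp_v2 allometric exponent on central volume.
#' @return A `pk_parameters` object with scaled `cl` and `v2`.
#' @examples
#' scale_pk_allometric(pk_parameters(), weight = 97)
#' @export
scale_pk_allometric <- function(pk, weight, ref_weight = 70,
                                exp_cl = 0.8, exp_v2 = 1) {
  stopifnot(inherits(pk, "pk_parameters"))
  if (!is.numeric(weight) || length(weight) != 1 || !is.finite(weight) ||
      weight <= 0)
    stop("weight must be a single positive number")
  if (ref_weight <= 0) stop("ref_weight must be positive")
  pk$cl <- pk$cl * (weight / ref_weight)^exp_cl
  pk$v2 <- pk$v2 * (weight / ref_weight)^exp_v2
  pk
}

# Disposition micro-constants and hybrid rate constants (alpha >= beta >= 0).
disposition_rates <- function(cl, v2, v3, q) {
  k10 <- cl / v2
  k12 <- q / v2
  k21 <- if (v3 > 0) q / v3 else 0
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(max(s^2 - 4 * p, 0))
  list(k10 = k10, k12 = k12, k21 = k21,
       alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

#' Terminal half-life of the two-compartment model
#'
#' Returns `ln(2)/beta`, where `beta` is the smaller eigenvalue magnitude of
#' the disposition matrix with `k10 = CL/V2`, `k12 = Q/V2`, `k21 = Q/V3`.
#' When the peripheral compartment is absent (`v3 = 0` or `q = 0`) this
#' collapses to the one-compartment value `ln(2) * V2 / CL`.
#'
#' @param pk a [pk_parameters()] object.
#' @return Terminal half-life in days.
#' @export
terminal_half_life <- function(pk) {
  stopifnot(inherits(pk, "pk_parameters"))
  if (pk$v3 <= 0 || pk$q <= 0) return(log(2) * pk$v2 / pk$cl)
  r <- disposition_rates(pk$cl, pk$v2, pk$v3, pk$q)
  log(2) / r$beta
}

#' Calibrate intercompartmental clearance to a target terminal half-life
#'
#' The published model summaries print the terminal half-life (27 days) but
#' not the intercompartmental clearance Q. This solves for the Q that
#' reproduces the requested half-life given CL, V2 and V3. The half-life is a
#' decreasing function of Q with infimum `ln(2) * (V2 + V3) / CL` (the
#' infinitely-fast-distribution limit), so a target at or below that bound is
#' infeasible and raises an error.
#'
#' @param cl clearance (L/day).
#' @param v2 central volume (L).
#' @param v3 peripheral volume (L).
#' @param t_half target terminal half-life (days).
#' @param tol relative tolerance of the root solve.
#' @return Intercompartmental clearance Q (L/day).
#' @examples
#' calibrate_q_to_half_life(0.19, 3.61, 2.87, 27)
#' @export
calibrate_q_to_half_life <- function(cl, v2, v3, t_half, tol = 1e-10) {
  stopifnot(cl > 0, v2 > 0, v3 > 0, t_half > 0)
  lower_limit <- log(2) * (v2 + v3) / cl
  if (t_half <= lower_limit * (1 + 1e-12))
    stop(sprintf(paste0("target half-life %.4g d is infeasible: the ",
                        "infinite-Q limit for CL=%.4g, V2=%.4g, V3=%.4g is ",
                        "%.4g d; choose a longer half-life"),
                 t_half, cl, v2, v3, lower_limit))
  beta_target <- log(2) / t_half
  fn <- function(q) {
    r <- disposition_rates(cl, v2, v3, q)
    r$beta - beta_target
  }
  # beta increases with Q from 0 towards ln2/lower_limit: bracket and solve
  hi <- 1
  while (fn(hi) < 0) hi <- hi * 10
  stats::uniroot(fn, lower = 0, upper = hi, tol = tol)$root
}
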
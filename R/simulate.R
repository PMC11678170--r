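#' Initial state of the PK/PD system
#'
#' Returns the pre-treatment steady state: all drug amounts zero, every
#' prePASI transit compartment and the PASI state at the individual baseline,
#' and the tolerance mediators at zero. Together with `kin = kout *
#' pasi_base` (set by [pd_parameters()]) this makes the system exactly
#' stationary in the absence of drug.
#'
#' @param pasi_base individual baseline PASI (>= 0).
#' @return Named numeric vector of the 11 states: `depot`, `central`,
#'   `periph`, `P1`..`P4`, `PASI`, `M1`..`M3`.
#' @export
initial_state <- function(pasi_base) {
  if (!is.numeric(pasi_base) || length(pasi_base) != 1 || pasi_base < 0)
    stop("pasi_base must be a single non-negative number")
  c(depot = 0, central = 0, periph = 0,
    P1 = pasi_base, P2 = pasi_base, P3 = pasi_base, P4 = pasi_base,
    PASI = pasi_base, M1 = 0, M2 = 0, M3 = 0)
}

pkpd_parms <- function(ind) {
  pk <- ind$pk
  pd <- ind$pd
  slp <- if (ind$tolerance_active) pd$slp else 0
  c(ka = pk$ka, cl = pk$cl, v2 = pk$v2, v3 = pk$v3, q = pk$q,
    kin = pd$kin, kout = pd$kout, ktr = pd$ktr,
    imax = pd$imax, ic50 = pd$ic50, slp = slp, ktol = pd$kout_tol)
}

#' Simulate concentration and PASI trajectories
#'
#' Integrates the full PK/PD ODE system (two-compartment PK with first-order
#' SC absorption, four prePASI transit compartments, PASI turnover, three
#' tolerance mediators) under an arbitrary dosing history. Doses enter as
#' boluses of `F * amount` into the absorption depot at their event times;
#' the solver is restarted at each event. Concentration is `central / V2`.
#'
#' @param ind an [individual_parameters()] object.
#' @param doses data frame with columns `time` (days) and `amount` (mg), as
#'   from [regimen_doses()] or [dose_events()]; may have zero rows.
#' @param times strictly increasing, non-negative output time grid (days).
#' @param rtol,atol solver tolerances (lsoda).
#' @return A data frame of class `pkpd_trajectory` with columns `time`,
#'   `conc` (mg/L), `pasi` and `tol` (third tolerance mediator), one row per
#'   requested time. The full state matrix is attached as attribute
#'   `"states"`.
#' @examples
#' ind <- individual_parameters(pk_parameters(), pd_parameters(pasi_base = 10),
#'                              weight = 70)
#' tr <- simulate_pkpd(ind, regimen_doses(regimen(300, 4), 6), times = 0:150)
#' @export
simulate_pkpd <- function(ind, doses, times, rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(ind, "individual_parameters"))
  if (is.null(doses)) doses <- data.frame(time = numeric(0), amount = numeric(0))
  if (!all(c("time", "amount") %in% names(doses)))
    stop("doses must have columns 'time' and 'amount'")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(times < 0)) stop("times must be non-negative")
  if (nrow(doses) && any(doses$time < 0)) stop("dose times must be non-negative")

  y0 <- initial_state(ind$pd$pasi_base)
  parms <- pkpd_parms(ind)

  out_times <- times
  solver_times <- sort(unique(c(0, times, doses$time[doses$time <= max(times)])))

  events <- NULL
  active <- doses[doses$time <= max(times), , drop = FALSE]
  if (nrow(active)) {
    amt <- tapply(active$amount, active$time, sum)
    events <- list(data = data.frame(
      var = 1L,                              # depot is state 1
      time = as.numeric(names(amt)),
      value = ind$pk$f * as.numeric(amt),
      method = "add"))
  }

  sol <- tryCatch(
    deSolve::lsoda(y = y0, times = solver_times, func = "secu_derivs",
                   parms = parms, dllname = "secumipd",
                   initfunc = "secu_initmod", events = events,
                   rtol = rtol, atol = atol, maxsteps = 50000),
    error = function(e)
      stop(sprintf("PK/PD simulation failed over [%g, %g] days: %s",
                   min(times), max(times), conditionMessage(e)))
  )
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("PK/PD solver did not converge over [%g, %g] days",
                 min(times), max(times)))

  sol <- as.data.frame(sol)
  sol <- sol[match(out_times, sol$time), , drop = FALSE]
  states <- as.matrix(sol[, -1, drop = FALSE])
  states[states < 0 & states > -atol * 10] <- 0  # clip solver noise
  traj <- data.frame(time = out_times,
                     conc = pmax(states[, "central"] / ind$pk$v2, 0),
                     pasi = pmax(states[, "PASI"], 0),
                     tol = pmax(states[, "M3"], 0))
  rownames(traj) <- NULL
  attr(traj, "states") <- states
  class(traj) <- c("pkpd_trajectory", "data.frame")
  traj
}

#' Closed-form PK profile (superposition of dose responses)
#'
#' Analytic solution of the linear PK subsystem: for each subcutaneous bolus,
#' the depot, central and peripheral amounts are sums of three exponentials
#' in the hybrid rate constants (alpha, beta, ka); profiles superpose across
#' doses. Used as an independent cross-check of the ODE integrator and as a
#' fast concentration evaluator. Requires alpha, beta and ka to be pairwise
#' distinct (always true for the default parameter set).
#'
#' @param pk a [pk_parameters()] object.
#' @param doses data frame with columns `time` and `amount`.
#' @param times output times (days).
#' @return Data frame with columns `time`, `depot`, `central`, `periph`,
#'   `conc`.
#' @export
pk_profile <- function(pk, doses, times) {
  stopifnot(inherits(pk, "pk_parameters"))
  r <- disposition_rates(pk$cl, pk$v2, pk$v3, pk$q)
  ka <- pk$ka
  rates <- c(ka, r$alpha, r$beta)
  if (min(dist(rates)) < 1e-9 * max(rates))
    stop("pk_profile requires distinct ka, alpha, beta; use simulate_pkpd")

  dep <- cen <- per <- numeric(length(times))
  da <- (ka - r$alpha) * (r$beta - r$alpha)
  db <- (ka - r$beta) * (r$alpha - r$beta)
  dk <- (r$alpha - ka) * (r$beta - ka)
  # left-limit convention at dose instants (matches the event handling of
  # the ODE integrator: the value reported at a dose time excludes the bolus)
  for (i in seq_len(nrow(doses))) {
    tau <- times - doses$time[i]
    on <- tau > 0
    if (!any(on)) next
    tau <- tau[on]
    d <- pk$f * doses$amount[i]
    ea <- exp(-r$alpha * tau); eb <- exp(-r$beta * tau); ek <- exp(-ka * tau)
    dep[on] <- dep[on] + d * ek
    cen[on] <- cen[on] + d * ka *
      ((r$k21 - r$alpha) * ea / da + (r$k21 - r$beta) * eb / db +
         (r$k21 - ka) * ek / dk)
    per[on] <- per[on] + d * ka * r$k12 * (ea / da + eb / db + ek / dk)
  }
  data.frame(time = times, depot = dep, central = cen, periph = per,
             conc = cen / pk$v2)
}

#' Trough concentration of a treatment cycle
#'
#' Concentration at the instant immediately before the dose that opens cycle
#' `cycle_index + 1`, i.e. at `cycle_index * interval` after the first
#' maintenance dose. The depot bolus does not change the central amount, so
#' the concentration is continuous at dose instants and the value at the
#' boundary is the left limit.
#'
#' @param traj a `pkpd_trajectory` from [simulate_pkpd()].
#' @param reg the [regimen()] in force.
#' @param cycle_index cycle whose end-of-cycle trough is requested (1-based).
#' @param start time of the first dose of this regimen (days).
#' @return Trough concentration (mg/L).
#' @export
trough_concentration <- function(traj, reg, cycle_index, start = 0) {
  stopifnot(inherits(traj, "pkpd_trajectory"), inherits(reg, "regimen"))
  t_trough <- start + cycle_index * reg$interval_days
  if (t_trough > max(traj$time) + 1e-9 || t_trough < min(traj$time) - 1e-9)
    stop(sprintf("cycle %d trough (day %g) is outside the simulated horizon [%g, %g]",
                 cycle_index, t_trough, min(traj$time), max(traj$time)))
  stats::approx(traj$time, traj$conc, xout = t_trough, rule = 2)$y
}

#' Fast PASI evaluation with a fixed concentration profile
#'
#' Integrates only the PD subsystem (prePASI chain, PASI, tolerance
#' mediators), with the concentration supplied as a linearly interpolated
#' forcing computed from the closed-form PK solution. Because the PK
#' parameters carry no sampled random effects, this path gives the same PASI
#' predictions as [simulate_pkpd()] at a fraction of the cost; it is the
#' workhorse of the likelihood evaluations. The forcing grid is the union of
#' a regular grid (`grid_step` days) and the dose times.
#'
#' @param ind an [individual_parameters()] object.
#' @param doses dose event data frame.
#' @param times output times (days, strictly increasing, >= 0).
#' @param grid_step spacing of the concentration forcing grid (days).
#' @param rtol,atol solver tolerances.
#' @return Data frame with columns `time`, `conc`, `pasi`, `tol`.
#' @export
simulate_pasi <- function(ind, doses, times, grid_step = 0.5,
                          rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(ind, "individual_parameters"))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  t_end <- max(times)
  fgrid <- sort(unique(c(seq(0, t_end, by = grid_step), t_end, times,
                         doses$time[doses$time <= t_end])))
  cf <- pk_profile(ind$pk, doses, fgrid)
  forcing <- cbind(cf$time, cf$conc)
  pasi <- pd_solve(ind, forcing, times, rtol = rtol, atol = atol)
  data.frame(time = times,
             conc = stats::approx(cf$time, cf$conc, xout = times, rule = 2)$y,
             pasi = pasi$pasi,
             tol = pasi$tol,
             row.names = NULL)
}

# Integrate the PD subsystem against a fixed concentration forcing matrix
# (two columns: time, conc). Returns list(pasi, tol) at `times`. Internal
# workhorse shared by simulate_pasi() and the likelihood evaluations, where
# the forcing is precomputed once per patient.
pd_solve <- function(ind, forcing, times, rtol = 1e-6, atol = 1e-8) {
  pd <- ind$pd
  slp <- if (ind$tolerance_active) pd$slp else 0
  parms <- c(kin = pd$kin, kout = pd$kout, ktr = pd$ktr, imax = pd$imax,
             ic50 = pd$ic50, slp = slp, ktol = pd$kout_tol)
  b <- pd$pasi_base
  y0 <- c(P1 = b, P2 = b, P3 = b, P4 = b, PASI = b, M1 = 0, M2 = 0, M3 = 0)
  solver_times <- if (times[1] > 0) c(0, times) else times
  sol <- deSolve::lsoda(y = y0, times = solver_times, func = "secu_pd_derivs",
                        parms = parms, dllname = "secumipd",
                        initfunc = "secu_pd_initmod",
                        initforc = "secu_pd_initforc",
                        forcings = forcing,
                        fcontrol = list(method = "linear", rule = 2),
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("PD solver did not converge over [%g, %g] days",
                 min(times), max(times)))
  keep <- match(times, solver_times)
  list(pasi = pmax(sol[keep, "PASI"], 0), tol = pmax(sol[keep, "M3"], 0))
}

#' State of the system at a given time
#'
#' Linear interpolation of the simulated PASI at a time point; used for
#' cycle-end evaluations.
#'
#' @param traj a `pkpd_trajectory`.
#' @param at time (days).
#' @return PASI value.
#' @keywords internal
pasi_at <- function(traj, at) {
  stats::approx(traj$time, traj$pasi, xout = at, rule = 2)$y
}
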
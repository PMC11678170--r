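#' Observation set for one patient
#'
#' Container for one patient's therapeutic drug monitoring data: time-stamped
#' PK concentrations and PASI scores (with censoring flags), the dosing
#' history, body weight and the observed baseline PASI.
#'
#' @param id patient identifier.
#' @param records data frame with columns `time` (days), `type` (`"pk"` or
#'   `"pasi"`), `value`, `cens` (0 observed, -1 below limit, 1 above limit).
#' @param doses dose event data frame (`time`, `amount`).
#' @param weight body weight (kg).
#' @param pasi_obs0 observed baseline PASI.
#' @param tolerance_active whether the tolerance mechanism is active for
#'   this patient.
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(id, records, doses, weight, pasi_obs0,
                            tolerance_active = FALSE) {
  if (nrow(records)) {
    stopifnot(all(c("time", "type", "value", "cens") %in% names(records)),
              all(records$type %in% c("pk", "pasi")),
              all(records$time >= 0))
    if (any(records$value < 0, na.rm = TRUE))
      stop("observed values must be non-negative")
  }
  structure(list(id = id, records = records, doses = doses, weight = weight,
                 pasi_obs0 = pasi_obs0,
                 tolerance_active = isTRUE(tolerance_active)),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("Observation set: patient %s (%.1f kg, baseline PASI %.1f)\n",
              x$id, x$weight, x$pasi_obs0))
  cat(sprintf("  %d PK records, %d PASI records, %d doses, tolerance %s\n",
              sum(x$records$type == "pk"), sum(x$records$type == "pasi"),
              nrow(x$doses), if (x$tolerance_active) "active" else "off"))
  invisible(x)
}

# Precompute everything about a patient's data that does not change when the
# PD random effects move: the concentration forcing, the PK predictions at
# the PK sampling times and their (constant) log-likelihood contribution.
likelihood_context <- function(obs, pop, grid_step = 1) {
  pk <- scale_pk_allometric(pop$pk_typical, obs$weight,
                            ref_weight = pop$allometry$ref_weight,
                            exp_cl = pop$allometry$exp_cl,
                            exp_v2 = pop$allometry$exp_v2)
  rec <- obs$records
  t_end <- max(c(rec$time, obs$doses$time, 1))
  fgrid <- sort(unique(c(seq(0, t_end, by = grid_step), t_end,
                         obs$doses$time[obs$doses$time <= t_end], rec$time)))
  cf <- pk_profile(pk, obs$doses, fgrid)
  forcing <- cbind(cf$time, cf$conc)

  ll_pk <- 0
  is_pk <- rec$type == "pk"
  if (any(is_pk)) {
    pred <- stats::approx(cf$time, cf$conc, xout = rec$time[is_pk],
                          rule = 2)$y
    pred <- pmax(pred, 1e-10)
    sdp <- pmax(pop$sigma_pk * pred, 1e-12)
    v <- rec$value[is_pk]
    cns <- rec$cens[is_pk]
    ll <- numeric(length(pred))
    ok <- cns == 0L
    ll[ok] <- stats::dnorm(v[ok], pred[ok], sdp[ok], log = TRUE)
    bql <- cns == -1L
    ll[bql] <- stats::pnorm(pop$obs$lloq_pk, pred[bql], sdp[bql],
                            log.p = TRUE)
    hi <- cns == 1L
    ll[hi] <- stats::pnorm(pop$obs$uloq_pk, pred[hi], sdp[hi],
                           lower.tail = FALSE, log.p = TRUE)
    ll_pk <- sum(ll)
  }

  pasi_idx <- which(rec$type == "pasi")
  list(pk = pk, forcing = forcing, ll_pk = ll_pk,
       pasi_times = rec$time[pasi_idx],
       pasi_values = rec$value[pasi_idx],
       pasi_cens = rec$cens[pasi_idx])
}

# PASI log-likelihood given predictions under the exponential error model,
# with left-censored records (recorded 0) contributing the log CDF below the
# recording threshold.
pasi_loglik <- function(values, cens, pred, sigma, threshold) {
  pred <- pmax(pred, 1e-10)
  ll <- numeric(length(pred))
  ok <- cens == 0L
  ll[ok] <- stats::dnorm(log(values[ok]), log(pred[ok]), sigma, log = TRUE) -
    log(values[ok])
  lc <- cens == -1L
  ll[lc] <- stats::pnorm(log(threshold), log(pred[lc]), sigma, log.p = TRUE)
  sum(ll)
}

#' Log-likelihood of an observation set given individual parameters
#'
#' Sums log-densities over the PK records (proportional normal error, with
#' below-LLOQ records contributing the log CDF at the limit) and the PASI
#' records (log-normal error; records stored as 0 contribute the log CDF
#' below the recording threshold). Returns a large negative surrogate
#' (rather than raising) when the trajectory simulation fails, so samplers
#' treat such parameter values as rejected.
#'
#' @param ind an [individual_parameters()] object.
#' @param obs an [observation_set()].
#' @param pop a [population_model()].
#' @return Scalar log-likelihood; 0 with a warning for an empty observation
#'   set.
#' @export
log_likelihood <- function(ind, obs, pop) {
  stopifnot(inherits(ind, "individual_parameters"),
            inherits(obs, "observation_set"),
            inherits(pop, "population_model"))
  if (nrow(obs$records) == 0) {
    warning("empty observation set: log-likelihood is 0")
    return(0)
  }
  ctx <- likelihood_context(obs, pop)
  log_likelihood_ctx(ind, ctx, pop)
}

log_likelihood_ctx <- function(ind, ctx, pop) {
  ll <- ctx$ll_pk
  if (length(ctx$pasi_times)) {
    sim_t <- sort(unique(ctx$pasi_times[ctx$pasi_times > 0]))
    pred <- rep(ind$pd$pasi_base, length(ctx$pasi_times))  # t = 0: baseline
    if (length(sim_t)) {
      sim <- tryCatch(pd_solve(ind, ctx$forcing, sim_t),
                      error = function(e) NULL)
      if (is.null(sim)) return(-1e10)
      pos <- ctx$pasi_times > 0
      pred[pos] <- sim$pasi[match(ctx$pasi_times[pos], sim_t)]
    }
    ll <- ll + pasi_loglik(ctx$pasi_values, ctx$pasi_cens, pred,
                           pop$sigma_pasi, pop$obs$pasi_zero_threshold)
  }
  if (!is.finite(ll)) return(-1e10)
  ll
}

#' Log-prior of the individual random effects
#'
#' Sum of `N(0, omega^2)` log-densities over the realized random effects of
#' the individual: `kout`, `kout_tol` and `imax` use the population IIV SDs;
#' the baseline effect `rv` uses the residual SD (B2 constraint). A nonzero
#' eta whose name has no variance in the population model is a configuration
#' error.
#'
#' @param ind an [individual_parameters()] object carrying `etas`.
#' @param pop a [population_model()].
#' @return Scalar log-prior density.
#' @export
log_prior <- function(ind, pop) {
  stopifnot(inherits(ind, "individual_parameters"),
            inherits(pop, "population_model"))
  etas <- ind$etas
  if (!length(etas)) return(0)
  sds <- eta_sds(pop)[names(etas)]
  if (any(is.na(sds)))
    stop("random effect without a population variance: ",
         paste(names(etas)[is.na(sds)], collapse = ", "))
  if (any(sds == 0 & etas != 0))
    stop("nonzero random effect with zero population variance")
  sum(stats::dnorm(etas[sds > 0], 0, sds[sds > 0], log = TRUE))
}

eta_sds <- function(pop) {
  c(kout = pop$omega[["kout"]], kout_tol = pop$omega[["kout_tol"]],
    imax = pop$omega[["imax"]], rv = pop$sigma_pasi)
}

# Names of the random effects sampled for a patient: the tolerance rate
# random effect is only sampled when the tolerance mechanism is active.
sampled_eta_names <- function(tolerance_active) {
  if (tolerance_active) c("kout", "imax", "rv", "kout_tol")
  else c("kout", "imax", "rv")
}

log_posterior_ctx <- function(eta, nm, obs, ctx, pop) {
  etas <- stats::setNames(eta, nm)
  ind <- make_individual(pop, obs$weight, obs$pasi_obs0, etas,
                         tolerance_active = obs$tolerance_active)
  lp <- log_prior(ind, pop)
  lp + log_likelihood_ctx(ind, ctx, pop)
}

#' Maximum a posteriori (MAP) estimate of individual parameters
#'
#' Maximizes `log_likelihood + log_prior` over the individual log-scale
#' random effects (empirical Bayes estimate) with a multi-start Nelder-Mead
#' search (starts at 0 and at +/- 0.5 SD on every coordinate); the best
#' objective is kept. With no observations the prior mode (all etas zero) is
#' returned.
#'
#' @param obs an [observation_set()].
#' @param pop a [population_model()].
#' @param maxit optimizer iteration cap per start.
#' @return A list with elements `individual` (an [individual_parameters()]),
#'   `etas`, and `objective` (the attained log-posterior, up to the constant
#'   `p(y)`).
#' @export
map_estimate <- function(obs, pop, maxit = 500) {
  stopifnot(inherits(obs, "observation_set"),
            inherits(pop, "population_model"))
  nm <- sampled_eta_names(obs$tolerance_active)
  sds <- eta_sds(pop)[nm]
  nm <- nm[sds > 0]
  sds <- sds[sds > 0]
  zero <- stats::setNames(rep(0, length(nm)), nm)
  if (nrow(obs$records) == 0) {
    ind <- make_individual(pop, obs$weight, obs$pasi_obs0, zero,
                           obs$tolerance_active)
    return(list(individual = ind, etas = zero,
                objective = log_prior(ind, pop)))
  }
  ctx <- likelihood_context(obs, pop)
  negpost <- function(eta) -log_posterior_ctx(eta, nm, obs, ctx, pop)
  starts <- list(zero, zero + 0.5 * sds, zero - 0.5 * sds)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negpost, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("MAP estimation failed from all starts")
  etas <- stats::setNames(best$par, nm)
  list(individual = make_individual(pop, obs$weight, obs$pasi_obs0, etas,
                                    obs$tolerance_active),
       etas = etas, objective = -best$value)
}

# Effective sample size by initial-positive-sequence autocorrelation sum.
ess_chain <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) {
    if (r < 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' Sample the individual conditional parameter distribution
#'
#' Random-walk Metropolis-Hastings on the log-scale random effects,
#' targeting `log_likelihood + log_prior` (the conditional distribution
#' p(psi_i | y_i) up to the normalizing constant p(y_i), which is never
#' computed). A joint Gaussian proposal is used, with its scale adapted
#' during burn-in towards an acceptance rate of 20-40%; after burn-in the
#' kept iterations are thinned to exactly `n_clones` draws ("clones").
#' Deterministic given `seed`. With no observations the target reduces to
#' the prior.
#'
#' @param obs an [observation_set()].
#' @param pop a [population_model()].
#' @param n_clones number of conditional draws to return.
#' @param seed integer seed (required: clone sets must be reproducible).
#' @param burn_in adaptation iterations discarded before sampling.
#' @param n_iter post-burn-in iterations thinned down to `n_clones`.
#' @param start `"map"` to start at the MAP estimate, or a named numeric
#'   vector of starting etas.
#' @param sample_etas names of the random effects to sample; defaults to
#'   every effect of the patient (kout, imax, rv, plus kout_tol when the
#'   tolerance mechanism is active) whose population SD is positive.
#'   Restricting to a single name gives a one-dimensional chain, useful for
#'   validating the sampler against grid integration.
#' @return An object of class `conditional_sample`: list with `draws` (a
#'   list of [individual_parameters()]), `etas` (matrix `n_clones` x
#'   n-effects), `acceptance_rate`, `ess` (effective sample size per
#'   effect over the kept iterations), and `seed`.
#' @export
sample_conditional <- function(obs, pop, n_clones = 100, seed,
                               burn_in = 300, n_iter = 1200,
                               start = "map", sample_etas = NULL) {
  stopifnot(inherits(obs, "observation_set"),
            inherits(pop, "population_model"),
            n_clones >= 1, n_iter >= n_clones)
  if (missing(seed) || is.null(seed))
    stop("an explicit seed is required for conditional sampling")
  set.seed(seed)

  nm <- sampled_eta_names(obs$tolerance_active)
  if (!is.null(sample_etas)) {
    if (!all(sample_etas %in% nm))
      stop("sample_etas must be a subset of: ", paste(nm, collapse = ", "))
    nm <- sample_etas
  }
  sds <- eta_sds(pop)[nm]
  nm <- nm[sds > 0]  # zero-variance effects stay fixed at zero
  sds <- sds[sds > 0]
  if (!length(nm)) stop("no random effect with positive variance to sample")
  has_data <- nrow(obs$records) > 0
  ctx <- if (has_data) likelihood_context(obs, pop) else NULL

  logpost <- function(eta) {
    lp <- sum(stats::dnorm(eta, 0, sds, log = TRUE))
    if (!has_data) return(lp)
    etas <- stats::setNames(eta, nm)
    ind <- make_individual(pop, obs$weight, obs$pasi_obs0, etas,
                           obs$tolerance_active)
    lp + log_likelihood_ctx(ind, ctx, pop)
  }

  if (identical(start, "map")) {
    cur <- if (has_data) map_estimate(obs, pop)$etas[nm]
           else stats::setNames(rep(0, length(nm)), nm)
  } else {
    cur <- start[nm]
  }
  cur <- as.numeric(cur)
  cur_lp <- logpost(cur)
  scale <- 0.5
  prop_sd <- pmax(sds, 1e-3)

  total <- burn_in + n_iter
  keep <- matrix(NA_real_, n_iter, length(nm),
                 dimnames = list(NULL, nm))
  acc_window <- 0
  acc_kept <- 0
  window <- 50
  for (i in seq_len(total)) {
    prop <- cur + scale * prop_sd * stats::rnorm(length(nm))
    lp <- logpost(prop)
    if (is.finite(lp) && log(stats::runif(1)) < lp - cur_lp) {
      cur <- prop
      cur_lp <- lp
      acc_window <- acc_window + 1
      if (i > burn_in) acc_kept <- acc_kept + 1
    }
    if (i <= burn_in && i %% window == 0) {
      rate <- acc_window / window
      if (rate < 0.2) scale <- scale * 0.7
      else if (rate > 0.4) scale <- scale * 1.4
      acc_window <- 0
    }
    if (i == burn_in) acc_window <- 0
    if (i > burn_in) keep[i - burn_in, ] <- cur
  }
  acceptance_rate <- acc_kept / n_iter
  if (acceptance_rate < 0.01)
    stop(sprintf(paste0("conditional sampler degenerate for patient %s: ",
                        "acceptance %.3f after adaptation (scale %.3g)"),
                 obs$id, acceptance_rate, scale))

  idx <- unique(round(seq(1, n_iter, length.out = n_clones)))
  while (length(idx) < n_clones)  # duplicates collapse only when n_iter ~ n_clones
    idx <- sort(c(idx, sample(setdiff(seq_len(n_iter), idx), 1)))
  etas <- keep[idx, , drop = FALSE]

  draws <- lapply(seq_len(nrow(etas)), function(i)
    make_individual(pop, obs$weight, obs$pasi_obs0,
                    stats::setNames(etas[i, ], nm),
                    obs$tolerance_active))
  structure(list(draws = draws, etas = etas,
                 acceptance_rate = acceptance_rate,
                 ess = apply(keep, 2, ess_chain),
                 seed = seed, patient = obs$id),
            class = "conditional_sample")
}

#' @export
print.conditional_sample <- function(x, ...) {
  cat(sprintf("Conditional sample: patient %s, %d clones (seed %s)\n",
              x$patient, nrow(x$etas), format(x$seed)))
  cat(sprintf("  acceptance %.2f; ESS %s\n", x$acceptance_rate,
              paste(sprintf("%s %.0f", names(x$ess), x$ess), collapse = ", ")))
  invisible(x)
}
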
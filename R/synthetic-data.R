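#' Synthetic cohort specification
#'
#' Statistical description of the study cohort emulated by
#' [generate_cohort()]: 22 patients, body weight truncated-normal
#' (mean 74.5, SD 15, bounds 46-97 kg), observed baseline PASI
#' truncated-normal (mean 11.6, SD 5.8, bounds 2-27.5), a regimen mix of
#' 18/22 on 300 mg q4w with a 150 q4w / 300 q5w / 300 q6w minority, and 4/22
#' tolerance-active patients.
#'
#' @param n_patients cohort size.
#' @param weight_mean,weight_sd,weight_range weight distribution (kg).
#' @param pasi_mean,pasi_sd,pasi_range observed baseline PASI distribution.
#' @param regimen_counts named integer vector (names are regimen labels)
#'   summing to `n_patients`.
#' @param n_tolerance number of tolerance-active patients.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 22,
                        weight_mean = 74.5, weight_sd = 15,
                        weight_range = c(46, 97),
                        pasi_mean = 11.6, pasi_sd = 5.8,
                        pasi_range = c(2, 27.5),
                        regimen_counts = c("300 q4w" = 18, "150 q4w" = 2,
                                           "300 q5w" = 1, "300 q6w" = 1),
                        n_tolerance = 4) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (weight_range[1] >= weight_range[2] || pasi_range[1] >= pasi_range[2])
    stop("range bounds must be ordered")
  counts <- round(regimen_counts * n_patients / sum(regimen_counts))
  while (sum(counts) != n_patients)  # fix rounding drift on rescaled cohorts
    counts[1] <- counts[1] + sign(n_patients - sum(counts))
  if (n_tolerance > n_patients)
    stop("n_tolerance cannot exceed n_patients")
  structure(list(n_patients = n_patients,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 weight_range = weight_range,
                 pasi_mean = pasi_mean, pasi_sd = pasi_sd,
                 pasi_range = pasi_range,
                 regimen_counts = counts, n_tolerance = n_tolerance),
            class = "cohort_spec")
}

# Truncated-normal sampling by rejection: exact bounds, no approximation.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Scenario presets for synthetic cohorts
#'
#' Named overrides reproducing the response phenotypes discussed for this
#' population: `non_responder` lowers the typical lesion remission rate to
#' `kout = 0.07`/day (the reported cutoff separating patients unlikely to
#' respond); `intensification_candidate` draws each patient's Imax uniformly
#' in 1.06-1.13, below the typical 1.19; `tolerance` activates the tolerance
#' mechanism in every patient; `typical` is the published model unchanged.
#'
#' @param name one of `"typical"`, `"non_responder"`,
#'   `"intensification_candidate"`, `"tolerance"`.
#' @return A list with elements `kout` (typical value override or `NULL`),
#'   `imax_range` (per-patient uniform range or `NULL`),
#'   `tolerance_all` (logical).
#' @export
scenario_preset <- function(name = c("typical", "non_responder",
                                     "intensification_candidate",
                                     "tolerance")) {
  name <- match.arg(name)
  switch(name,
    typical = list(kout = NULL, imax_range = NULL, tolerance_all = FALSE),
    non_responder = list(kout = 0.07, imax_range = NULL,
                         tolerance_all = FALSE),
    intensification_candidate = list(kout = NULL,
                                     imax_range = c(1.06, 1.13),
                                     tolerance_all = FALSE),
    tolerance = list(kout = NULL, imax_range = NULL, tolerance_all = TRUE))
}

#' Generate a virtual cohort
#'
#' Draws covariates from the truncated distributions of the [cohort_spec()],
#' assigns regimens and tolerance flags, and samples each patient's true
#' individual parameters from the population model (the truths are retained
#' for parameter-recovery experiments). Weight and baseline PASI are drawn
#' independently. Deterministic given `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param pop a [population_model()].
#' @param seed integer seed (required).
#' @param scenario optional [scenario_preset()] overrides.
#' @return A list of class `cohort`; each element has `id`, `weight`,
#'   `pasi_obs0`, `regimen` (a [regimen()]), `tolerance_active` and `truth`
#'   (an [individual_parameters()]).
#' @export
generate_cohort <- function(spec = cohort_spec(), pop = default_population(),
                            seed, scenario = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(pop, "population_model"))
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  set.seed(seed)
  n <- spec$n_patients
  if (!is.null(scenario) && !is.null(scenario$kout)) {
    pd <- pop$pd_typical
    pop$pd_typical <- pd_parameters(kout = scenario$kout, imax = pd$imax,
                                    ic50 = pd$ic50, slp = pd$slp,
                                    kout_tol = pd$kout_tol,
                                    pasi_base = pd$pasi_base)
  }
  weights <- rtruncnorm(n, spec$weight_mean, spec$weight_sd,
                        spec$weight_range[1], spec$weight_range[2])
  pasi0 <- rtruncnorm(n, spec$pasi_mean, spec$pasi_sd,
                      spec$pasi_range[1], spec$pasi_range[2])
  regs <- sample(rep(names(spec$regimen_counts), spec$regimen_counts))
  tol_ids <- if (!is.null(scenario) && scenario$tolerance_all) seq_len(n)
             else sample(n, spec$n_tolerance)
  cohort <- lapply(seq_len(n), function(i) {
    popi <- pop
    if (!is.null(scenario) && !is.null(scenario$imax_range)) {
      imax_i <- stats::runif(1, scenario$imax_range[1], scenario$imax_range[2])
      pd <- popi$pd_typical
      popi$pd_typical <- pd_parameters(kout = pd$kout, imax = imax_i,
                                       ic50 = pd$ic50, slp = pd$slp,
                                       kout_tol = pd$kout_tol,
                                       pasi_base = pd$pasi_base)
      popi$omega[["imax"]] <- 0  # Imax set deterministically per patient
    }
    truth <- sample_individual(popi, weights[i], pasi0[i],
                               tolerance_active = i %in% tol_ids)
    list(id = i, weight = weights[i], pasi_obs0 = pasi0[i],
         regimen = parse_regimen(regs[i]),
         tolerance_active = i %in% tol_ids,
         truth = truth, population = popi)
  })
  structure(cohort, class = "cohort", seed = seed)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients (seed %s)\n", length(x),
              format(attr(x, "seed"))))
  regs <- table(vapply(x, function(p) p$regimen$label, character(1)))
  cat("  regimens:", paste(sprintf("%s x%d", names(regs), regs),
                           collapse = ", "), "\n")
  cat(sprintf("  tolerance-active: %d\n",
              sum(vapply(x, `[[`, logical(1), "tolerance_active"))))
  invisible(x)
}

#' Therapeutic drug monitoring sampling design
#'
#' The sampling schedule emulated for virtual patients: PK samples pre-dose
#' and at fixed offsets (about 2, 7, 14, 22, 30 and 40 days) after a
#' reference maintenance dose, and PASI visits at baseline, once in weeks
#' 5-6, once in weeks 16-24, and every 6 months thereafter. The study
#' averaged about four PK samples per patient, so each virtual patient
#' receives `n_pk_per_patient` offsets drawn from the design without
#' replacement (plus the pre-dose sample).
#'
#' @param pk_offsets days post reference dose (0 = pre-dose trough).
#' @param n_pk_per_patient PK samples drawn per patient from the offsets.
#' @param pasi_every_days interval of long-term PASI visits (days).
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(pk_offsets = c(0, 2, 7, 14, 22, 30, 40),
                            n_pk_per_patient = 4,
                            pasi_every_days = 182) {
  if (any(pk_offsets < 0) || is.unsorted(pk_offsets))
    stop("pk_offsets must be non-negative and sorted")
  structure(list(pk_offsets = pk_offsets,
                 n_pk_per_patient = min(n_pk_per_patient, length(pk_offsets)),
                 pasi_every_days = pasi_every_days),
            class = "sampling_design")
}

#' Simulate a therapeutic drug monitoring trial on a virtual cohort
#'
#' Simulates each patient's true trajectory under their assigned maintenance
#' regimen for `duration_years`, samples concentrations and PASI scores at
#' the design times with residual error and assay censoring
#' ([apply_residual()]), and returns one [observation_set()] per patient.
#' PASI visit times are jittered uniformly within their scheduling windows.
#' The observed baseline PASI is included as a PASI record at time 0 (it is
#' a measured data point; the B2 baseline model treats it with the same
#' residual error as later scores). Deterministic given `seed`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param pop the [population_model()] used for residual error.
#' @param design a [sampling_design()].
#' @param duration_years follow-up duration.
#' @param seed integer seed (required).
#' @return A list of [observation_set()] objects.
#' @export
simulate_trial <- function(cohort, pop = default_population(),
                           design = sampling_design(),
                           duration_years = 1.5, seed) {
  stopifnot(inherits(cohort, "cohort"), inherits(design, "sampling_design"))
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  set.seed(seed)
  horizon <- duration_years * 365
  if (max(design$pk_offsets) > horizon)
    stop("PK sampling offsets extend beyond the trial duration")
  lapply(cohort, function(p) {
    reg <- p$regimen
    n_doses <- ceiling(horizon / reg$interval_days)
    doses <- regimen_doses(reg, n_doses)

    # PK sampling anchored at the last dose that leaves the longest offset
    # inside the follow-up window (steady-state region of the schedule)
    offs <- sort(c(0, sample(setdiff(design$pk_offsets, 0),
                             design$n_pk_per_patient)))
    ref_dose <- max(doses$time[doses$time + max(offs) <= horizon])
    pk_times <- ref_dose + offs

    pasi_times <- c(stats::runif(1, 35, 42), stats::runif(1, 112, 168))
    nxt <- max(pasi_times) + design$pasi_every_days
    while (nxt <= horizon) {
      pasi_times <- c(pasi_times, nxt)
      nxt <- nxt + design$pasi_every_days
    }

    all_t <- sort(unique(c(pk_times, pasi_times)))
    traj <- simulate_pasi(p$truth, doses, all_t)
    pk_pred <- traj$conc[match(pk_times, traj$time)]
    pasi_pred <- traj$pasi[match(pasi_times, traj$time)]

    pk_obs <- apply_residual(pk_pred, pop, "pk")
    pasi_obs <- apply_residual(pasi_pred, pop, "pasi")
    base_obs <- data.frame(time = 0, type = "pasi", value = p$pasi_obs0,
                           cens = 0L)
    records <- rbind(
      base_obs,
      data.frame(time = pk_times, type = "pk", value = pk_obs$value,
                 cens = pk_obs$cens),
      data.frame(time = pasi_times, type = "pasi", value = pasi_obs$value,
                 cens = pasi_obs$cens))
    records <- records[order(records$time, records$type), ]
    rownames(records) <- NULL
    observation_set(p$id, records, doses, p$weight, p$pasi_obs0,
                    tolerance_active = p$tolerance_active)
  })
}
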
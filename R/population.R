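#' Observation model specification
#'
#' Error forms and censoring limits of the therapeutic drug monitoring data:
#' PASI scores carry exponential (log-normal) residual error and are recorded
#' as 0 below a small threshold; serum concentrations carry proportional
#' error and are quantifiable between the assay limits 0.2 and 225 mg/L.
#'
#' @param lloq_pk lower limit of quantification of the assay (mg/L).
#' @param uloq_pk upper limit of the calibration range (mg/L).
#' @param pasi_zero_threshold observed PASI values below this are recorded
#'   as 0 and treated as left-censored.
#' @return An object of class `observation_model_spec`.
#' @export
observation_model_spec <- function(lloq_pk = 0.2, uloq_pk = 225,
                                   pasi_zero_threshold = 0.05) {
  if (lloq_pk >= uloq_pk) stop("lloq_pk must be below uloq_pk")
  if (pasi_zero_threshold < 0) stop("pasi_zero_threshold must be >= 0")
  structure(list(pasi_error_form = "exponential",
                 pk_error_form = "proportional",
                 lloq_pk = lloq_pk, uloq_pk = uloq_pk,
                 pasi_zero_threshold = pasi_zero_threshold),
            class = "observation_model_spec")
}

#' Population PK/PD model
#'
#' Bundles the typical parameter values, the inter-individual variability
#' (IIV) standard deviations of the log-normal random effects, the residual
#' error magnitudes, the allometric covariate model and the observation
#' model. [default_population()] fills in the published estimates.
#'
#' The PASI residual SD (`sigma_pasi`) is interpreted as the standard
#' deviation on the log (exponential) scale, coherent with the multiplicative
#' baseline model `PASI_i = PASI_i0 * exp(eta_RV)` whose random effect is
#' constrained to the residual variance. The PK residual SD (`sigma_pk`,
#' proportional scale) and the tolerance slope for tolerance-active patients
#' (`slp_tolerance`) are not published; the defaults are package assumptions
#' and can be overridden.
#'
#' @param pk_typical typical [pk_parameters()].
#' @param pd_typical typical [pd_parameters()] (its `pasi_base` is a
#'   placeholder; individual baselines come from the B2 method).
#' @param omega named vector of IIV SDs on the log scale for `kout`,
#'   `kout_tol` and `imax`.
#' @param sigma_pasi residual SD of PASI on the log scale.
#' @param sigma_pk proportional residual SD of PK concentrations
#'   (unpublished; package default 0.2).
#' @param ref_weight,exp_cl,exp_v2 allometric covariate model (see
#'   [scale_pk_allometric()]).
#' @param slp_tolerance tolerance-driving slope assigned to
#'   tolerance-active patients (L/mg/day; unpublished, package default).
#' @param obs an [observation_model_spec()].
#' @return An object of class `population_model`.
#' @export
population_model <- function(pk_typical = pk_parameters(),
                             pd_typical = pd_parameters(),
                             omega = c(kout = 0.913, kout_tol = 0.3715,
                                       imax = 0.0763),
                             sigma_pasi = 0.76,
                             sigma_pk = 0.2,
                             ref_weight = 70, exp_cl = 0.8, exp_v2 = 1,
                             slp_tolerance = 5e-4,
                             obs = observation_model_spec()) {
  stopifnot(inherits(pk_typical, "pk_parameters"),
            inherits(pd_typical, "pd_parameters"),
            inherits(obs, "observation_model_spec"))
  if (any(omega < 0)) stop("IIV standard deviations must be non-negative")
  if (sigma_pasi < 0 || sigma_pk < 0)
    stop("residual SDs must be non-negative")
  if (!all(c("kout", "kout_tol", "imax") %in% names(omega)))
    stop("omega must name kout, kout_tol and imax")
  structure(list(pk_typical = pk_typical, pd_typical = pd_typical,
                 omega = omega, sigma_pasi = sigma_pasi, sigma_pk = sigma_pk,
                 allometry = list(ref_weight = ref_weight, exp_cl = exp_cl,
                                  exp_v2 = exp_v2),
                 slp_tolerance = slp_tolerance, obs = obs),
            class = "population_model")
}

#' Published population PK/PD parameter set
#'
#' Returns the [population_model()] with the published typical values:
#' clearance 0.19 L/day, central volume 3.61 L, peripheral volume 2.87 L
#' (intercompartmental clearance calibrated to a 27-day terminal half-life),
#' allometric exponents 0.8 (CL) and 1 (V2) on body weight; `kout` 0.11/day,
#' `kout_tol` 0.003/day, `Imax` 1.19 and `IC50` fixed at 9.35 mg/L; IIV SDs
#' 0.913 (`kout`), 0.3715 (`kout_tol`) and 0.0763 (`Imax`); PASI residual SD
#' 0.76 on the log scale.
#'
#' @param ... overrides forwarded to [population_model()].
#' @return A `population_model`.
#' @examples
#' pop <- default_population()
#' pop$pd_typical$kout   # 0.11
#' pop$omega[["imax"]]   # 0.0763
#' @export
default_population <- function(...) population_model(...)

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK/PD model (secukinumab, plaque psoriasis)\n")
  cat(sprintf("  PK: CL %.3g L/day, V2 %.3g L, V3 %.3g L, Q %.3g L/day (t1/2 %.1f d)\n",
              x$pk_typical$cl, x$pk_typical$v2, x$pk_typical$v3,
              x$pk_typical$q, terminal_half_life(x$pk_typical)))
  cat(sprintf("  PD: kout %.3g 1/day, Imax %.3g, IC50 %.3g mg/L, kout_tol %.3g 1/day\n",
              x$pd_typical$kout, x$pd_typical$imax, x$pd_typical$ic50,
              x$pd_typical$kout_tol))
  cat(sprintf("  IIV SD (log): kout %.3g, kout_tol %.3g, Imax %.3g; RUV (log PASI) %.3g\n",
              x$omega[["kout"]], x$omega[["kout_tol"]], x$omega[["imax"]],
              x$sigma_pasi))
  cat(sprintf("  allometry: WT^%.2g on CL, WT^%.2g on V2, ref %g kg\n",
              x$allometry$exp_cl, x$allometry$exp_v2, x$allometry$ref_weight))
  invisible(x)
}

#' Serialize a population model to a JSON configuration file
#'
#' Writes every population parameter — typical PK and PD values, IIV SDs,
#' residual SDs, allometry, tolerance slope and observation limits — as a
#' flat, human-editable JSON document. [read_population()] restores the
#' model; round-trips are exact up to double precision. Fields absent from
#' an edited file fall back to the package defaults, so a configuration can
#' override any single published value.
#'
#' @param pop a [population_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "population_model"))
  cfg <- list(
    pk = pop$pk_typical[c("ka", "f", "cl", "v2", "v3", "q")],
    pd = pop$pd_typical[c("kout", "imax", "ic50", "slp", "kout_tol")],
    omega = as.list(pop$omega),
    sigma_pasi = pop$sigma_pasi,
    sigma_pk = pop$sigma_pk,
    allometry = pop$allometry,
    slp_tolerance = pop$slp_tolerance,
    obs = pop$obs[c("lloq_pk", "uloq_pk", "pasi_zero_threshold")])
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a population model from a JSON configuration file
#'
#' @param path file written by [write_population()] (or hand-edited; missing
#'   fields take the package defaults).
#' @return A [population_model()].
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  take <- function(x, defaults) {
    out <- defaults
    out[names(x)] <- x
    out
  }
  pk_args <- take(cfg$pk, list(ka = 0.18, f = 0.73, cl = 0.19, v2 = 3.61,
                               v3 = 2.87, q = NULL))
  pd_args <- take(cfg$pd, list(kout = 0.11, imax = 1.19, ic50 = 9.35,
                               slp = 0, kout_tol = 0.003))
  omega <- unlist(take(as.list(cfg$omega),
                       list(kout = 0.913, kout_tol = 0.3715, imax = 0.0763)))
  allo <- take(cfg$allometry, list(ref_weight = 70, exp_cl = 0.8, exp_v2 = 1))
  obs_args <- take(cfg$obs, list(lloq_pk = 0.2, uloq_pk = 225,
                                 pasi_zero_threshold = 0.05))
  population_model(
    pk_typical = do.call(pk_parameters, pk_args),
    pd_typical = do.call(pd_parameters, pd_args),
    omega = omega,
    sigma_pasi = if (is.null(cfg$sigma_pasi)) 0.76 else cfg$sigma_pasi,
    sigma_pk = if (is.null(cfg$sigma_pk)) 0.2 else cfg$sigma_pk,
    ref_weight = allo$ref_weight, exp_cl = allo$exp_cl,
    exp_v2 = allo$exp_v2,
    slp_tolerance = if (is.null(cfg$slp_tolerance)) 5e-4
                    else cfg$slp_tolerance,
    obs = do.call(observation_model_spec, obs_args))
}

#' Individual baseline PASI by the B2 method
#'
#' The individual model baseline is the observed baseline times a log-normal
#' deviate, `PASI_i = PASI_i0 * exp(eta_RV)`, where `eta_RV` has mean zero
#' and a variance constrained to equal the residual unexplained variability.
#'
#' @param pasi_obs0 observed baseline PASI (>= 0).
#' @param eta_rv realized baseline random effect (log scale).
#' @return Model baseline PASI.
#' @examples
#' b2_baseline(11.6, 0)     # 11.6
#' b2_baseline(11.6, 0.76)  # 11.6 * exp(0.76)
#' @export
b2_baseline <- function(pasi_obs0, eta_rv) {
  if (any(pasi_obs0 < 0)) stop("observed baseline PASI must be non-negative")
  pasi_obs0 * exp(eta_rv)
}

#' Build an individual from realized random effects
#'
#' Deterministic construction of one patient's parameter set from a
#' population model, covariates and named log-scale random effects: PD
#' parameters are `typical * exp(eta)`, the baseline comes from
#' [b2_baseline()] with `etas["rv"]`, and the PK parameters are
#' weight-scaled. Missing etas default to zero.
#'
#' @param pop a [population_model()].
#' @param weight body weight (kg).
#' @param pasi_obs0 observed baseline PASI.
#' @param etas named numeric vector with any of `kout`, `kout_tol`, `imax`,
#'   `rv`.
#' @param tolerance_active whether the tolerance mechanism is on for this
#'   patient (assigns `slp_tolerance` from the population model).
#' @return An [individual_parameters()] object.
#' @export
make_individual <- function(pop, weight, pasi_obs0, etas = numeric(0),
                            tolerance_active = FALSE) {
  stopifnot(inherits(pop, "population_model"))
  get_eta <- function(nm) if (nm %in% names(etas)) etas[[nm]] else 0
  pk <- scale_pk_allometric(pop$pk_typical, weight,
                            ref_weight = pop$allometry$ref_weight,
                            exp_cl = pop$allometry$exp_cl,
                            exp_v2 = pop$allometry$exp_v2)
  typ <- pop$pd_typical
  pd <- pd_parameters(
    kout = typ$kout * exp(get_eta("kout")),
    imax = typ$imax * exp(get_eta("imax")),
    ic50 = typ$ic50,
    slp = if (tolerance_active) pop$slp_tolerance else 0,
    kout_tol = typ$kout_tol * exp(get_eta("kout_tol")),
    pasi_base = b2_baseline(pasi_obs0, get_eta("rv")))
  individual_parameters(pk, pd, weight, etas = etas,
                        tolerance_active = tolerance_active)
}

#' Sample a virtual individual from the population
#'
#' Draws log-normal random effects (`eta ~ N(0, omega^2)`) for `kout`,
#' `kout_tol` and `imax`, a baseline random effect `eta_RV ~ N(0,
#' sigma_pasi^2)` for the B2 baseline, and assembles the individual with
#' weight-scaled PK parameters. Deterministic given `seed`.
#'
#' @param pop a [population_model()].
#' @param weight body weight (kg), physiologic range 20-200.
#' @param pasi_obs0 observed baseline PASI.
#' @param seed optional integer seed.
#' @param tolerance_active whether the tolerance mechanism is active.
#' @return An [individual_parameters()] object.
#' @export
sample_individual <- function(pop, weight, pasi_obs0, seed = NULL,
                              tolerance_active = FALSE) {
  stopifnot(inherits(pop, "population_model"))
  if (!is.numeric(weight) || weight < 20 || weight > 200)
    stop("weight outside the physiologic range 20-200 kg")
  if (pasi_obs0 < 0) stop("observed baseline PASI must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  etas <- c(kout = stats::rnorm(1, 0, pop$omega[["kout"]]),
            kout_tol = stats::rnorm(1, 0, pop$omega[["kout_tol"]]),
            imax = stats::rnorm(1, 0, pop$omega[["imax"]]),
            rv = stats::rnorm(1, 0, pop$sigma_pasi))
  make_individual(pop, weight, pasi_obs0, etas,
                  tolerance_active = tolerance_active)
}

#' Apply residual error and censoring to model predictions
#'
#' PASI: `obs = pred * exp(eps)` with `eps ~ N(0, sigma_pasi^2)`; observed
#' values below the recording threshold are stored as 0 and flagged
#' left-censored (`cens = -1`). PK: `obs = pred * (1 + eps)` with
#' `eps ~ N(0, sigma_pk^2)`, floored at 0; values below the assay LLOQ are
#' flagged `cens = -1`, values above the ULOQ `cens = 1`.
#'
#' @param pred numeric vector of model predictions (>= 0).
#' @param pop a [population_model()] (residual SDs and assay limits).
#' @param kind `"pk"` or `"pasi"`.
#' @param seed optional integer seed.
#' @return Data frame with columns `value` and `cens` (0 observed, -1 below
#'   limit, 1 above limit).
#' @export
apply_residual <- function(pred, pop, kind = c("pasi", "pk"), seed = NULL) {
  stopifnot(inherits(pop, "population_model"))
  kind <- match.arg(kind)
  if (any(pred < 0)) stop("predictions must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- length(pred)
  if (kind == "pasi") {
    obs <- pred * exp(stats::rnorm(n, 0, pop$sigma_pasi))
    cens <- ifelse(obs < pop$obs$pasi_zero_threshold, -1L, 0L)
    obs[cens == -1L] <- 0
  } else {
    obs <- pmax(pred * (1 + stats::rnorm(n, 0, pop$sigma_pk)), 0)
    cens <- ifelse(obs < pop$obs$lloq_pk, -1L,
                   ifelse(obs > pop$obs$uloq_pk, 1L, 0L))
  }
  data.frame(value = obs, cens = cens)
}
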
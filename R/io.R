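#' Write observation sets to an event dataset CSV
#'
#' Serializes a list of [observation_set()] objects to the tabular event
#' dialect (NONMEM-convention columns): `ID, TIME, EVID, AMT, DVID, DV,
#' CENS, WT`. Dose rows have `EVID = 1` and carry `AMT`; observation rows
#' have `EVID = 0` and carry `DVID` (`pk`/`pasi`), `DV` and `CENS` (0
#' observed, -1 below limit, 1 above limit). Fields that do not apply are
#' left empty. Comma-separated, period decimal, UTF-8, header mandatory.
#'
#' @param obs_list list of [observation_set()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(obs_list, path) {
  rows <- lapply(obs_list, function(o) {
    dose <- data.frame(ID = o$id, TIME = o$doses$time, EVID = 1L,
                       AMT = o$doses$amount, DVID = "", DV = NA_real_,
                       CENS = NA_integer_, WT = o$weight)
    obs <- data.frame(ID = o$id, TIME = o$records$time, EVID = 0L,
                      AMT = NA_real_, DVID = o$records$type,
                      DV = o$records$value, CENS = o$records$cens,
                      WT = o$weight)
    d <- rbind(dose, obs)
    d[order(d$TIME, -d$EVID), ]
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an event dataset CSV
#'
#' Parses the event dialect written by [write_dataset()], validates row
#' invariants (dose rows carry `AMT` and no `DV`; observation rows carry a
#' `DVID` and, unless censored, a `DV`; times non-negative) and splits the
#' rows into one [observation_set()] per `ID`. Malformed rows fail fast with
#' their line numbers; nothing is silently dropped. The observed baseline
#' PASI of each patient is the earliest uncensored PASI record.
#'
#' @param path CSV file path.
#' @param tolerance_ids patient IDs with the tolerance mechanism active.
#' @return A list of [observation_set()] objects, one per patient.
#' @export
read_dataset <- function(path, tolerance_ids = integer(0)) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("ID", "TIME", "EVID", "AMT", "DVID", "DV", "CENS", "WT")
  if (!all(required %in% names(d)))
    stop("dataset header must contain: ", paste(required, collapse = ", "))
  line <- seq_len(nrow(d)) + 1L  # header is line 1
  bad <- function(cond, msg) {
    if (any(cond))
      stop(sprintf("dataset %s: %s at line(s) %s", path, msg,
                   paste(utils::head(line[cond], 5), collapse = ", ")))
  }
  bad(!d$EVID %in% c(0L, 1L), "EVID must be 0 or 1")
  bad(is.na(d$TIME) | d$TIME < 0, "TIME must be non-negative")
  is_dose <- d$EVID == 1L
  bad(is_dose & (is.na(d$AMT) | d$AMT <= 0), "dose rows need positive AMT")
  bad(is_dose & !is.na(d$DV), "dose rows must not carry DV")
  bad(!is_dose & is.na(d$AMT) == FALSE, "observation rows must not carry AMT")
  bad(!is_dose & !d$DVID %in% c("pk", "pasi"), "DVID must be pk or pasi")
  bad(!is_dose & is.na(d$CENS), "observation rows need CENS")
  bad(!is_dose & d$CENS == 0L & is.na(d$DV),
      "uncensored observation rows need DV")
  d$DV[!is_dose & d$CENS == -1L & d$DVID == "pasi" & is.na(d$DV)] <- 0
  bad(!is_dose & is.na(d$DV), "censored PK rows still need the recorded DV")

  lapply(split(d, d$ID), function(di) {
    id <- di$ID[1]
    doses <- di[di$EVID == 1L, c("TIME", "AMT")]
    names(doses) <- c("time", "amount")
    oi <- di[di$EVID == 0L, ]
    records <- data.frame(time = oi$TIME, type = oi$DVID, value = oi$DV,
                          cens = as.integer(oi$CENS))
    base <- records[records$type == "pasi" & records$cens == 0L, ]
    pasi_obs0 <- if (nrow(base)) base$value[which.min(base$time)] else NA_real_
    observation_set(id, records, doses, weight = di$WT[1],
                    pasi_obs0 = pasi_obs0,
                    tolerance_active = id %in% tolerance_ids)
  })
}

#' Export a trajectory as a tidy table
#'
#' @param traj a `pkpd_trajectory` from [simulate_pkpd()].
#' @param id patient identifier to attach.
#' @return Data frame with columns `id`, `time`, `conc`, `pasi`, `tol`.
#' @export
trajectory_table <- function(traj, id = 1) {
  data.frame(id = id, time = traj$time, conc = traj$conc, pasi = traj$pasi,
             tol = traj$tol)
}

#' MIPD run configuration
#'
#' Gathers the tunable settings of the decision pipeline: number of clones,
#' PASI target and probability rule, the evaluation cycles, the
#' Metropolis-Hastings schedule and the cost parameters.
#'
#' @param n_clones conditional draws per patient.
#' @param target_pasi response target (PASI <= target).
#' @param prob_rule required probability (percent) at the late cycle.
#' @param burn_in,n_iter Metropolis-Hastings schedule
#'   (see [sample_conditional()]).
#' @param unit_cost_eur,comparator_doses_per_year cost settings
#'   (see [annual_cost()]).
#' @return A list of class `mipd_config`.
#' @export
mipd_config <- function(n_clones = 100, target_pasi = 1.0, prob_rule = 90,
                        burn_in = 300, n_iter = 1200,
                        unit_cost_eur = 1246.98,
                        comparator_doses_per_year = 14) {
  if (n_clones < 1) stop("n_clones must be >= 1")
  if (prob_rule <= 0 || prob_rule > 100) stop("prob_rule must be in (0, 100]")
  structure(list(n_clones = n_clones, target_pasi = target_pasi,
                 prob_rule = prob_rule, burn_in = burn_in, n_iter = n_iter,
                 unit_cost_eur = unit_cost_eur,
                 comparator_doses_per_year = comparator_doses_per_year),
            class = "mipd_config")
}

#' Run the MIPD decision pipeline for one patient
#'
#' Samples the conditional parameter distribution, simulates the clone set
#' under every candidate regimen across cycles 1-10 (current regimen) and
#' 11-20 (candidate), tabulates the probabilities of PASI <= target and
#' selects and classifies the recommended regimen.
#'
#' @param obs an [observation_set()].
#' @param current the patient's current [regimen()].
#' @param pop a [population_model()].
#' @param config an [mipd_config()].
#' @param seed integer seed for the conditional sampler.
#' @return List with `clones` ([sample_conditional()] result), `table`
#'   ([probability_table()]) and `recommendation` ([select_regimen()]).
#' @export
run_mipd_patient <- function(obs, current, pop = default_population(),
                             config = mipd_config(), seed) {
  clones <- sample_conditional(obs, pop, n_clones = config$n_clones,
                               seed = seed, burn_in = config$burn_in,
                               n_iter = config$n_iter)
  table <- probability_table(clones, current, target = config$target_pasi)
  rec <- select_regimen(table, current, prob_rule = config$prob_rule)
  list(clones = clones, table = table, recommendation = rec)
}

#' Run the MIPD decision pipeline on a cohort
#'
#' Applies [run_mipd_patient()] to every patient (per-patient seeds are
#' derived deterministically from `seed`) and assembles the cohort summary:
#' one row per patient with the current regimen, the selected regimen, its
#' classification and cycle-20 probability, plus a regimen-transition edge
#' list and a run manifest.
#'
#' @param obs_list list of [observation_set()] objects.
#' @param regimens list of current [regimen()]s, one per patient.
#' @param pop a [population_model()].
#' @param config an [mipd_config()].
#' @param seed integer master seed.
#' @return An object of class `mipd_run`: list with `patients` (per-patient
#'   pipeline results), `summary` (data frame), `transitions` (edge-list
#'   data frame `from`, `to`, `n`), `pairs` (pooled cycle-20 clone
#'   trough/PASI pairs) and `manifest`.
#' @export
run_mipd_cohort <- function(obs_list, regimens, pop = default_population(),
                            config = mipd_config(), seed) {
  stopifnot(length(obs_list) == length(regimens))
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  n <- length(obs_list)
  seeds <- seed + 1000L * seq_len(n)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    patients[[i]] <- run_mipd_patient(obs_list[[i]], regimens[[i]], pop,
                                      config, seed = seeds[i])
  }
  assemble_cohort_run(obs_list, patients, seed, config)
}

#' @export
print.mipd_run <- function(x, ...) {
  cat(sprintf("MIPD cohort run: %d patients (seed %s)\n",
              nrow(x$summary), format(x$manifest$seed)))
  print(table(x$summary$classification))
  invisible(x)
}

#' Write MIPD cohort outputs
#'
#' Writes the cohort summary and the per-regimen probability tables as CSV,
#' the transition edge list as CSV, the clone draws as CSV and the run
#' manifest as JSON into a directory.
#'
#' @param run an `mipd_run` from [run_mipd_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mipd_run <- function(run, dir) {
  stopifnot(inherits(run, "mipd_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$summary, file.path(dir, "recommendations.csv"),
                   row.names = FALSE)
  utils::write.csv(run$transitions, file.path(dir, "transitions.csv"),
                   row.names = FALSE)
  tabs <- do.call(rbind, lapply(run$patients, function(p) {
    tb <- as.data.frame(p$table)
    tb$id <- attr(p$table, "patient")
    tb
  }))
  utils::write.csv(tabs, file.path(dir, "probability_tables.csv"),
                   row.names = FALSE)
  # tolerance-active patients carry an extra kout_tol effect; pad the
  # others with NA so the per-clone draws stack into one table
  all_eta <- unique(unlist(lapply(run$patients,
                                  function(p) colnames(p$clones$etas))))
  draws <- do.call(rbind, lapply(run$patients, function(p) {
    e <- as.data.frame(p$clones$etas)
    for (nm in setdiff(all_eta, names(e))) e[[nm]] <- NA_real_
    e <- e[all_eta]
    e$id <- p$clones$patient
    e$clone <- seq_len(nrow(e))
    e
  }))
  utils::write.csv(draws, file.path(dir, "clone_draws.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
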
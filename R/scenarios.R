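#' Run the full MIPD pipeline on a synthetic scenario cohort
#'
#' Convenience wrapper chaining the whole method end to end on simulated
#' data: apply a [scenario_preset()] to the population, draw a virtual
#' cohort ([generate_cohort()]), simulate its therapeutic drug monitoring
#' data ([simulate_trial()]), and run the decision pipeline
#' ([run_mipd_cohort()]) against every patient's current regimen. All
#' randomness derives from `seed`.
#'
#' @param scenario scenario name passed to [scenario_preset()].
#' @param seed integer master seed.
#' @param pop a [population_model()].
#' @param spec a [cohort_spec()].
#' @param config an [mipd_config()].
#' @param duration_years follow-up duration of the simulated trial.
#' @return The [run_mipd_cohort()] result, with the cohort and observation
#'   sets attached as attributes `"cohort"` and `"obs"`.
#' @export
run_scenario_cohort <- function(scenario = "typical", seed,
                                pop = default_population(),
                                spec = cohort_spec(),
                                config = mipd_config(),
                                duration_years = 1.5) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  preset <- scenario_preset(scenario)
  cohort <- generate_cohort(spec, pop, seed = seed, scenario = preset)
  # per-patient populations may carry scenario overrides (e.g. fixed Imax)
  obs <- simulate_trial(cohort, pop, seed = seed + 1,
                        duration_years = duration_years)
  regimens <- lapply(cohort, `[[`, "regimen")
  run <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    run[[i]] <- run_mipd_patient(obs[[i]], regimens[[i]],
                                 cohort[[i]]$population, config,
                                 seed = seed + 1000L * i)
  }
  out <- assemble_cohort_run(obs, run, seed, config)
  attr(out, "cohort") <- cohort
  attr(out, "obs") <- obs
  out
}

# Shared assembly of an mipd_run object from per-patient pipeline results.
assemble_cohort_run <- function(obs_list, patients, seed, config) {
  n <- length(obs_list)
  summary <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- patients[[i]]$recommendation
    data.frame(id = obs_list[[i]]$id,
               current = r$current$label,
               selected = if (is.null(r$selected)) NA_character_
                          else r$selected$label,
               classification = r$classification,
               prob20 = r$prob20,
               acceptance = patients[[i]]$clones$acceptance_rate)
  }))
  trans <- summary
  trans$to <- ifelse(is.na(trans$selected), "no_target", trans$selected)
  edges <- as.data.frame(table(from = trans$current, to = trans$to),
                         stringsAsFactors = FALSE)
  edges <- edges[edges$Freq > 0, ]
  names(edges)[3] <- "n"
  rownames(edges) <- NULL
  pairs <- do.call(rbind, lapply(patients, function(p)
    attr(p$table, "clone_pairs")))
  structure(list(patients = patients, summary = summary,
                 transitions = edges, pairs = pairs,
                 manifest = list(seed = seed, n_patients = n,
                                 config = unclass(config),
                                 package_version =
                                   as.character(utils::packageVersion("secumipd")))),
            class = "mipd_run")
}
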
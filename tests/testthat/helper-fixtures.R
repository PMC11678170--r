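# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

test_pop <- function(...) default_population(...)

# A typical 70-kg individual on the published parameter set.
typical_individual <- function(pasi_base = 11.6, pop = test_pop(), ...) {
  individual_parameters(pop$pk_typical,
                        pd_parameters(pasi_base = pasi_base, ...),
                        weight = 70)
}

# Dense synthetic observation set simulated from a known truth: PASI every
# `every` days over `days`, with multiplicative residual noise. Returns the
# observation set together with the true individual. With `etas = NULL` the
# truth is drawn from the population; a named vector fixes it.
dense_patient <- function(id, pop, seed, days = 300, every = 1,
                          regimen_label = "300 q4w", etas = NULL) {
  set.seed(seed)
  weight <- stats::runif(1, 50, 95)
  pasi_obs0 <- stats::runif(1, 8, 20)
  truth <- if (is.null(etas)) sample_individual(pop, weight, pasi_obs0)
           else make_individual(pop, weight, pasi_obs0, etas)
  reg <- parse_regimen(regimen_label)
  doses <- regimen_doses(reg, ceiling(days / reg$interval_days))
  tt <- seq(every, days, by = every)
  traj <- simulate_pasi(truth, doses, tt)
  obs_val <- apply_residual(traj$pasi, pop, "pasi")
  records <- rbind(
    data.frame(time = 0, type = "pasi", value = pasi_obs0, cens = 0L),
    data.frame(time = tt, type = "pasi", value = obs_val$value,
               cens = obs_val$cens))
  list(obs = observation_set(id, records, doses, weight, pasi_obs0),
       truth = truth)
}

# Observation set with a single baseline PASI record: the posterior of the
# baseline random effect has a normal-normal closed form.
baseline_only_patient <- function(value, pasi_obs0, weight = 70) {
  records <- data.frame(time = 0, type = "pasi", value = value, cens = 0L)
  observation_set("toy", records,
                  doses = data.frame(time = numeric(0), amount = numeric(0)),
                  weight = weight, pasi_obs0 = pasi_obs0)
}

# Hand-built probability table over the full candidate grid, for exercising
# the selection rule against prescribed probabilities.
fake_table <- function(probs, patient = "p") {
  cand <- candidate_regimens()
  tab <- do.call(rbind, lapply(cand, function(r) data.frame(
    regimen = r$label, dose = r$dose, interval = r$interval,
    prob10 = 50, prob20 = probs[[r$label]],
    median_pasi20 = 1, trough20 = 40, n_failed = 0L)))
  structure(tab, patient = patient,
            clone_pairs = data.frame(regimen = "x", trough = 1, pasi = 1),
            class = c("probability_table", "data.frame"))
}

empty_patient <- function(weight = 70, pasi_obs0 = 11.6) {
  observation_set("prior-only",
                  data.frame(time = numeric(0), type = character(0),
                             value = numeric(0), cens = integer(0)),
                  doses = data.frame(time = numeric(0), amount = numeric(0)),
                  weight = weight, pasi_obs0 = pasi_obs0)
}
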
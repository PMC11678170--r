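#' Candidate maintenance regimens for MIPD
#'
#' The seven-member candidate grid evaluated at the 20th cycle: 150 mg at
#' q4w/q5w/q6w and 300 mg at q2w/q4w/q5w/q6w (150 mg q2w is not a
#' candidate). Ordered by descending annualized dose, so intensified options
#' come first and the most optimized last.
#'
#' @return A list of [regimen()] objects of length 7.
#' @export
candidate_regimens <- function() {
  grid <- list(regimen(300, 2), regimen(300, 4), regimen(300, 5),
               regimen(300, 6), regimen(150, 4), regimen(150, 5),
               regimen(150, 6))
  grid[order(-vapply(grid, optimization_rank, numeric(1)))]
}

#' Optimization ranking of a regimen
#'
#' Total order used to choose "the most optimized" among qualifying
#' regimens: lower annualized dose (`dose * 365 / (7 * interval)`) is more
#' optimized; at an exactly equal annualized dose the longer interval (fewer
#' injections) wins. Returned as a single sortable key where smaller means
#' more optimized.
#'
#' @param reg a [regimen()] object.
#' @return Numeric sort key (mg/year minus an interval tie-break epsilon).
#' @examples
#' optimization_rank(regimen(150, 6)) < optimization_rank(regimen(150, 4))
#' @export
optimization_rank <- function(reg) {
  stopifnot(inherits(reg, "regimen"))
  annualized <- reg$dose * 365 / reg$interval_days
  annualized - 1e-6 * reg$interval
}

#' Probability of attaining the PASI target
#'
#' The fraction, in percent, of simulated clones whose PASI is at or below
#' the threshold: `100 * n_PASI / T_PASI`, where ties at exactly the
#' threshold count as successes (the target is "PASI <= 1").
#'
#' @param pasi_values numeric vector of clone PASI values.
#' @param threshold response target (default 1.0).
#' @return Probability in percent, in `[0, 100]`.
#' @examples
#' probability_target(c(0.5, 1.5))  # 50
#' @export
probability_target <- function(pasi_values, threshold = 1.0) {
  if (length(pasi_values) == 0)
    stop("probability undefined for an empty set of clone PASI values")
  100 * sum(pasi_values <= threshold) / length(pasi_values)
}

#' Simulate clones across treatment cycles
#'
#' Simulates every clone of a patient's conditional sample under the current
#' regimen for cycles 1-10 and a candidate regimen for cycles 11-20
#' (a "cycle" is one interdose interval of the regimen in force; boundaries
#' are re-derived at the switch). Returns the PASI at the end-of-cycle
#' trough instants of cycles 10 and 20 and the trough concentration at cycle
#' 20. The trough concentration is identical across clones because the PK
#' parameters carry no sampled random effects. Clones whose simulation fails
#' are flagged and excluded.
#'
#' @param clones a [sample_conditional()] result (or a plain list of
#'   [individual_parameters()]).
#' @param current the patient's current [regimen()].
#' @param candidate the candidate [regimen()] for cycles 11-20.
#' @return A list with `pasi10`, `pasi20` (numeric vectors over surviving
#'   clones), `trough20` (scalar, mg/L), `n_failed`.
#' @export
simulate_clones <- function(clones, current, candidate) {
  draws <- if (inherits(clones, "conditional_sample")) clones$draws else clones
  stopifnot(length(draws) >= 1, inherits(current, "regimen"),
            inherits(candidate, "regimen"))
  t10 <- 10 * current$interval_days
  t20 <- t10 + 10 * candidate$interval_days
  doses <- rbind(regimen_doses(current, 10),
                 regimen_doses(candidate, 10, start = t10))

  pk <- draws[[1]]$pk
  fgrid <- sort(unique(c(seq(0, t20, by = 1), doses$time, t10, t20)))
  cf <- pk_profile(pk, doses, fgrid)
  forcing <- cbind(cf$time, cf$conc)
  trough20 <- cf$conc[match(t20, cf$time)]

  pasi10 <- pasi20 <- numeric(0)
  n_failed <- 0L
  for (d in draws) {
    sim <- tryCatch(pd_solve(d, forcing, c(t10, t20)),
                    error = function(e) NULL)
    if (is.null(sim)) {
      n_failed <- n_failed + 1L
    } else {
      pasi10 <- c(pasi10, sim$pasi[1])
      pasi20 <- c(pasi20, sim$pasi[2])
    }
  }
  list(pasi10 = pasi10, pasi20 = pasi20, trough20 = trough20,
       n_failed = n_failed)
}

#' Per-regimen probability table for one patient
#'
#' Runs [simulate_clones()] for every candidate regimen and tabulates the
#' probability of PASI <= `target` at cycles 10 and 20, the median cycle-20
#' PASI and the cycle-20 trough concentration. Patients whose clone failure
#' fraction exceeds 5% for any regimen are rejected.
#'
#' @param clones a [sample_conditional()] result.
#' @param current the current [regimen()].
#' @param candidates list of candidate regimens (default the 7-member grid).
#' @param target PASI response target.
#' @return An object of class `probability_table`: data frame with columns
#'   `regimen`, `dose`, `interval`, `prob10`, `prob20`, `median_pasi20`,
#'   `trough20`, `n_failed`, plus attributes `patient` and `clone_pairs`
#'   (per-clone cycle-20 `(trough, pasi)` pairs pooled over regimens, used
#'   for exposure-response summaries).
#' @export
probability_table <- function(clones, current,
                              candidates = candidate_regimens(),
                              target = 1.0) {
  stopifnot(inherits(current, "regimen"))
  n <- if (inherits(clones, "conditional_sample")) nrow(clones$etas)
       else length(clones)
  rows <- list()
  pairs <- list()
  for (cand in candidates) {
    sim <- simulate_clones(clones, current, cand)
    if (sim$n_failed > 0.05 * n)
      stop(sprintf("clone failure fraction %.0f%% under %s invalidates the table",
                   100 * sim$n_failed / n, cand$label))
    rows[[cand$label]] <- data.frame(
      regimen = cand$label, dose = cand$dose, interval = cand$interval,
      prob10 = probability_target(sim$pasi10, target),
      prob20 = probability_target(sim$pasi20, target),
      median_pasi20 = stats::median(sim$pasi20),
      trough20 = sim$trough20,
      n_failed = sim$n_failed)
    pairs[[cand$label]] <- data.frame(regimen = cand$label,
                                      trough = sim$trough20,
                                      pasi = sim$pasi20)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  patient <- if (inherits(clones, "conditional_sample")) clones$patient else NA
  structure(tab, patient = patient,
            clone_pairs = do.call(rbind, c(pairs, list(make.row.names = FALSE))),
            class = c("probability_table", "data.frame"))
}

#' Select the recommended regimen from a probability table
#'
#' Among candidate regimens whose cycle-20 probability of PASI <= 1 is at
#' least `prob_rule` percent, picks the most optimized one (lowest
#' [optimization_rank()]); when none qualifies the patient is classified
#' `no_target`. The result is classified against the current regimen by
#' [classify_regimen()].
#'
#' @param table a [probability_table()] covering all candidates.
#' @param current the current [regimen()].
#' @param prob_rule required probability (percent), default 90.
#' @return An object of class `recommendation`: list with `current`,
#'   `selected` (a [regimen()] or `NULL`), `classification`, `prob20`
#'   (probability of the selected regimen, `NA` if none).
#' @export
select_regimen <- function(table, current, prob_rule = 90) {
  stopifnot(inherits(table, "probability_table"), inherits(current, "regimen"))
  grid <- vapply(candidate_regimens(), function(r) r$label, character(1))
  if (!all(grid %in% table$regimen))
    stop("probability table must cover all 7 candidate regimens")
  ok <- table[table$prob20 >= prob_rule, , drop = FALSE]
  if (nrow(ok) == 0) {
    sel <- NULL
    prob <- NA_real_
  } else {
    regs <- lapply(seq_len(nrow(ok)), function(i)
      regimen(ok$dose[i], ok$interval[i]))
    ranks <- vapply(regs, optimization_rank, numeric(1))
    sel <- regs[[which.min(ranks)]]
    prob <- ok$prob20[which.min(ranks)]
  }
  structure(list(patient = attr(table, "patient"), current = current,
                 selected = sel,
                 classification = classify_regimen(current, sel),
                 prob20 = prob),
            class = "recommendation")
}

#' Classify a regimen change
#'
#' Truth table of the decision layer: no selected regimen is `no_target`;
#' the same regimen is `maintained`; a selected regimen more optimized than
#' the current one (see [optimization_rank()]) is `optimized`; anything else
#' is `intensified`.
#'
#' @param current current [regimen()].
#' @param selected selected [regimen()] or `NULL`.
#' @return One of `"no_target"`, `"maintained"`, `"optimized"`,
#'   `"intensified"`.
#' @export
classify_regimen <- function(current, selected) {
  stopifnot(inherits(current, "regimen"))
  if (is.null(selected)) return("no_target")
  stopifnot(inherits(selected, "regimen"))
  if (selected$label == current$label) return("maintained")
  if (optimization_rank(selected) < optimization_rank(current))
    return("optimized")
  "intensified"
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("MIPD recommendation (patient %s)\n", format(x$patient)))
  cat(sprintf("  current %s -> %s [%s]%s\n", x$current$label,
              if (is.null(x$selected)) "none" else x$selected$label,
              x$classification,
              if (is.na(x$prob20)) "" else
                sprintf(", P(PASI<=1 at cycle 20) = %.0f%%", x$prob20)))
  invisible(x)
}

#' Annual dose count, cost and savings of a regimen
#'
#' Cost arithmetic anchored at the labeled comparator of 14 annual doses on
#' the q4w maintenance schedule: the yearly number of administrations of a
#' qNw regimen is the comparator count scaled by the interval ratio
#' (`14 * 4 / N`, rounded to the nearest integer; this reproduces the
#' published 11 doses for q5w, whereas a bare 365/interval calculation would
#' give 10.4), the annual cost is doses times the unit price rounded to the
#' nearest euro, and the savings are relative to the comparator count in
#' percent (rounded; negative for intensified regimens).
#'
#' @param reg a [regimen()] object.
#' @param unit_cost_eur price per injection (EUR).
#' @param comparator_doses_per_year annual dose count of the q4w comparator.
#' @return List with `doses_per_year`, `cost_eur`, `savings_percent`.
#' @examples
#' annual_cost(regimen(300, 5))  # 11 doses, EUR 13717, 21% savings
#' @export
annual_cost <- function(reg, unit_cost_eur = 1246.98,
                        comparator_doses_per_year = 14) {
  stopifnot(inherits(reg, "regimen"))
  if (unit_cost_eur <= 0) stop("unit cost must be positive")
  doses <- round(comparator_doses_per_year * 4 / reg$interval)
  cost <- round(doses * unit_cost_eur)
  savings <- round((1 - doses / comparator_doses_per_year) * 100)
  list(doses_per_year = doses, cost_eur = cost, savings_percent = savings)
}

#' Exposure-response trough window
#'
#' Estimates the steady-state trough concentration range that secures the
#' PASI target in at least `target_prob` percent of clones. From pooled
#' cycle-20 `(trough concentration, PASI)` clone pairs, the local response
#' probability is computed on a trough grid (resolution 0.1 mg/L) as the
#' response fraction among pairs within `bandwidth` mg/L of each grid point;
#' the window is the first through last qualifying grid point (local
#' fraction >= `target_prob` with at least `min_n` supporting pairs).
#' Returns `NULL` when no grid point attains the target. When every clone
#' responds the window is the full observed trough range.
#'
#' @param pairs data frame with columns `trough` and `pasi` (pooled over
#'   patients and regimens, e.g. the `clone_pairs` attributes of
#'   [probability_table()] results).
#' @param target_prob required response probability (percent).
#' @param pasi_threshold PASI response target.
#' @param resolution trough grid resolution (mg/L).
#' @param bandwidth half-width of the local estimation window (mg/L).
#' @param min_n minimum pairs supporting a local estimate.
#' @return List with `lo` and `hi` (mg/L), or `NULL` if unattainable.
#' @export
exposure_response_window <- function(pairs, target_prob = 90,
                                     pasi_threshold = 1.0,
                                     resolution = 0.1, bandwidth = 2.5,
                                     min_n = 10) {
  stopifnot(all(c("trough", "pasi") %in% names(pairs)))
  if (nrow(pairs) < 100)
    stop("insufficient data: need at least 100 pooled (trough, PASI) pairs")
  grid <- seq(floor(min(pairs$trough) / resolution) * resolution,
              ceiling(max(pairs$trough) / resolution) * resolution,
              by = resolution)
  resp <- pairs$pasi <= pasi_threshold
  ok <- vapply(grid, function(g) {
    inside <- abs(pairs$trough - g) <= bandwidth
    n <- sum(inside)
    n >= min_n && 100 * sum(resp[inside]) / n >= target_prob
  }, logical(1))
  if (!any(ok)) return(NULL)
  list(lo = grid[which(ok)[1]], hi = grid[rev(which(ok))[1]])
}
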
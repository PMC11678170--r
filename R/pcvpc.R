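#' Prediction-corrected visual predictive check
#'
#' Simulation-based model diagnostic. Observations are prediction-corrected
#' by the Bergstrand convention, `pcY = Y * median(PRED in bin) / PRED_ind`,
#' where `PRED_ind` is the population prediction for the patient (typical
#' parameters, the patient's weight, dosing history and observed baseline;
#' all random effects zero). `n_sim` replicate datasets are then simulated
#' from the population model (new random effects and residual errors at the
#' original design times), corrected the same way, and the spread of their
#' binned percentiles forms the predictive bands. Bins are quantile-based on
#' time after the most recent dose; bins with fewer than 3 observations are
#' merged with their left neighbour (with a warning).
#'
#' @param obs_list list of [observation_set()] objects.
#' @param pop a [population_model()].
#' @param dvid which observation stream to check, `"pasi"` or `"pk"`.
#' @param n_sim number of simulation replicates.
#' @param bins number of time bins.
#' @param seed integer seed (required).
#' @param probs percentiles summarized per bin.
#' @param band coverage of the simulated percentile intervals.
#' @return Data frame with one row per bin x percentile: `bin`, `t_mid`
#'   (median binned time), `n`, `prob`, `observed` (prediction-corrected
#'   observed percentile), `sim_lo`, `sim_med`, `sim_hi`.
#' @export
pcvpc <- function(obs_list, pop = default_population(),
                  dvid = c("pasi", "pk"), n_sim = 500, bins = 6, seed,
                  probs = c(0.05, 0.5, 0.95), band = 0.9) {
  dvid <- match.arg(dvid)
  if (length(obs_list) == 0) stop("obs_list must be non-empty")
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  set.seed(seed)

  # Assemble per-observation design: time, value, censoring, patient index,
  # time after most recent dose, and the population prediction PRED.
  rows <- list()
  preds <- list()
  for (i in seq_along(obs_list)) {
    o <- obs_list[[i]]
    rec <- o$records[o$records$type == dvid & o$records$cens == 0L, ]
    if (nrow(rec) == 0) next
    typical <- make_individual(pop, o$weight, o$pasi_obs0,
                               tolerance_active = FALSE)
    tpos <- rec$time[rec$time > 0]
    pred <- rep(NA_real_, nrow(rec))
    if (dvid == "pasi") {
      if (length(tpos)) {
        sim <- simulate_pasi(typical, o$doses, sort(unique(tpos)))
        pred[rec$time > 0] <- sim$pasi[match(tpos, sim$time)]
      }
      pred[rec$time == 0] <- typical$pd$pasi_base
    } else {
      prof <- pk_profile(typical$pk, o$doses, sort(unique(rec$time)))
      pred <- prof$conc[match(rec$time, prof$time)]
    }
    tad <- vapply(rec$time, function(tt) {
      prior <- o$doses$time[o$doses$time <= tt]
      if (length(prior)) tt - max(prior) else tt
    }, numeric(1))
    rows[[i]] <- data.frame(patient = i, time = rec$time, tad = tad,
                            value = rec$value, pred = pmax(pred, 1e-10))
  }
  dat <- do.call(rbind, rows)
  if (is.null(dat) || nrow(dat) == 0)
    stop("no uncensored observations of type ", dvid)

  # quantile bins on time after dose, small bins merged leftwards
  edges <- unique(stats::quantile(dat$tad, probs = seq(0, 1, length.out = bins + 1)))
  dat$bin <- cut(dat$tad, breaks = edges, include.lowest = TRUE,
                 labels = FALSE)
  counts <- table(dat$bin)
  for (b in sort(unique(dat$bin), decreasing = TRUE)) {
    if (sum(dat$bin == b) < 3 && b > 1) {
      warning(sprintf("bin %d has fewer than 3 observations; merged left", b))
      dat$bin[dat$bin == b] <- b - 1
    }
  }
  dat$bin <- match(dat$bin, sort(unique(dat$bin)))

  med_pred <- tapply(dat$pred, dat$bin, stats::median)
  dat$pc <- dat$value * med_pred[dat$bin] / dat$pred

  obs_pct <- do.call(rbind, lapply(sort(unique(dat$bin)), function(b) {
    v <- dat$pc[dat$bin == b]
    data.frame(bin = b, t_mid = stats::median(dat$tad[dat$bin == b]),
               n = length(v), prob = probs,
               observed = as.numeric(stats::quantile(v, probs)))
  }))

  # simulation replicates: new individuals at the same design points
  sim_pct <- array(NA_real_, c(n_sim, length(unique(dat$bin)), length(probs)))
  for (s in seq_len(n_sim)) {
    vals <- numeric(nrow(dat))
    for (i in unique(dat$patient)) {
      o <- obs_list[[i]]
      sel <- dat$patient == i
      ind <- sample_individual(pop, o$weight, o$pasi_obs0,
                               tolerance_active = FALSE)
      tt <- dat$time[sel]
      ut <- sort(unique(pmax(tt, 1e-6)))
      if (dvid == "pasi") {
        sim <- simulate_pasi(ind, o$doses, ut)
        pred_s <- sim$pasi[match(pmax(tt, 1e-6), sim$time)]
        vals[sel] <- pred_s * exp(stats::rnorm(sum(sel), 0, pop$sigma_pasi))
      } else {
        prof <- pk_profile(ind$pk, o$doses, ut)
        pred_s <- prof$conc[match(pmax(tt, 1e-6), prof$time)]
        vals[sel] <- pmax(pred_s * (1 + stats::rnorm(sum(sel), 0, pop$sigma_pk)), 0)
      }
    }
    pc_s <- vals * med_pred[dat$bin] / dat$pred
    for (b in sort(unique(dat$bin)))
      sim_pct[s, b, ] <- stats::quantile(pc_s[dat$bin == b], probs)
  }
  a <- (1 - band) / 2
  out <- obs_pct
  out$sim_lo <- out$sim_med <- out$sim_hi <- NA_real_
  for (b in sort(unique(dat$bin))) {
    for (k in seq_along(probs)) {
      r <- out$bin == b & out$prob == probs[k]
      out$sim_lo[r] <- stats::quantile(sim_pct[, b, k], a)
      out$sim_med[r] <- stats::median(sim_pct[, b, k])
      out$sim_hi[r] <- stats::quantile(sim_pct[, b, k], 1 - a)
    }
  }
  rownames(out) <- NULL
  out
}
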
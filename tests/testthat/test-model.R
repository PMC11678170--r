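test_that("inhibition multiplier follows the Imax model with a floor", {
  expect_equal(inhibition_multiplier(0), 1.0)
  # half-maximal occupancy at C = IC50
  expect_equal(inhibition_multiplier(9.35, imax = 1.19, ic50 = 9.35),
               1 - 1.19 / 2, tolerance = 1e-12)
  # analytic zero crossing at C = IC50/(Imax - 1) = 49.21 mg/L
  c_star <- 9.35 / 0.19
  expect_gt(inhibition_multiplier(c_star * 0.999, 1.19, 9.35), 0)
  expect_equal(inhibition_multiplier(c_star * 1.001, 1.19, 9.35), 0)
  expect_equal(inhibition_multiplier(200, 1.19, 9.35), 0)
  # tolerance attenuation: higher M3, weaker inhibition
  expect_gt(inhibition_multiplier(50, 1.19, 9.35, m3 = 2),
            inhibition_multiplier(50, 1.19, 9.35, m3 = 0))
  expect_error(inhibition_multiplier(-1), "non-negative")
})

test_that("inhibition multiplier is non-increasing in concentration", {
  conc <- seq(0, 120, by = 0.5)
  for (m3 in c(0, 0.5, 3)) {
    m <- inhibition_multiplier(conc, imax = 1.19, ic50 = 9.35, m3 = m3)
    expect_true(all(diff(m) <= 1e-12))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("baseline initialisation is exactly stationary", {
  expect_equal(pd_parameters(kout = 0.11, pasi_base = 11.6)$kin, 1.276,
               tolerance = 1e-12)
  s0 <- initial_state(11.6)
  expect_equal(unname(s0[c("P1", "P4", "PASI")]), rep(11.6, 3))
  expect_equal(unname(s0[c("depot", "central", "M3")]), rep(0, 3))
  expect_error(initial_state(-1), "non-negative")
  # zero baseline: all PD states zero, no production
  expect_equal(pd_parameters(pasi_base = 0)$kin, 0)

  # zero-dose simulation holds every PD state at baseline for two years
  ind <- typical_individual(pasi_base = 5)
  tr <- simulate_pkpd(ind, NULL, times = seq(0, 730, by = 5),
                      rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(tr$pasi - 5)), 1e-6 * 5)
  states <- attr(tr, "states")
  expect_lt(max(abs(states[, c("P1", "P2", "P3", "P4")] - 5)), 1e-6 * 5)
  expect_equal(max(tr$conc), 0)
})

test_that("drug mass is conserved when clearance is zero", {
  pk <- pk_parameters(cl = 0, f = 1, q = 0.3033)
  ind <- individual_parameters(pk, pd_parameters(pasi_base = 5), 70)
  doses <- data.frame(time = c(0, 14, 42), amount = c(300, 150, 300))
  tr <- simulate_pkpd(ind, doses, times = seq(0, 100, by = 1),
                      rtol = 1e-10, atol = 1e-12)
  states <- attr(tr, "states")
  total <- rowSums(states[, c("depot", "central", "periph")])
  # left-limit convention: the bolus at time t is not yet in the state at t
  dosed <- vapply(tr$time, function(tt) sum(doses$amount[doses$time < tt]),
                  numeric(1))
  ok <- dosed > 0
  expect_lt(max(abs(total[ok] - dosed[ok]) / dosed[ok]), 1e-8)
})

test_that("the PK subsystem is linear: superposition and homogeneity", {
  ind <- typical_individual()
  times <- seq(0, 120, by = 1)
  one0 <- simulate_pkpd(ind, data.frame(time = 0, amount = 300), times,
                        rtol = 1e-10, atol = 1e-12)
  one28 <- simulate_pkpd(ind, data.frame(time = 28, amount = 300), times,
                         rtol = 1e-10, atol = 1e-12)
  both <- simulate_pkpd(ind, data.frame(time = c(0, 28), amount = 300), times,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(both$conc - (one0$conc + one28$conc))) / max(both$conc),
            1e-6)
  # homogeneity of degree 1 in dose
  half <- simulate_pkpd(ind, data.frame(time = 0, amount = 150), times,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(one0$conc - 2 * half$conc)) / max(one0$conc), 1e-6)
})

test_that("late-time concentration declines at the terminal rate", {
  ind <- typical_individual()
  times <- seq(0, 400, by = 1)
  tr <- simulate_pkpd(ind, data.frame(time = 0, amount = 300), times,
                      rtol = 1e-10, atol = 1e-12)
  late <- tr$time >= 200
  slope <- stats::coef(stats::lm(log(tr$conc[late]) ~ tr$time[late]))[2]
  expect_equal(unname(-log(2) / slope), 27, tolerance = 0.02)
})

test_that("without drug effect the PASI never moves; with it, never negative", {
  # Imax = 0: dosing has no PD consequence
  ind0 <- typical_individual(pasi_base = 9, imax = 0)
  tr0 <- simulate_pkpd(ind0, regimen_doses(regimen(300, 2), 20),
                       times = seq(0, 280, by = 2), rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(tr0$pasi - 9)), 1e-6 * 9)
  # intense dosing at Imax = 1.19: production floor keeps PASI >= 0
  ind <- typical_individual(pasi_base = 9)
  tr <- simulate_pkpd(ind, regimen_doses(regimen(300, 1), 60),
                      times = seq(0, 420, by = 2))
  expect_true(all(tr$pasi >= 0))
  expect_true(all(tr$conc >= 0))
})

test_that("fast PD path agrees with the full ODE system", {
  pop <- test_pop()
  doses <- regimen_doses(regimen(300, 4), 15)
  times <- seq(1, 420, by = 1)
  for (tol_active in c(FALSE, TRUE)) {
    ind <- make_individual(pop, weight = 83, pasi_obs0 = 14,
                           etas = c(kout = 0.4, imax = 0.05, rv = -0.2,
                                    kout_tol = 0.1),
                           tolerance_active = tol_active)
    full <- simulate_pkpd(ind, doses, times, rtol = 1e-10, atol = 1e-12)
    fast <- simulate_pasi(ind, doses, times)
    expect_lt(max(abs(full$pasi - fast$pasi)), 0.02)
    expect_lt(max(abs(full$tol - fast$tol)), 0.02)
  }
})

test_that("trough concentration accumulates and reaches steady state", {
  ind <- typical_individual()
  q4 <- regimen(300, 4)
  q2 <- regimen(300, 2)
  doses4 <- regimen_doses(q4, 13)
  doses2 <- regimen_doses(q2, 25)
  times <- seq(0, 350, by = 0.5)
  tr4 <- simulate_pkpd(ind, doses4, times)
  tr2 <- simulate_pkpd(ind, doses2, times)
  # no doses: trough is zero
  tr0 <- simulate_pkpd(ind, NULL, times)
  expect_equal(trough_concentration(tr0, q4, 3), 0)
  # more frequent dosing accumulates to a higher trough
  expect_gt(trough_concentration(tr2, q2, 10),
            trough_concentration(tr4, q4, 10))
  # steady state by cycle 10 on q4w (>= 10 half-lives)
  c10 <- trough_concentration(tr4, q4, 10)
  c11 <- trough_concentration(tr4, q4, 11)
  expect_lt(abs(c11 - c10) / c10, 0.01)
  expect_error(trough_concentration(tr4, q4, 14), "horizon")
})
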
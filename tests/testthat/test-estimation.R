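test_that("PASI log-likelihood matches the closed-form log-normal density", {
  pop <- test_pop()
  # single record equal to the prediction (baseline record at t = 0):
  # log-density of a log-normal at its median is -log(y * sigma * sqrt(2*pi))
  y <- 11.6
  obs <- baseline_only_patient(value = y, pasi_obs0 = y)
  ind <- make_individual(pop, 70, y)  # eta = 0 so pred = y
  expect_equal(log_likelihood(ind, obs, pop),
               -log(y * 0.76 * sqrt(2 * pi)), tolerance = 1e-10)

  # shrinking sigma increases the density at a perfect fit, without bound
  lls <- vapply(c(0.76, 0.38, 0.19, 0.05), function(s) {
    pops <- default_population(sigma_pasi = s)
    log_likelihood(ind, obs, pops)
  }, numeric(1))
  expect_true(all(diff(lls) > 0))
  # doubling sigma lowers the log-likelihood at obs = pred by exactly log(2)
  pop2 <- default_population(sigma_pasi = 1.52)
  expect_equal(log_likelihood(ind, obs, pop2),
               log_likelihood(ind, obs, pop) - log(2), tolerance = 1e-10)

  # empty observation set: zero with a warning
  expect_warning(ll0 <- log_likelihood(ind, empty_patient(), pop), "empty")
  expect_equal(ll0, 0)
})

test_that("censored PASI records contribute the tail probability", {
  pop <- test_pop()
  rec <- data.frame(time = 50, type = "pasi", value = 0, cens = -1L)
  obs <- observation_set("c", rec,
                         doses = regimen_doses(regimen(300, 4), 3),
                         weight = 70, pasi_obs0 = 10)
  ind <- make_individual(pop, 70, 10)
  tr <- simulate_pasi(ind, obs$doses, 50, grid_step = 1)
  expected <- stats::pnorm(log(0.05), log(tr$pasi), 0.76, log.p = TRUE)
  expect_equal(log_likelihood(ind, obs, pop), expected, tolerance = 1e-6)
})

test_that("the prior over random effects is Gaussian on the log scale", {
  pop <- test_pop()
  ind0 <- make_individual(pop, 70, 11.6,
                          etas = c(kout = 0, imax = 0, rv = 0))
  sds <- c(0.913, 0.0763, 0.76)
  expect_equal(log_prior(ind0, pop), sum(-log(sds * sqrt(2 * pi))),
               tolerance = 1e-12)
  # one-SD displacement costs exactly 1/2
  ind1 <- make_individual(pop, 70, 11.6,
                          etas = c(kout = 0.913, imax = 0, rv = 0))
  expect_equal(log_prior(ind1, pop), log_prior(ind0, pop) - 0.5,
               tolerance = 1e-12)
  # symmetry
  indm <- make_individual(pop, 70, 11.6,
                          etas = c(kout = -0.4, imax = 0.02, rv = 0.3))
  indp <- make_individual(pop, 70, 11.6,
                          etas = c(kout = 0.4, imax = -0.02, rv = -0.3))
  expect_equal(log_prior(indm, pop), log_prior(indp, pop))
  # unknown random effect name
  bad <- make_individual(pop, 70, 11.6, etas = c(kout = 0, foo = 0.1))
  expect_error(log_prior(bad, pop), "variance")
})

test_that("MAP estimation returns the prior mode without data and improves on truth", {
  pop <- test_pop()
  fit0 <- map_estimate(empty_patient(), pop)
  expect_equal(unname(fit0$etas), rep(0, 3))

  # a moderate truth (all effects within one SD): with daily PASI the
  # remission rate is well identified; extreme kout values are not, because
  # the PASI floors at zero early regardless
  dp <- dense_patient(1, pop, seed = 301, days = 150,
                      etas = c(kout = 0.3, imax = -0.05, rv = 0.1))
  fit <- map_estimate(dp$obs, pop)
  # the attained objective is at least the posterior at the truth
  ctx_obj <- log_likelihood(fit$individual, dp$obs, pop) +
    log_prior(fit$individual, pop)
  truth_ind <- dp$truth
  obj_truth <- log_likelihood(truth_ind, dp$obs, pop) +
    log_prior(truth_ind, pop)
  expect_gte(ctx_obj + 1e-6, obj_truth)
  # dense data pins kout reasonably well
  expect_lt(abs(fit$individual$pd$kout - dp$truth$pd$kout) /
              dp$truth$pd$kout, 0.15)
})

test_that("the conditional sampler reduces to the prior without data", {
  pop <- test_pop()
  cs <- sample_conditional(empty_patient(), pop, n_clones = 2000, seed = 17,
                           burn_in = 500, n_iter = 20000)
  # moment checks at ~3 standard errors (thinned chain, mild autocorrelation)
  expect_lt(abs(mean(cs$etas[, "kout"])), 3.5 * 0.913 / sqrt(2000))
  expect_equal(stats::sd(cs$etas[, "kout"]), 0.913, tolerance = 0.08)
  expect_equal(stats::sd(cs$etas[, "rv"]), 0.76, tolerance = 0.08)
  expect_gt(cs$acceptance_rate, 0.1)
})

test_that("the sampler matches the conjugate normal-normal posterior", {
  pop <- test_pop()
  # a single baseline record y: z = log(y) - log(pasi_obs0) is a normal
  # observation of eta_rv with SD sigma; prior eta_rv ~ N(0, sigma^2);
  # closed-form posterior: N(z/2, sigma^2/2)
  y <- 20; b0 <- 11.6; s <- 0.76
  z <- log(y) - log(b0)
  obs <- baseline_only_patient(value = y, pasi_obs0 = b0)
  cs <- sample_conditional(obs, pop, n_clones = 2000, seed = 23,
                           burn_in = 500, n_iter = 20000,
                           sample_etas = "rv")
  post_mean <- z / 2
  post_sd <- s / sqrt(2)
  expect_equal(mean(cs$etas[, "rv"]), post_mean,
               tolerance = 3.5 * post_sd / sqrt(2000) / abs(post_mean))
  expect_equal(stats::sd(cs$etas[, "rv"]), post_sd, tolerance = 0.08)
})

test_that("the sampler matches a brute-force grid posterior in one dimension", {
  pop <- test_pop()
  dp <- dense_patient(2, pop, seed = 302, days = 120, every = 10,
                      etas = c(kout = 0.2, imax = 0, rv = 0))
  # freeze everything except eta_kout; long chain with strong thinning so
  # the empirical distribution is nearly independent
  cs <- sample_conditional(dp$obs, pop, n_clones = 1500, seed = 29,
                           burn_in = 500, n_iter = 30000,
                           sample_etas = "kout")
  # 400-point normalized grid posterior over eta_kout; a coarse first pass
  # locates the posterior mass so the fine grid resolves it properly
  lp_at <- function(e) {
    ind <- make_individual(pop, dp$obs$weight, dp$obs$pasi_obs0,
                           etas = c(kout = e))
    log_likelihood(ind, dp$obs, pop) + stats::dnorm(e, 0, 0.913, log = TRUE)
  }
  coarse <- seq(-4 * 0.913, 4 * 0.913, length.out = 80)
  lp_c <- vapply(coarse, lp_at, numeric(1))
  keep <- coarse[lp_c > max(lp_c) - 18]  # +- ~6 posterior SDs of mass
  grid <- seq(min(keep), max(keep), length.out = 400)
  lp_g <- vapply(grid, lp_at, numeric(1))
  w <- exp(lp_g - max(lp_g))
  # trapezoidal cumulative distribution, normalized
  cdf <- c(0, cumsum((w[-1] + w[-length(w)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  # Kolmogorov-Smirnov distance between the chain and the grid posterior
  draws <- sort(cs$etas[, "kout"])
  grid_cdf_at <- stats::approxfun(grid, cdf, yleft = 0, yright = 1)
  emp <- seq_along(draws) / length(draws)
  ks <- max(abs(emp - grid_cdf_at(draws)))
  expect_lt(ks, 0.05)
})

test_that("chains are reproducible and invariant to posterior shifts", {
  pop <- test_pop()
  dp <- dense_patient(3, pop, seed = 303, days = 60)
  a <- sample_conditional(dp$obs, pop, n_clones = 50, seed = 41,
                          burn_in = 100, n_iter = 400)
  b <- sample_conditional(dp$obs, pop, n_clones = 50, seed = 41,
                          burn_in = 100, n_iter = 400)
  expect_identical(a$etas, b$etas)
  expect_identical(a$acceptance_rate, b$acceptance_rate)

  # adding a constant to the log-posterior leaves the chain untouched:
  # PK records do not depend on the sampled (PD) random effects, so an
  # extra PK record shifts the log-posterior by a constant for every eta
  rec2 <- rbind(dp$obs$records,
                data.frame(time = 30, type = "pk", value = 45, cens = 0L))
  obs2 <- observation_set(dp$obs$id, rec2, dp$obs$doses, dp$obs$weight,
                          dp$obs$pasi_obs0)
  c2 <- sample_conditional(obs2, pop, n_clones = 50, seed = 41,
                           burn_in = 100, n_iter = 400, start = a$etas[1, ])
  c1 <- sample_conditional(dp$obs, pop, n_clones = 50, seed = 41,
                           burn_in = 100, n_iter = 400, start = a$etas[1, ])
  expect_identical(c1$etas, c2$etas)
})

test_that("posterior spread does not grow with more data", {
  pop <- test_pop()
  dp_short <- dense_patient(4, pop, seed = 304, days = 75)
  set.seed(304)  # same covariate/truth stream, longer follow-up
  dp_long <- dense_patient(4, pop, seed = 304, days = 150)
  cs_s <- sample_conditional(dp_short$obs, pop, n_clones = 200, seed = 51,
                             burn_in = 200, n_iter = 800)
  cs_l <- sample_conditional(dp_long$obs, pop, n_clones = 200, seed = 51,
                             burn_in = 200, n_iter = 800)
  expect_lt(stats::sd(cs_l$etas[, "kout"]),
            stats::sd(cs_s$etas[, "kout"]) * 1.05)
})
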
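test_that("the log posterior matches closed forms on small datasets", {
  cfg <- model_config()
  one <- tibble::tibble(turbine_id = "a", month_key = "2018-05", y = 1)
  par1 <- list(mu = 0, alpha = 0, beta = 0, gamma = 0,
               sigma2_turbine = 1, sigma2_month = 1, sigma2_cell = 1)
  dens <- 3 * dnorm(0, 0, 1, log = TRUE)
  expect_equal(log_posterior(par1, one, cfg), log(0.5) + dens)

  # k successes out of n at a flat rate: the Bernoulli part is the binomial
  # log likelihood
  k <- 7; n <- 20
  dat <- tibble::tibble(turbine_id = "a", month_key = "2018-05",
                        y = rep(c(1, 0), c(k, n - k)))
  par2 <- par1; par2$mu <- qlogis(0.3)
  expect_equal(log_posterior(par2, dat, cfg) - dens,
               k * log(0.3) + (n - k) * log(0.7))

  # outside the prior support
  par3 <- par1; par3$sigma2_cell <- 26
  expect_identical(log_posterior(par3, one, cfg), -Inf)
  par4 <- par1; par4$mu <- 11
  expect_identical(log_posterior(par4, one, cfg), -Inf)
})

test_that("the Gelman-Rubin statistic matches its defining formula", {
  expect_equal(gelman_rubin(cbind(1:4, 1:4)), sqrt(0.75))
  # chains offset by one: B = 2, W = 5/3
  expect_equal(gelman_rubin(cbind(1:4, 2:5)), sqrt((3 / 4 * 5 / 3 + 2 / 4) / (5 / 3)))
  expect_equal(round(gelman_rubin(cbind(1:4, 2:5)), 4), 1.0247)
  expect_equal(gelman_rubin(list(c(1, 2, 3, 4), c(1, 2, 3, 4))), sqrt(0.75))
  # two long chains from one stream converge to 1
  set.seed(123)
  expect_equal(gelman_rubin(matrix(rnorm(20000), ncol = 2)), 1, tolerance = 0.01)
  expect_warning(r <- gelman_rubin(cbind(rep(1, 5), rep(1, 5))), "constant")
  expect_equal(r, 1)
  expect_error(gelman_rubin(matrix(1:4, ncol = 1)), "2 chains")
})

test_that("sampling is reproducible and draw counts follow the schedule", {
  dat <- small_study()$outcomes
  cfg <- model_config(n_iter = 600, burn_in = 100, thin = 2, seed = 42)
  f1 <- fit_entry_model(dat, cfg)
  f2 <- fit_entry_model(dat, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_equal(length(f1$draws$mu), 3 * (600 - 100) / 2)
  f3 <- fit_entry_model(dat, model_config(n_iter = 600, burn_in = 100, seed = 43))
  expect_false(identical(f1$draws$mu, f3$draws$mu))
})

test_that("cell probabilities are the inverse-logit of the linear predictor", {
  fit <- small_fit()
  p <- cell_probabilities(fit)
  expect_true(all(p > 0 & p < 1))
  cells <- fit$cells
  manual <- plogis(fit$draws$mu + fit$draws$alpha[, cells$turbine_index] +
                     fit$draws$beta[, cells$month_index] + fit$draws$gamma)
  expect_equal(as.vector(p), as.vector(manual))
  # increasing the interaction effect increases the probability
  j <- 3
  bumped <- fit
  bumped$draws$gamma[, j] <- bumped$draws$gamma[, j] + 0.5
  expect_true(all(cell_probabilities(bumped)[, j] > p[, j]))
})

test_that("a flat-effects posterior matches the conjugate Beta oracle", {
  # single cell, 30 entries out of 100: Beta(31, 71) posterior under a
  # uniform prior has mean 31/102 = 0.30392
  dat <- tibble::tibble(turbine_id = "a", month_key = "2018-05",
                        y = rep(c(1, 0), c(30, 70)))
  fit <- fit_entry_model(dat, model_config(seed = 9, include_main_effects = FALSE))
  p <- cell_probabilities(fit)
  expect_equal(mean(p), 31 / 102, tolerance = 0.03 / (31 / 102))
  q <- quantile(p, c(0.025, 0.975))
  oracle_q <- qbeta(c(0.025, 0.975), 31, 71)
  expect_equal(unname(q), oracle_q, tolerance = 0.1)
})

test_that("with no heterogeneity the posterior recovers the generating rate", {
  cfg <- sim_config(n_turbines = 20, n_siemens = 8, n_months = 6,
                    total_approaches = 20000, mu = qlogis(0.3),
                    sigma_alpha = 0, sigma_beta = 0, sigma_gamma = 0,
                    install_waves = c("1" = 1), seed = 5)
  truth <- simulate_effects(cfg, seed = 5)
  expect_equal(unique(as.vector(truth$p_true)), 0.3, tolerance = 1e-12)
  outcomes <- simulate_outcomes(truth, cfg, seed = 6)
  fit <- fit_entry_model(outcomes, model_config(seed = 5))
  avg <- reference_average(fit)
  expect_equal(mean(avg$draws), 0.3, tolerance = 0.02 / 0.3)
})

test_that("the sampler agrees with an independent Gibbs engine (JAGS)", {
  skip_if_not_installed("rjags")
  set.seed(31)
  # small design with clearly different cells
  cells <- expand.grid(t = 1:3, m = 1:2)
  n <- rep(150, 6)
  k <- c(25, 60, 45, 30, 75, 40)
  dat <- tibble::tibble(
    turbine_id = rep(paste0("T", cells$t), n),
    month_key = rep(paste0("2018-0", 4 + cells$m), n),
    y = unlist(purrr::map2(k, n, ~ rep(c(1, 0), c(.x, .y - .x))))
  )
  fit <- fit_entry_model(dat, model_config(seed = 8))
  mine <- colMeans(cell_probabilities(fit))
  # hand JAGS the cells in the fitted model's own cell order
  fc <- fit$cells
  kk <- fc$k; nn <- fc$n

  jm <- rjags::jags.model(textConnection("
    model {
      for (i in 1:C) { k[i] ~ dbin(p[i], n[i])
                       logit(p[i]) <- mu + a[t[i]] + b[m[i]] + g[i]
                       g[i] ~ dnorm(0, 1/s2g) }
      for (j in 1:T) { a[j] ~ dnorm(0, 1/s2a) }
      for (j in 1:M) { b[j] ~ dnorm(0, 1/s2b) }
      mu ~ dunif(-10, 10)
      s2a ~ dunif(0, 25); s2b ~ dunif(0, 25); s2g ~ dunif(0, 25)
    }"), data = list(C = 6, T = 3, M = 2, t = fc$turbine_index,
                     m = fc$month_index, n = nn, k = kk),
    n.chains = 3, quiet = TRUE)
  update(jm, 1000, progress.bar = "none")
  s <- rjags::coda.samples(jm, "p", 4000, progress.bar = "none")
  theirs <- colMeans(as.matrix(s))
  expect_equal(unname(mine), unname(theirs), tolerance = 0.05)
})

test_that("diagnostics, tidy and glance expose convergence information", {
  fit <- small_fit()
  d <- diagnostics(fit)
  expect_true(all(c("mu", "sigma2_cell") %in% d$parameter))
  expect_equal(nrow(d), 4 + nrow(fit$cells))
  expect_true(all(d$rhat < 1.2))
  expect_true(all(d$n_eff > 10))
  td <- tidy(fit)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  te <- tidy(fit, effects = TRUE)
  expect_equal(nrow(te), 4 + length(fit$turbine_levels) + length(fit$month_levels))
  g <- glance(fit)
  expect_equal(g$n_obs, 400)
  expect_equal(g$n_draws, length(fit$draws$mu))
})

test_that("degenerate responses warn about boundary posteriors", {
  dat <- tibble::tibble(turbine_id = "a", month_key = "2018-05", y = rep(1, 30))
  # an all-ones response drives the posterior to the boundary; acceptance
  # rates can also end up outside the target band there
  ws <- capture_warnings(fit_entry_model(dat, model_config(n_iter = 300, burn_in = 100)))
  expect_match(ws, "boundary", all = FALSE)
})
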
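# Two-way random-effects Bernoulli ANOVA on the logit scale:
#   y_i ~ Bernoulli(p[t(i), m(i)])
#   logit p[t, m] = mu + alpha_t + beta_m + gamma_tm
#   alpha_t ~ N(0, s2_turbine), beta_m ~ N(0, s2_month),
#   gamma_tm ~ N(0, s2_cell)
# with vague uniform priors on mu and on each variance component.
# Fitted by adaptive random-walk Metropolis-within-Gibbs; the Bernoulli
# likelihood is aggregated to per-cell binomial counts (identical likelihood,
# one term per observed turbine-month cell instead of one per approach).

#' MCMC configuration for the entry model
#'
#' Defaults follow standard practice for this model class: three chains of
#' 5,000 iterations, burn-in 500, thinning rate 2, uniform priors on the
#' grand mean over `[-10, 10]` and on each variance over `[0, 25]` (vague on
#' the logit scale).
#'
#' @param n_chains Number of independent chains.
#' @param n_iter Iterations per chain (including burn-in).
#' @param burn_in Iterations discarded per chain.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Integer seed; chains are seeded reproducibly from it.
#' @param mu_range Uniform prior support for the grand mean (logit scale).
#' @param variance_range Uniform prior support applied to each variance
#'   component.
#' @param include_main_effects If `FALSE`, drop the turbine and month main
#'   effects and model a single turbine-month random effect.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_chains = 3, n_iter = 5000, burn_in = 500, thin = 2,
                         seed = 1, mu_range = c(-10, 10),
                         variance_range = c(0, 25),
                         include_main_effects = TRUE) {
  if (burn_in >= n_iter) abort("burn_in must be smaller than n_iter")
  if (thin < 1) abort("thin must be >= 1")
  if (diff(mu_range) <= 0 || diff(variance_range) < 0 || any(!is.finite(mu_range)) ||
      any(!is.finite(variance_range)) || variance_range[1] < 0) {
    abort("prior ranges must be finite with positive width (variances non-negative)")
  }
  structure(list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, seed = as.integer(seed), mu_range = mu_range,
                 variance_range = variance_range,
                 include_main_effects = include_main_effects),
            class = "model_config")
}

log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(x)))

# Aggregate entry data to per-cell binomial counts.
entry_cells <- function(data) {
  if (is.null(attr(data, "turbine_levels"))) data <- index_entry_data(data)
  cells <- data |>
    dplyr::group_by(.data$turbine_index, .data$month_index,
                    .data$turbine_id, .data$month_key) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$y), .groups = "drop") |>
    dplyr::arrange(.data$turbine_index, .data$month_index)
  attr(cells, "turbine_levels") <- attr(data, "turbine_levels")
  attr(cells, "month_levels") <- attr(data, "month_levels")
  cells
}

#' Unnormalised log posterior of the entry model
#'
#' Sum of the Bernoulli log likelihood, the Normal log densities of the
#' random effects, and the flat priors (0 inside their support, `-Inf`
#' outside). Exposed for transparency and testing; the sampler uses the same
#' cell-aggregated likelihood.
#'
#' @param params List with `mu`, `alpha`, `beta`, `gamma` (aligned with the
#'   observed cells in index order), `sigma2_turbine`, `sigma2_month`,
#'   `sigma2_cell`.
#' @param data Entry-data tibble (`turbine_id`, `month_key`, `y`).
#' @param config A [model_config()].
#' @return Scalar log posterior; `-Inf` outside the prior support.
#' @export
log_posterior <- function(params, data, config = model_config()) {
  cells <- entry_cells(data)
  vr <- config$variance_range; mr <- config$mu_range
  s2 <- c(params$sigma2_turbine, params$sigma2_month, params$sigma2_cell)
  if (!config$include_main_effects) s2 <- params$sigma2_cell
  if (params$mu < mr[1] || params$mu > mr[2] ||
      any(s2 < vr[1] | s2 > vr[2]) || any(s2 <= 0)) {
    return(-Inf)
  }
  eta <- params$mu + params$gamma
  dens <- dnorm(params$gamma, 0, sqrt(params$sigma2_cell), log = TRUE)
  if (config$include_main_effects) {
    eta <- eta + params$alpha[cells$turbine_index] + params$beta[cells$month_index]
    dens <- c(dens,
              dnorm(params$alpha, 0, sqrt(params$sigma2_turbine), log = TRUE),
              dnorm(params$beta, 0, sqrt(params$sigma2_month), log = TRUE))
  }
  sum(cells$k * eta - cells$n * log1pexp(eta)) + sum(dens)
}

# Draw a variance component from its full conditional under a Uniform(range)
# prior on the variance: density \propto s2^(-kdim/2) exp(-S/(2 s2)).
# For kdim >= 3 this is a truncated inverse-gamma sampled by inverse CDF;
# smaller dimensions fall back to a Metropolis step.
draw_variance <- function(s2, S, kdim, range) {
  lo <- max(range[1], 1e-10); hi <- range[2]
  shape <- kdim / 2 - 1
  if (shape > 0 && S > 0) {
    rate <- S / 2
    u_lo <- stats::pgamma(1 / hi, shape, rate = rate)
    u_hi <- if (lo <= 1e-10) 1 else stats::pgamma(1 / lo, shape, rate = rate)
    u <- runif(1, u_lo, u_hi)
    y <- stats::qgamma(u, shape, rate = rate)
    return(min(max(1 / y, lo), hi))
  }
  prop <- s2 * exp(0.5 * rnorm(1))
  if (prop < lo || prop > hi) return(s2)
  lp <- function(v) -(kdim / 2) * log(v) - S / (2 * v)
  # include the log-scale proposal Jacobian
  if (log(runif(1)) < lp(prop) - lp(s2) + log(prop) - log(s2)) prop else s2
}

run_chain <- function(cells, config, chain_id) {
  set.seed(config$seed * 1009L + chain_id)
  tc <- cells$turbine_index; mc <- cells$month_index
  n <- cells$n; k <- cells$k
  Tn <- max(tc); Mn <- max(mc); C <- nrow(cells)
  main <- config$include_main_effects
  vr <- config$variance_range; mr <- config$mu_range

  phat <- (sum(k) + 1) / (sum(n) + 2)
  mu <- min(max(qlogis(phat) + rnorm(1, 0, 0.4), mr[1]), mr[2])
  alpha <- if (main) rnorm(Tn, 0, 0.3) else numeric(Tn)
  beta <- if (main) rnorm(Mn, 0, 0.3) else numeric(Mn)
  gamma <- rnorm(C, 0, 0.3)
  mid <- mean(vr)
  s2 <- abs(mid + rnorm(3, 0, mid / 4))
  s2 <- pmin(pmax(s2, 0.01), vr[2])

  eta <- mu + gamma
  if (main) eta <- eta + alpha[tc] + beta[mc]
  ll <- function(e) k * e - n * log1pexp(e)
  ll_cur <- ll(eta)

  step <- c(mu = 0.1, alpha = 0.3, beta = 0.3, gamma = 0.5)
  acc <- att <- c(mu = 0, alpha = 0, beta = 0, gamma = 0)

  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  out <- list(mu = numeric(n_keep),
              alpha = matrix(0, n_keep, Tn), beta = matrix(0, n_keep, Mn),
              gamma = matrix(0, n_keep, C), sigma2 = matrix(NA_real_, n_keep, 3,
                dimnames = list(NULL, c("turbine", "month", "cell"))))
  kept <- 0L

  for (iter in seq_len(config$n_iter)) {
    in_burn <- iter <= config$burn_in

    # grand mean
    d <- step["mu"] * rnorm(1)
    if (mu + d >= mr[1] && mu + d <= mr[2]) {
      ll_new <- ll(eta + d)
      if (log(runif(1)) < sum(ll_new - ll_cur)) {
        mu <- mu + d; eta <- eta + d; ll_cur <- ll_new
        acc["mu"] <- acc["mu"] + 1
      }
    }
    att["mu"] <- att["mu"] + 1

    if (main) {
      # turbine effects, elementwise Metropolis
      d <- step["alpha"] * rnorm(Tn)
      ll_new <- ll(eta + d[tc])
      dpost <- rowsum(ll_new - ll_cur, tc)[, 1] +
        dnorm(alpha + d, 0, sqrt(s2[1]), log = TRUE) -
        dnorm(alpha, 0, sqrt(s2[1]), log = TRUE)
      ok <- log(runif(Tn)) < dpost
      if (any(ok)) {
        alpha[ok] <- alpha[ok] + d[ok]
        upd <- ok[tc]
        eta[upd] <- eta[upd] + d[tc][upd]
        ll_cur[upd] <- ll_new[upd]
      }
      acc["alpha"] <- acc["alpha"] + mean(ok); att["alpha"] <- att["alpha"] + 1

      # month effects
      d <- step["beta"] * rnorm(Mn)
      ll_new <- ll(eta + d[mc])
      dpost <- rowsum(ll_new - ll_cur, mc)[, 1] +
        dnorm(beta + d, 0, sqrt(s2[2]), log = TRUE) -
        dnorm(beta, 0, sqrt(s2[2]), log = TRUE)
      ok <- log(runif(Mn)) < dpost
      if (any(ok)) {
        beta[ok] <- beta[ok] + d[ok]
        upd <- ok[mc]
        eta[upd] <- eta[upd] + d[mc][upd]
        ll_cur[upd] <- ll_new[upd]
      }
      acc["beta"] <- acc["beta"] + mean(ok); att["beta"] <- att["beta"] + 1
    }

    # interaction effects, one per observed cell
    d <- step["gamma"] * rnorm(C)
    ll_new <- ll(eta + d)
    dpost <- ll_new - ll_cur +
      dnorm(gamma + d, 0, sqrt(s2[3]), log = TRUE) -
      dnorm(gamma, 0, sqrt(s2[3]), log = TRUE)
    ok <- log(runif(C)) < dpost
    if (any(ok)) {
      gamma[ok] <- gamma[ok] + d[ok]
      eta[ok] <- eta[ok] + d[ok]
      ll_cur[ok] <- ll_new[ok]
    }
    acc["gamma"] <- acc["gamma"] + mean(ok); att["gamma"] <- att["gamma"] + 1

    # variance components (Gibbs)
    if (main) {
      s2[1] <- draw_variance(s2[1], sum(alpha^2), Tn, vr)
      s2[2] <- draw_variance(s2[2], sum(beta^2), Mn, vr)
    }
    s2[3] <- draw_variance(s2[3], sum(gamma^2), C, vr)

    # step-size adaptation, burn-in only (frozen afterward so the kept
    # draws come from a fixed-kernel chain)
    if (in_burn && iter %% 50 == 0) {
      rate <- acc / pmax(att, 1)
      step <- step * exp(pmin(pmax(rate - 0.3, -0.25), 0.25))
      acc[] <- 0; att[] <- 0
    }
    if (iter == config$burn_in) {
      # report acceptance over the kept (frozen-kernel) portion only
      acc[] <- 0; att[] <- 0
    }

    if (!in_burn && (iter - config$burn_in) %% config$thin == 0) {
      kept <- kept + 1L
      out$mu[kept] <- mu
      out$alpha[kept, ] <- alpha
      out$beta[kept, ] <- beta
      out$gamma[kept, ] <- gamma
      out$sigma2[kept, ] <- if (main) s2 else c(NA, NA, s2[3])
    }
  }
  out$accept <- acc / pmax(att, 1)
  out
}

#' Fit the Bayesian turbine-month entry model
#'
#' Runs independent adaptive Metropolis-within-Gibbs chains over parameter
#' blocks (grand mean; turbine effects; month effects; turbine-month
#' interaction effects; variance components), discards burn-in, thins, and
#' returns the pooled posterior draws. Reproducible for a given
#' `config$seed`.
#'
#' @param data Entry-data tibble with columns `turbine_id`, `month_key`, `y`
#'   (e.g. from [build_dataset()] or [read_entry_data()]).
#' @param config A [model_config()].
#' @return An object of class `entry_fit`: posterior draws of `mu`, `alpha`,
#'   `beta`, `gamma` and the variance components, the per-draw chain index,
#'   the observed-cell table (with approach counts), and sampler metadata.
#'   Use [cell_probabilities()], [risk_summary()], [tidy()], [glance()].
#' @export
fit_entry_model <- function(data, config = model_config()) {
  if (nrow(data) == 0) abort("empty entry dataset")
  if (any(!data$y %in% c(0, 1))) abort("y must be 0/1")
  cells <- entry_cells(data)
  if (sum(cells$k) == 0 || sum(cells$k) == sum(cells$n)) {
    warn("all responses identical (all 0 or all 1): posterior sits at the boundary")
  }
  chains <- purrr::map(seq_len(config$n_chains),
                       function(ch) run_chain(cells, config, ch))
  n_keep <- length(chains[[1]]$mu)
  fit <- structure(list(
    draws = list(
      mu = unlist(purrr::map(chains, "mu")),
      alpha = do.call(rbind, purrr::map(chains, "alpha")),
      beta = do.call(rbind, purrr::map(chains, "beta")),
      gamma = do.call(rbind, purrr::map(chains, "gamma")),
      sigma2 = do.call(rbind, purrr::map(chains, "sigma2"))
    ),
    chain = rep(seq_len(config$n_chains), each = n_keep),
    n_keep = n_keep,
    cells = cells,
    turbine_levels = attr(cells, "turbine_levels"),
    month_levels = attr(cells, "month_levels"),
    config = config,
    accept = do.call(rbind, purrr::map(chains, "accept")),
    n_obs = sum(cells$n), n_entries = sum(cells$k)
  ), class = "entry_fit")
  keep_cols <- if (config$include_main_effects) c("mu", "alpha", "beta", "gamma") else c("mu", "gamma")
  band <- fit$accept[, keep_cols, drop = FALSE]
  if (any(band < 0.10 | band > 0.70)) {
    warn("some acceptance rates outside [0.10, 0.70] after adaptation")
  }
  fit
}

#' @export
print.entry_fit <- function(x, ...) {
  cat("Bayesian turbine-month entry model\n")
  cat(sprintf("  %d approaches, %d entries (%.1f%%), %d observed cells (%d turbines x %d months)\n",
              x$n_obs, x$n_entries, 100 * x$n_entries / x$n_obs,
              nrow(x$cells), length(x$turbine_levels), length(x$month_levels)))
  cat(sprintf("  %d chains x %d kept draws (burn-in %d, thin %d)\n",
              x$config$n_chains, x$n_keep, x$config$burn_in, x$config$thin))
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic
#'
#' The classic potential scale reduction factor
#' `sqrt(((n - 1) / n * W + B / n) / W)` with `B = n * var(chain means)` and
#' `W` the mean within-chain sample variance.
#'
#' @param chains A draws-by-chains matrix, or a list of equal-length numeric
#'   vectors (one per chain).
#' @return The scalar R-hat. Constant chains (`W = 0`) return 1 with a
#'   warning.
#' @export
gelman_rubin <- function(chains) {
  x <- if (is.list(chains)) do.call(cbind, chains) else as.matrix(chains)
  if (ncol(x) < 2 || nrow(x) < 2) abort("need >= 2 chains with >= 2 draws each")
  n <- nrow(x)
  W <- mean(apply(x, 2, var))
  if (W == 0) {
    warn("constant chains: R-hat undefined, returning 1")
    return(1)
  }
  B <- n * var(colMeans(x))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via the initial positive sequence of autocorrelations
ess <- function(x, max_lag = 100) {
  n <- length(x)
  if (var(x) == 0) return(n)
  rho <- as.numeric(acf(x, lag.max = min(max_lag, n - 2), plot = FALSE)$acf)[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(rho))
}

split_by_chain <- function(fit, v) {
  matrix(v, nrow = fit$n_keep, ncol = fit$config$n_chains)
}

#' Convergence diagnostics for a fitted entry model
#'
#' R-hat and effective draw count for the monitored parameters: the grand
#' mean, the variance components, and every observed-cell entry probability.
#'
#' @param fit An `entry_fit`.
#' @return A tibble with columns `parameter`, `rhat`, `n_eff`.
#' @export
diagnostics <- function(fit) {
  p <- cell_probabilities(fit)
  scalars <- list(mu = fit$draws$mu)
  s2names <- c("sigma2_turbine", "sigma2_month", "sigma2_cell")
  for (i in 1:3) {
    v <- fit$draws$sigma2[, i]
    if (!all(is.na(v))) scalars[[s2names[i]]] <- v
  }
  cell_names <- paste0("p[", fit$cells$turbine_id, ",", fit$cells$month_key, "]")
  rows <- c(
    purrr::imap(scalars, function(v, nm) {
      tibble::tibble(parameter = nm,
                     rhat = gelman_rubin(split_by_chain(fit, v)),
                     n_eff = ess(v))
    }),
    purrr::map(seq_len(ncol(p)), function(j) {
      tibble::tibble(parameter = cell_names[j],
                     rhat = gelman_rubin(split_by_chain(fit, p[, j])),
                     n_eff = ess(p[, j]))
    })
  )
  dplyr::bind_rows(rows)
}

#' Per-draw entry probabilities for the observed turbine-month cells
#'
#' Applies the inverse logit to `mu + alpha_t + beta_m + gamma_tm` draw-wise.
#' Only observed cells (>= 1 approach) are represented; unobserved cells are
#' excluded from all downstream summaries.
#'
#' @param fit An `entry_fit`.
#' @return A draws-by-cells numeric matrix; the cell table is attached as
#'   attribute `cells`.
#' @export
cell_probabilities <- function(fit) {
  cells <- fit$cells
  eta <- fit$draws$mu + fit$draws$gamma
  if (fit$config$include_main_effects) {
    eta <- eta + fit$draws$alpha[, cells$turbine_index, drop = FALSE] +
      fit$draws$beta[, cells$month_index, drop = FALSE]
  }
  p <- plogis(eta)
  colnames(p) <- paste0(cells$turbine_id, ":", cells$month_key)
  attr(p, "cells") <- cells
  p
}

#' @method tidy entry_fit
#' @export
tidy.entry_fit <- function(x, effects = FALSE, conf_level = 0.95, ...) {
  lo <- (1 - conf_level) / 2
  summarise_one <- function(nm, v) {
    tibble::tibble(term = nm, estimate = mean(v), std.error = sd(v),
                   conf.low = as.numeric(quantile(v, lo)),
                   conf.high = as.numeric(quantile(v, 1 - lo)),
                   rhat = gelman_rubin(split_by_chain(x, v)))
  }
  out <- list(summarise_one("mu", x$draws$mu))
  s2names <- c("sigma2_turbine", "sigma2_month", "sigma2_cell")
  for (i in 1:3) {
    v <- x$draws$sigma2[, i]
    if (!all(is.na(v))) out <- c(out, list(summarise_one(s2names[i], v)))
  }
  if (effects) {
    for (j in seq_along(x$turbine_levels)) {
      out <- c(out, list(summarise_one(paste0("alpha[", x$turbine_levels[j], "]"),
                                       x$draws$alpha[, j])))
    }
    for (j in seq_along(x$month_levels)) {
      out <- c(out, list(summarise_one(paste0("beta[", x$month_levels[j], "]"),
                                       x$draws$beta[, j])))
    }
  }
  dplyr::bind_rows(out)
}

#' @method glance entry_fit
#' @export
glance.entry_fit <- function(x, ...) {
  d <- diagnostics(x)
  tibble::tibble(
    n_obs = x$n_obs, n_entries = x$n_entries,
    n_cells = nrow(x$cells),
    n_turbines = length(x$turbine_levels), n_months = length(x$month_levels),
    n_chains = x$config$n_chains, n_draws = length(x$draws$mu),
    max_rhat = max(d$rhat), min_n_eff = min(d$n_eff)
  )
}
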
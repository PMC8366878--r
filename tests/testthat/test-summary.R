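# Deterministic checks use stub fits with hand-chosen draws; stochastic
# checks use the cached small fit.

two_cell_stub <- function() {
  cells <- tibble::tibble(turbine_id = c("A", "B"), month_key = "2018-05",
                          n = c(10L, 30L), k = c(1L, 15L))
  # constant draws: p = (0.1, 0.5) in every draw
  gamma <- matrix(rep(qlogis(c(0.1, 0.5)), each = 4), nrow = 4)
  stub_fit(cells, mu_draws = rep(0, 4), gamma_draws = gamma)
}

test_that("the reference average is the count-weighted mean of cell draws", {
  fit <- two_cell_stub()
  avg <- reference_average(fit)
  expect_equal(avg$draws, rep((10 * 0.1 + 30 * 0.5) / 40, 4))
  expect_equal(avg$empirical, 16 / 40)

  # equal cell probabilities make the weights irrelevant
  cells <- tibble::tibble(turbine_id = c("A", "B"), month_key = "2018-05",
                          n = c(3L, 97L), k = c(1L, 29L))
  flat <- stub_fit(cells, rep(qlogis(0.3), 3), matrix(0, 3, 2))
  expect_equal(reference_average(flat)$draws, rep(0.3, 3))
})

test_that("the study counts give the printed overall entry rate and interval", {
  s <- entry_rate_summary(3015, 10222)
  expect_equal(round(100 * s$rate, 1), 29.5)
  expect_equal(round(100 * s$cri_low, 1), 28.6)
  expect_equal(round(100 * s$cri_high, 1), 30.4)
  expect_error(entry_rate_summary(5, 0), "approaches")
})

test_that("group means average observed cells, unweighted by default", {
  cells <- tibble::tibble(
    turbine_id = c("A", "A", "B", "C", "C", "C"),
    month_key = c("2018-05", "2018-06", "2018-05", "2018-05", "2018-06", "2018-07"),
    n = c(5L, 15L, 8L, 2L, 2L, 2L), k = 0L)
  pvals <- c(0.2, 0.4, 0.35, 0.1, 0.2, 0.6)
  fit <- stub_fit(cells, rep(0, 2), matrix(rep(qlogis(pvals), each = 2), nrow = 2))
  gt <- group_means(fit, "turbine")
  expect_equal(gt[1, ], c(A = 0.3, B = 0.35, C = 0.3))
  gm <- group_means(fit, "month")
  expect_equal(gm[1, ], c("2018-05" = mean(c(0.2, 0.35, 0.1)),
                          "2018-06" = 0.3, "2018-07" = 0.6))
  # count-weighted option
  gw <- group_means(fit, "turbine", weighted = TRUE)
  expect_equal(unname(gw[1, "A"]), (5 * 0.2 + 15 * 0.4) / 20)
  # a turbine observed in a single month reduces to that cell
  expect_equal(unname(gt[1, "B"]), 0.35)
})

test_that("probability of direction counts strictly positive differences", {
  expect_equal(probability_of_direction(c(0.5, 0.6, 0.7), c(0.1, 0.2, 0.3)), 1)
  expect_equal(probability_of_direction(c(0.3, 0.3, 0.3), c(0.2, 0.4, 0.2)), 2 / 3)
  # ties are not greater: identical draws give 0
  expect_equal(probability_of_direction(c(0.3, 0.3), c(0.3, 0.3)), 0)
  m <- cbind(a = c(0.1, 0.2), b = c(0.9, 0.8))
  expect_equal(probability_of_direction(c(0.5, 0.5), m), c(a = 1, b = 0))
  expect_error(probability_of_direction(1:3, 1:4), "differ")
})

test_that("classification uses the 0.95 / 0.05 thresholds by default", {
  expect_equal(classify_direction(0.976), "safer")
  expect_equal(classify_direction(0), "riskier")
  expect_equal(classify_direction(0.5), "average")
  expect_equal(classify_direction(c(0.95, 0.05)), c("average", "average"))
  # the relaxed map threshold
  expect_equal(classify_direction(0.92, safer_threshold = 0.90,
                                  riskier_threshold = 0.10), "safer")
  expect_error(classify_direction(1.2), "0, 1")
})

test_that("extremal ratios reproduce the printed study contrasts", {
  expect_equal(round(rszentry:::risk_ratio(c(0.190, 0.454)), 2), 2.39)
  expect_equal(round(rszentry:::risk_ratio(c(0.153, 0.617)), 2), 4.03)
  expect_equal(rszentry:::risk_ratio(c(0.3, 0.3, 0.3)), 1)
})

test_that("the summary table covers all scopes with coherent intervals", {
  fit <- small_fit()
  s <- risk_summary(fit)
  expect_setequal(unique(s$scope), c("overall", "turbine", "month", "turbine_month"))
  expect_equal(sum(s$scope == "turbine"), length(fit$turbine_levels))
  expect_equal(sum(s$scope == "month"), length(fit$month_levels))
  expect_equal(sum(s$scope == "turbine_month"), nrow(fit$cells))
  expect_true(all(s$cri_low <= s$posterior_mean & s$posterior_mean <= s$cri_high))
  expect_true(all(s$pd >= 0 & s$pd <= 1, na.rm = TRUE))
  h <- headline_stats(s)
  expect_gte(h$turbine_ratio, 1)
  expect_gte(h$cell_ratio, h$turbine_ratio * 0 + 1)
  expect_true(all(h$monthly_range$n_months > 1))
  expect_equal(glance(s)$empirical_rate, fit$n_entries / fit$n_obs)

  # the weighted reference lies between the cell extremes, draw by draw
  p <- cell_probabilities(fit)
  avg <- reference_average(fit, p)
  expect_true(all(avg$draws >= apply(p, 1, min) & avg$draws <= apply(p, 1, max)))

  # pd and its complement partition the draws when there are no exact ties
  gt <- group_means(fit, "turbine", p)
  pd_fwd <- probability_of_direction(avg$draws, gt)
  pd_rev <- purrr::map_dbl(seq_len(ncol(gt)),
                           function(j) mean(gt[, j] - avg$draws > 0))
  expect_equal(unname(pd_fwd + pd_rev), rep(1, ncol(gt)))
})

test_that("summaries are equivariant under relabelling of turbines", {
  cells <- tibble::tibble(
    turbine_id = c("A", "A", "B", "B"),
    month_key = rep(c("2018-05", "2018-06"), 2),
    n = c(4L, 6L, 10L, 5L), k = c(1L, 2L, 6L, 1L))
  set.seed(77)
  gamma <- matrix(rnorm(40, 0, 0.4), 10, 4)
  fit1 <- stub_fit(cells, rnorm(10, -0.8, 0.1), gamma)
  # swap the labels A <-> B, leaving counts and draws attached to the same cells
  cells2 <- cells
  cells2$turbine_id <- c("B", "B", "A", "A")
  fit2 <- stub_fit(cells2, fit1$draws$mu, gamma)
  s1 <- tibble::as_tibble(risk_summary(fit1)) |>
    dplyr::arrange(scope, turbine_id, month_key)
  s2 <- tibble::as_tibble(risk_summary(fit2)) |>
    dplyr::mutate(turbine_id = dplyr::recode(turbine_id, A = "B", B = "A")) |>
    dplyr::arrange(scope, turbine_id, month_key)
  expect_equal(unname(s1$posterior_mean), unname(s2$posterior_mean))
  expect_equal(unname(s1$pd), unname(s2$pd))
  expect_equal(s1$class, s2$class)
})

test_that("identical cells produce the degenerate all-average summary", {
  cells <- tibble::tibble(turbine_id = c("A", "B"), month_key = "2018-05",
                          n = c(10L, 10L), k = c(3L, 3L))
  fit <- stub_fit(cells, rep(qlogis(0.3), 5), matrix(0, 5, 2))
  s <- risk_summary(fit)
  h <- headline_stats(s)
  expect_equal(h$turbine_ratio, 1)
  expect_equal(h$cell_ratio, 1)
  expect_equal(h$cell_sd_mean, 0)
  # every quantity ties with the average in every draw, so by the strict
  # ">" convention pd is exactly 0 for all of them
  expect_true(all(s$pd[s$scope != "overall"] == 0))
})
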
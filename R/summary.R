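# Posterior summaries: the facility reference average, per-turbine /
# per-month / per-cell means, probability of direction, and the
# safer / average / riskier classification.

#' Facility reference average probability of entry
#'
#' The reference against which turbines, months and cells are compared: the
#' overall probability of entry (entries / approaches). It is computed per
#' posterior draw as the approach-count-weighted mean of the cell
#' probabilities — the model analogue of the empirical ratio — so the
#' reference carries posterior uncertainty; the empirical scalar is returned
#' alongside.
#'
#' @param fit An `entry_fit`.
#' @param p_draws Optional precomputed [cell_probabilities()] matrix.
#' @return A list with `draws` (per-draw weighted average) and `empirical`
#'   (sum(y) / n).
#' @export
reference_average <- function(fit, p_draws = NULL) {
  p <- p_draws %||% cell_probabilities(fit)
  n <- fit$cells$n
  if (sum(n) == 0) abort("no approaches in the fitted data")
  list(draws = as.numeric(p %*% n) / sum(n),
       empirical = fit$n_entries / fit$n_obs)
}

#' Empirical entry rate with its binomial-posterior credible interval
#'
#' The entries/approaches ratio together with the 2.5th/97.5th percentiles
#' of the posterior under a uniform prior on the rate, i.e.
#' Beta(entries + 1, approaches - entries + 1).
#'
#' @param entries Number of rotor-swept-zone entries.
#' @param approaches Number of approaches within the approach radius.
#' @param conf_level Credible-interval mass.
#' @return A tibble with `rate`, `cri_low`, `cri_high` (probabilities).
#' @export
entry_rate_summary <- function(entries, approaches, conf_level = 0.95) {
  if (approaches <= 0 || entries < 0 || entries > approaches) {
    abort("need 0 <= entries <= approaches, approaches > 0")
  }
  lo <- (1 - conf_level) / 2
  tibble::tibble(
    rate = entries / approaches,
    cri_low = qbeta(lo, entries + 1, approaches - entries + 1),
    cri_high = qbeta(1 - lo, entries + 1, approaches - entries + 1)
  )
}

#' Per-draw group means of cell probabilities
#'
#' Per turbine: the unweighted mean of that turbine's cell probabilities over
#' the months in which it was observed. Per month: the unweighted mean over
#' turbines observed in that month. Set `weighted = TRUE` to weight cells by
#' approach counts instead.
#'
#' @param fit An `entry_fit`.
#' @param by `"turbine"` or `"month"`.
#' @param p_draws Optional precomputed [cell_probabilities()] matrix.
#' @param weighted Weight cells by approach counts.
#' @return A draws-by-groups matrix with group ids as column names.
#' @export
group_means <- function(fit, by = c("turbine", "month"), p_draws = NULL,
                        weighted = FALSE) {
  by <- match.arg(by)
  p <- p_draws %||% cell_probabilities(fit)
  cells <- fit$cells
  ids <- if (by == "turbine") cells$turbine_id else cells$month_key
  levels <- if (by == "turbine") fit$turbine_levels else fit$month_levels
  w <- if (weighted) cells$n else rep(1, nrow(cells))
  # indicator matrix cells x groups with normalised weights
  ind <- matrix(0, nrow(cells), length(levels), dimnames = list(NULL, levels))
  ind[cbind(seq_len(nrow(cells)), match(ids, levels))] <- w
  ind <- sweep(ind, 2, colSums(ind), "/")
  p %*% ind
}

#' Probability of direction
#'
#' The proportion of posterior draws for which the reference average exceeds
#' the quantity: `pd = mean(avg - q > 0)` (strict inequality; exact ties
#' count as not greater). Values near 1 mean the quantity is below average
#' (safer); values near 0 mean above average (riskier).
#'
#' @param avg_draws Numeric vector of reference-average draws.
#' @param quantity_draws Numeric vector or draws-by-quantities matrix aligned
#'   with `avg_draws`.
#' @return A scalar or per-column numeric vector of proportions.
#' @export
probability_of_direction <- function(avg_draws, quantity_draws) {
  q <- as.matrix(quantity_draws)
  if (nrow(q) != length(avg_draws)) abort("draw counts differ")
  out <- colMeans(avg_draws - q > 0)
  if (ncol(q) == 1 && is.null(colnames(q))) out <- unname(out)[1]
  out
}

#' Classify probability of direction into safer / average / riskier
#'
#' @param pd Probability-of-direction values in `[0, 1]`.
#' @param safer_threshold pd above this means the quantity is credibly below
#'   the facility average.
#' @param riskier_threshold pd below this means credibly above average.
#' @return Character vector: `"safer"`, `"average"` or `"riskier"`.
#' @export
classify_direction <- function(pd, safer_threshold = 0.95,
                               riskier_threshold = 0.05) {
  if (any(pd < 0 | pd > 1, na.rm = TRUE)) abort("pd must lie in [0, 1]")
  dplyr::case_when(pd > safer_threshold ~ "safer",
                   pd < riskier_threshold ~ "riskier",
                   TRUE ~ "average")
}

risk_ratio <- function(means) max(means) / min(means)

#' Posterior risk summary of a fitted entry model
#'
#' One row per scope: the overall reference average, every turbine, every
#' month, and every observed turbine-month cell, each with its posterior
#' mean, equal-tailed 95% credible interval (2.5/97.5 percentiles of pooled
#' draws), probability of direction versus the facility average, and the
#' safer/average/riskier classification.
#'
#' Headline statistics are attached as attribute `"headline"` (also via
#' [headline_stats()]): the max/min ratio of per-turbine posterior means, the
#' max/min ratio of per-cell means, the posterior of the draw-wise SD of cell
#' probabilities, and per-turbine monthly ranges for turbines observed in
#' more than one month.
#'
#' @param fit An `entry_fit`.
#' @param safer_threshold,riskier_threshold Classification thresholds on the
#'   probability of direction.
#' @param weighted_groups Use approach-count weighting in the group means.
#' @return A tibble of class `risk_summary` with columns `scope`,
#'   `turbine_id`, `month_key`, `n`, `posterior_mean`, `cri_low`, `cri_high`,
#'   `pd`, `class`.
#' @export
risk_summary <- function(fit, safer_threshold = 0.95, riskier_threshold = 0.05,
                         weighted_groups = FALSE) {
  p <- cell_probabilities(fit)
  avg <- reference_average(fit, p)
  cls <- function(pd) classify_direction(pd, safer_threshold, riskier_threshold)
  qs <- function(m) apply(m, 2, quantile, probs = c(0.025, 0.975))

  overall <- tibble::tibble(
    scope = "overall", turbine_id = NA_character_, month_key = NA_character_,
    n = fit$n_obs, posterior_mean = mean(avg$draws),
    cri_low = as.numeric(quantile(avg$draws, 0.025)),
    cri_high = as.numeric(quantile(avg$draws, 0.975)),
    pd = NA_real_, class = "average"
  )

  gt <- group_means(fit, "turbine", p, weighted_groups)
  gm <- group_means(fit, "month", p, weighted_groups)
  n_turb <- tapply(fit$cells$n, fit$cells$turbine_id, sum)[colnames(gt)]
  n_month <- tapply(fit$cells$n, fit$cells$month_key, sum)[colnames(gm)]

  scope_rows <- function(scope, m, tid, mk, n) {
    q <- qs(m); pd <- probability_of_direction(avg$draws, m)
    tibble::tibble(scope = scope, turbine_id = tid, month_key = mk, n = as.integer(n),
                   posterior_mean = colMeans(m), cri_low = q[1, ], cri_high = q[2, ],
                   pd = as.numeric(pd), class = cls(pd))
  }
  turbines <- scope_rows("turbine", gt, colnames(gt), NA_character_, n_turb)
  months <- scope_rows("month", gm, NA_character_, colnames(gm), n_month)
  cells <- scope_rows("turbine_month", p, fit$cells$turbine_id,
                      fit$cells$month_key, fit$cells$n)

  out <- dplyr::bind_rows(overall, turbines, months, cells)
  attr(out, "headline") <- headline_from(fit, p, turbines, cells, avg)
  attr(out, "thresholds") <- c(safer = safer_threshold, riskier = riskier_threshold)
  class(out) <- c("risk_summary", class(out))
  out
}

headline_from <- function(fit, p, turbines, cells, avg) {
  sd_draws <- apply(p, 1, sd)
  monthly_range <- cells |>
    dplyr::group_by(.data$turbine_id) |>
    dplyr::summarise(n_months = dplyr::n(),
                     min_month = min(.data$posterior_mean),
                     max_month = max(.data$posterior_mean),
                     range = max(.data$posterior_mean) - min(.data$posterior_mean),
                     .groups = "drop") |>
    dplyr::filter(.data$n_months > 1)
  list(
    empirical_rate = avg$empirical,
    overall_mean = mean(avg$draws),
    turbine_ratio = risk_ratio(turbines$posterior_mean),
    cell_ratio = risk_ratio(cells$posterior_mean),
    cell_sd_mean = mean(sd_draws),
    cell_sd_cri = as.numeric(quantile(sd_draws, c(0.025, 0.975))),
    monthly_range = monthly_range,
    n_safer_turbines = sum(turbines$class == "safer"),
    n_riskier_turbines = sum(turbines$class == "riskier"),
    n_safer_cells = sum(cells$class == "safer"),
    n_riskier_cells = sum(cells$class == "riskier")
  )
}

#' @rdname risk_summary
#' @param summary A `risk_summary` tibble.
#' @export
headline_stats <- function(summary) attr(summary, "headline")

#' @method glance risk_summary
#' @export
glance.risk_summary <- function(x, ...) {
  h <- headline_stats(x)
  tibble::tibble(
    empirical_rate = h$empirical_rate, overall_mean = h$overall_mean,
    turbine_ratio = h$turbine_ratio, cell_ratio = h$cell_ratio,
    cell_sd_mean = h$cell_sd_mean,
    n_safer_turbines = h$n_safer_turbines,
    n_riskier_turbines = h$n_riskier_turbines,
    n_safer_cells = h$n_safer_cells, n_riskier_cells = h$n_riskier_cells
  )
}
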
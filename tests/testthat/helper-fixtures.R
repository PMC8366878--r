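# Shared fixtures, built once per test run and cached. The "study" fixtures
# use the generator defaults (the study-scale conditions); the small fixture
# keeps unit tests fast.

`%||%` <- function(x, y) if (is.null(x)) y else x

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_sim_config <- function() {
  sim_config(n_turbines = 12, n_siemens = 5, n_months = 4,
             total_approaches = 400, install_waves = c("1" = 1), seed = 7)
}

small_study <- function() {
  fixture("small_study", simulate_entry_study(small_sim_config(), seed = 7))
}

small_fit <- function() {
  fixture("small_fit", {
    study <- small_study()
    fit_entry_model(study$outcomes,
                    model_config(n_iter = 2000, burn_in = 400, seed = 3))
  })
}

# full study-scale fixture: 110 turbines x 11 months, ~10^4 approaches
big_study <- function() {
  fixture("big_study", simulate_entry_study(sim_config(), seed = 1))
}

big_dataset <- function() {
  fixture("big_dataset", {
    study <- big_study()
    suppressMessages(build_dataset(study$tracks, study$layout$turbines))
  })
}

big_fit <- function() {
  fixture("big_fit", fit_entry_model(big_dataset(), model_config(seed = 1)))
}

# per-cell (n, sum y) table, used for round-trip comparisons
cell_counts <- function(df) {
  df |>
    dplyr::group_by(.data$turbine_id, .data$month_key) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$y), .groups = "drop") |>
    dplyr::arrange(.data$turbine_id, .data$month_key) |>
    as.data.frame()
}

# a one-row turbine table positioned at given ENU metres from a reference
turbine_at <- function(x = 0, y = 0, model = c("siemens", "ge"), id = "T1",
                       ref_lat = 42.7, ref_lon = -106.2) {
  model <- match.arg(model)
  ll <- enu_unproject(x, y, ref_lat, ref_lon)
  turbine_table(tibble::tibble(
    turbine_id = id, model_name = model, lat = ll$lat, lon = ll$lon,
    ground_elevation = 0,
    rotor_diameter = if (model == "siemens") 101 else 77,
    hub_height = 80,
    max_blade_height = if (model == "siemens") 131.5 else 119
  ))
}

# build a track-point tibble from ENU coordinates (1 Hz unless times given)
track_points <- function(x, y, z, track_id = "trk1", unit_id = "U1",
                         unit_xy = c(0, 1000), confidence = 0.95,
                         t0 = 1530000000, times = NULL,
                         ref_lat = 42.7, ref_lon = -106.2) {
  ll <- enu_unproject(x, y, ref_lat, ref_lon)
  ull <- enu_unproject(unit_xy[1], unit_xy[2], ref_lat, ref_lon)
  tibble::tibble(
    track_id = track_id, unit_id = unit_id,
    unit_lat = ull$lat, unit_lon = ull$lon,
    timestamp = times %||% (t0 + seq_along(x) - 1),
    lat = ll$lat, lon = ll$lon, alt_m = z, confidence = confidence
  )
}

# straight 1-Hz pass: from (x0, y0) along direction (dx, dy) at speed v,
# constant altitude
straight_track <- function(x0, y0, dx, dy, v = 15, n = 60, z = 80, ...) {
  len <- sqrt(dx^2 + dy^2)
  ux <- dx / len; uy <- dy / len
  s <- (seq_len(n) - 1) * v
  track_points(x0 + s * ux, y0 + s * uy, rep(z, n), ...)
}

# independent brute-force oracle for cylinder entry times: step the ray at
# `dt` resolution over [0, horizon] and report the first in-cylinder time
brute_force_entry_time <- function(pos, vel, cyl, dt = 0.01, horizon = 60) {
  tt <- seq(0, horizon, by = dt)
  inside <- point_in_cylinder(pos[1] + tt * vel[1], pos[2] + tt * vel[2],
                              pos[3] + tt * vel[3], cyl)
  if (!any(inside)) return(NA_real_)
  tt[which(inside)[1]]
}

# Hand-built entry_fit with known draws, for deterministic summary checks.
# `gamma_draws` is draws x cells; alpha/beta default to zero so the cell
# probabilities are plogis(mu + gamma).
stub_fit <- function(cells, mu_draws, gamma_draws,
                     alpha_draws = NULL, beta_draws = NULL, n_chains = 2) {
  cells <- index_stub_cells(cells)
  S <- length(mu_draws)
  Tn <- max(cells$turbine_index); Mn <- max(cells$month_index)
  structure(list(
    draws = list(
      mu = mu_draws,
      alpha = alpha_draws %||% matrix(0, S, Tn),
      beta = beta_draws %||% matrix(0, S, Mn),
      gamma = gamma_draws,
      sigma2 = matrix(1, S, 3, dimnames = list(NULL, c("turbine", "month", "cell")))
    ),
    chain = rep(seq_len(n_chains), length.out = S),
    n_keep = S %/% n_chains,
    cells = cells,
    turbine_levels = attr(cells, "turbine_levels"),
    month_levels = attr(cells, "month_levels"),
    config = model_config(n_chains = n_chains, n_iter = 4, burn_in = 1, thin = 1),
    accept = NULL,
    n_obs = sum(cells$n), n_entries = sum(cells$k)
  ), class = "entry_fit")
}

index_stub_cells <- function(cells) {
  tl <- sort(unique(cells$turbine_id)); ml <- sort(unique(cells$month_key))
  cells$turbine_index <- match(cells$turbine_id, tl)
  cells$month_index <- match(cells$month_key, ml)
  if (is.null(cells$k)) cells$k <- 0L
  attr(cells, "turbine_levels") <- tl
  attr(cells, "month_levels") <- ml
  cells
}
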
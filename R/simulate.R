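# Synthetic study generator. Emulates the study facility: 110 turbines
# (44 with 101-m rotors, 66 with 77-m rotors, hub 80 m), 11 calendar months
# with staggered monitoring, ~10^4 approaches allocated unevenly over
# observed turbine-month cells, per-cell entry probabilities drawn from the
# model's own logit-scale random-effects structure, and 1-Hz 3D tracks
# constructed to match each approach's entry / no-entry label exactly —
# so the geometry pipeline can be checked against the generator cell for
# cell, and the model against the generating parameters.

#' Configuration of the synthetic study
#'
#' Defaults mirror the study conditions: 110 turbines (44/66 split of the
#' two models), 11 months from May 2018, 10,000 approaches, grand mean at
#' logit(0.295) (the study's overall entry rate), monitoring installed in
#' four waves, and 8.5% of tracks approaching two turbines.
#'
#' @param n_turbines Total turbines; `n_siemens` of them get the 101-m rotor
#'   specification, the rest the 77-m one.
#' @param n_siemens Number of 101-m-rotor turbines.
#' @param n_months Number of consecutive calendar months.
#' @param start_month First month, `"YYYY-MM"`.
#' @param total_approaches Total approaches allocated across observed cells.
#' @param mu Grand mean of the entry probability, logit scale.
#' @param sigma_alpha,sigma_beta,sigma_gamma SDs of the turbine, month and
#'   turbine-month random effects, logit scale.
#' @param install_waves Named fractions of turbines whose monitoring starts
#'   at each month index (staggered installation).
#' @param multi_fraction Fraction of tracks that approach two turbines.
#' @param spacing Turbine grid spacing, m.
#' @param intensity_sdlog Log-normal SD of the per-cell visitation intensity
#'   (eagles do not approach all turbines equally often).
#' @param seed Default seed used by [simulate_entry_study()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_turbines = 110, n_siemens = 44, n_months = 11,
                       start_month = "2018-05", total_approaches = 10000,
                       mu = qlogis(0.295), sigma_alpha = 0.25,
                       sigma_beta = 0.10, sigma_gamma = 0.5,
                       install_waves = c("1" = 0.4, "3" = 0.3, "9" = 0.2, "11" = 0.1),
                       multi_fraction = 0.085, spacing = 600,
                       intensity_sdlog = 1, seed = 1) {
  install_waves <- unlist(install_waves)  # YAML delivers a named list
  if (any(c(sigma_alpha, sigma_beta, sigma_gamma) < 0)) abort("effect SDs must be >= 0")
  if (n_siemens > n_turbines) abort("n_siemens cannot exceed n_turbines")
  if (abs(sum(install_waves) - 1) > 1e-8) abort("install_waves must sum to 1")
  structure(list(n_turbines = n_turbines, n_siemens = n_siemens,
                 n_months = n_months, start_month = start_month,
                 total_approaches = total_approaches, mu = mu,
                 sigma_alpha = sigma_alpha, sigma_beta = sigma_beta,
                 sigma_gamma = sigma_gamma, install_waves = install_waves,
                 multi_fraction = multi_fraction, spacing = spacing,
                 intensity_sdlog = intensity_sdlog, seed = as.integer(seed)),
            class = "sim_config")
}

SIM_REF_LAT <- 42.7
SIM_REF_LON <- -106.2

month_sequence <- function(start_month, n_months) {
  start <- as.Date(paste0(start_month, "-01"))
  format(seq(start, by = "month", length.out = n_months), "%Y-%m")
}

#' Simulate a turbine layout with monitoring units
#'
#' Turbines sit on a jittered square grid (spacing per config, jitter small
#' enough that neighbours stay > 250 m apart); the two turbine models use
#' the study dimensions (101-m rotor / 131.5-m tip and 77-m rotor / 119-m
#' tip, hub 80 m). Monitoring units are placed on a coarser grid so that
#' every turbine lies within 1,000 m of at least one unit. Flat terrain.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `turbines` (a [turbine_table()]) and `units`
#'   (tibble `unit_id`, `lat`, `lon`).
#' @export
simulate_layout <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  n <- config$n_turbines
  nx <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1
  gx <- (idx %% nx) * config$spacing + runif(n, -20, 20)
  gy <- (idx %/% nx) * config$spacing + runif(n, -20, 20)
  gx <- gx - mean(gx); gy <- gy - mean(gy)
  model <- sample(rep(c("siemens_2.3", "ge_1.5"),
                      c(config$n_siemens, n - config$n_siemens)))
  rotor <- ifelse(model == "siemens_2.3", 101, 77)
  maxh <- ifelse(model == "siemens_2.3", 131.5, 119)
  ll <- enu_unproject(gx, gy, SIM_REF_LAT, SIM_REF_LON)
  turbines <- turbine_table(tibble::tibble(
    turbine_id = sprintf("T%03d", seq_len(n)),
    model_name = model, lat = ll$lat, lon = ll$lon,
    ground_elevation = 0, rotor_diameter = rotor,
    hub_height = 80, max_blade_height = maxh
  ))
  # unit grid: one unit per 2x2 block of turbine grid nodes
  ux <- seq(min(gx) + config$spacing / 2, max(gx) + config$spacing / 2,
            by = 2 * config$spacing)
  uy <- seq(min(gy) + config$spacing / 2, max(gy) + config$spacing / 2,
            by = 2 * config$spacing)
  grid <- expand.grid(x = ux, y = uy)
  ull <- enu_unproject(grid$x, grid$y, SIM_REF_LAT, SIM_REF_LON)
  units <- tibble::tibble(unit_id = sprintf("U%02d", seq_len(nrow(grid))),
                          lat = ull$lat, lon = ull$lon, x = grid$x, y = grid$y)
  list(turbines = turbines, units = units,
       xy = tibble::tibble(turbine_id = turbines$turbine_id, x = gx, y = gy))
}

#' Simulate ground-truth effects and cell probabilities
#'
#' Draws the turbine, month and interaction effects from their generative
#' Normal distributions, builds `p_true = plogis(mu + alpha + beta + gamma)`
#' for every turbine-month cell, and marks which cells are observable under
#' the staggered monitoring schedule (each turbine is monitored from its
#' installation wave's month onward).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `mu`, `alpha`, `beta`, `gamma` (T x M), `p_true`
#'   (T x M), `observed` (T x M logical), `turbine_ids`, `month_keys`.
#' @export
simulate_effects <- function(config = sim_config(), seed = config$seed + 1) {
  set.seed(seed)
  Tn <- config$n_turbines; Mn <- config$n_months
  alpha <- rnorm(Tn, 0, config$sigma_alpha)
  beta <- rnorm(Mn, 0, config$sigma_beta)
  gamma <- matrix(rnorm(Tn * Mn, 0, config$sigma_gamma), Tn, Mn)
  p_true <- plogis(config$mu + outer(alpha, beta, "+") + gamma)
  waves <- config$install_waves
  counts <- round(as.numeric(waves) * Tn)
  counts[length(counts)] <- Tn - sum(counts[-length(counts)])
  install_month <- sample(rep(as.integer(names(waves)), counts))
  observed <- outer(install_month, seq_len(Mn), "<=")
  ids <- sprintf("T%03d", seq_len(Tn))
  keys <- month_sequence(config$start_month, Mn)
  dimnames(p_true) <- dimnames(gamma) <- dimnames(observed) <- list(ids, keys)
  list(mu = config$mu, alpha = setNames(alpha, ids), beta = setNames(beta, keys),
       gamma = gamma, p_true = p_true, observed = observed,
       install_month = setNames(install_month, ids),
       turbine_ids = ids, month_keys = keys)
}

#' Simulate per-approach entry outcomes
#'
#' Allocates the configured total number of approaches across observed cells
#' by a multinomial draw over log-normal cell intensities (unequal
#' visitation), then draws each approach's outcome `y ~ Bernoulli(p_true)`.
#'
#' @param truth Output of [simulate_effects()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A tibble `approach_id`, `turbine_id`, `month_key`, `y`, with the
#'   realised per-cell approach-count matrix as attribute `n_matrix`.
#' @export
simulate_outcomes <- function(truth, config = sim_config(), seed = config$seed + 2) {
  set.seed(seed)
  obs <- which(truth$observed)
  if (config$total_approaches < length(obs)) {
    abort("total_approaches must be at least the number of observed cells")
  }
  w <- rlnorm(length(obs), 0, config$intensity_sdlog)
  n_cell <- as.integer(rmultinom(1, config$total_approaches, w))
  t_idx <- (obs - 1) %% nrow(truth$observed) + 1
  m_idx <- (obs - 1) %/% nrow(truth$observed) + 1
  out <- tibble::tibble(
    turbine_id = rep(truth$turbine_ids[t_idx], n_cell),
    month_key = rep(truth$month_keys[m_idx], n_cell),
    p = rep(truth$p_true[obs], n_cell)
  )
  out$y <- rbinom(nrow(out), 1, out$p)
  out <- out |>
    dplyr::arrange(.data$month_key, .data$turbine_id) |>
    dplyr::mutate(approach_id = sprintf("A%05d", dplyr::row_number())) |>
    dplyr::select("approach_id", "turbine_id", "month_key", "y")
  nm <- matrix(0L, nrow(truth$observed), ncol(truth$observed),
               dimnames = dimnames(truth$observed))
  nm[obs] <- n_cell
  attr(out, "n_matrix") <- nm
  out
}

# --- track construction ----------------------------------------------------

# One straight-ish pass at a turbine: a chord of the 360-m circle around the
# turbine with closest-approach distance d chosen from the label's band,
# flown at constant speed with a gentle sinusoidal cross-track wiggle.
# Entering passes cut well inside the rotor-swept zone at blade altitude;
# non-entering passes keep a > 5 m clearance outside it at all altitudes
# while still dipping inside the 150-m approach cylinder.
make_segment <- function(center, zones, label, v, heading = NULL) {
  r_rsz <- zones$rsz$radius
  theta <- heading %||% runif(1, 0, 2 * pi)
  side <- sample(c(-1, 1), 1)
  if (label == 1) {
    d <- runif(1, 0, 0.45 * r_rsz)
    z <- runif(1, zones$rsz$z_min + 8, zones$rsz$z_max - 8)
  } else {
    d <- runif(1, r_rsz + 9, min(140, r_rsz + 80))
    z <- runif(1, max(zones$inner$z_min + 5, 40), min(zones$inner$z_max - 5, 120))
  }
  R0 <- 360
  L <- sqrt(R0^2 - d^2)
  s <- seq(-L, L, by = v)
  phase <- runif(1, 0, 2 * pi)
  off <- side * d + 2.5 * sin(2 * pi * s / 150 + phase)
  ux <- cos(theta); uy <- sin(theta)
  tibble::tibble(
    x = center[1] + s * ux - off * uy,
    y = center[2] + s * uy + off * ux,
    z = z + 1.5 * sin(2 * pi * s / 200 + phase)
  )
}

bridge_points <- function(from, to, v) {
  dist <- sqrt(sum((unlist(to[1, c("x", "y")]) - unlist(from[1, c("x", "y")]))^2 +
                     (to$z[1] - from$z[1])^2))
  nb <- ceiling(dist / v)
  if (nb < 2) return(NULL)
  f <- seq_len(nb - 1) / nb
  tibble::tibble(x = from$x + f * (to$x - from$x),
                 y = from$y + f * (to$y - from$y),
                 z = from$z + f * (to$z - from$z))
}

#' Simulate 1-Hz flight tracks consistent with the outcome labels
#'
#' Builds one 3D track per single-turbine approach and one two-turbine track
#' per paired approach (pairs are formed within a month between
#' grid-adjacent turbines until the configured two-turbine track fraction is
#' met). Entry / no-entry is decided first from the outcome table and each
#' path is constructed to match its label, which makes the generator's
#' per-cell counts an exact oracle for the geometry pipeline. Each track is
#' attributed to its nearest monitoring unit with classification confidence
#' >= 0.9.
#'
#' @param outcomes A [simulate_outcomes()] tibble.
#' @param layout A [simulate_layout()] list.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A track-point tibble in the [read_tracks()] schema, with the
#'   track-to-approach assignment table as attribute `assignments`.
#' @export
simulate_tracks <- function(outcomes, layout, config = sim_config(),
                            seed = config$seed + 3) {
  set.seed(seed)
  turbines <- layout$turbines
  xy <- layout$xy
  zones_by_turbine <- lapply(seq_len(nrow(turbines)), function(t) {
    build_zones(turbines[t, ], center_xy = c(xy$x[t], xy$y[t]))
  })
  names(zones_by_turbine) <- turbines$turbine_id
  centers <- as.matrix(xy[, c("x", "y")])
  rownames(centers) <- xy$turbine_id

  # grid-adjacent turbine pairs (orthogonal neighbours only)
  dmat <- as.matrix(stats::dist(centers))
  adj <- dmat > 0 & dmat <= 1.05 * config$spacing

  pairs <- pair_approaches(outcomes, adj, config)
  tracks <- build_track_plan(outcomes, pairs)

  # deterministic start times spread through each month
  tracks <- tracks |>
    dplyr::group_by(.data$month_key) |>
    dplyr::mutate(t0 = month_start_epoch(.data$month_key[1]) +
                    (dplyr::row_number() - 1) * floor(2.3e6 / dplyr::n())) |>
    dplyr::ungroup()

  pts <- purrr::pmap_dfr(tracks, function(track_id, month_key, t0, segments, ...) {
    v <- runif(1, 8, 20)
    segs <- segments
    first_center <- centers[segs$turbine_id[1], ]
    heading <- NULL
    if (nrow(segs) == 2) {
      second_center <- centers[segs$turbine_id[2], ]
      phi <- atan2(second_center[2] - first_center[2],
                   second_center[1] - first_center[1])
    }
    path <- NULL
    for (i in seq_len(nrow(segs))) {
      ctr <- centers[segs$turbine_id[i], ]
      hd <- if (nrow(segs) == 2) phi + runif(1, -0.5, 0.5) else NULL
      seg <- make_segment(ctr, zones_by_turbine[[segs$turbine_id[i]]],
                          segs$y[i], v, hd)
      if (!is.null(path)) {
        br <- bridge_points(path[nrow(path), ], seg[1, ], v)
        path <- dplyr::bind_rows(path, br)
      }
      path <- dplyr::bind_rows(path, seg)
    }
    path$track_id <- track_id
    path$timestamp <- t0 + seq_len(nrow(path)) - 1
    path$confidence <- round(runif(1, 0.90, 0.995), 3)
    path
  })

  # nearest unit by first point of each track
  units <- layout$units
  first_pts <- pts |> dplyr::group_by(.data$track_id) |> dplyr::slice(1) |> dplyr::ungroup()
  nearest <- purrr::map_int(seq_len(nrow(first_pts)), function(i) {
    which.min((units$x - first_pts$x[i])^2 + (units$y - first_pts$y[i])^2)
  })
  unit_of_track <- setNames(nearest, first_pts$track_id)
  ui <- unit_of_track[pts$track_id]
  ll <- enu_unproject(pts$x, pts$y, SIM_REF_LAT, SIM_REF_LON)
  out <- tibble::tibble(
    track_id = pts$track_id,
    unit_id = units$unit_id[ui],
    unit_lat = units$lat[ui], unit_lon = units$lon[ui],
    timestamp = pts$timestamp,
    lat = ll$lat, lon = ll$lon,
    alt_m = pts$z, confidence = pts$confidence
  )
  assignments <- tracks |>
    dplyr::select("track_id", "segments") |>
    tidyr::unnest("segments")
  attr(out, "assignments") <- assignments
  out
}

month_start_epoch <- function(key) {
  as.numeric(as.POSIXct(paste0(key, "-01 00:00:00"), tz = "UTC"))
}

# Pair approaches within a month between adjacent turbines until the target
# number of two-turbine tracks is reached.
pair_approaches <- function(outcomes, adj, config) {
  target <- round(config$multi_fraction / (1 + config$multi_fraction) * nrow(outcomes))
  if (target == 0) return(NULL)
  pairs <- list()
  for (mk in unique(outcomes$month_key)) {
    if (length(pairs) >= target) break
    rows <- which(outcomes$month_key == mk)
    shuffled <- sample(rows)
    pool <- split(shuffled, outcomes$turbine_id[shuffled])
    for (tid in names(pool)) {
      while (length(pool[[tid]]) > 0 && length(pairs) < target) {
        nbrs <- colnames(adj)[adj[tid, ]]
        nbrs <- nbrs[nbrs %in% names(pool)]
        nbrs <- nbrs[purrr::map_int(nbrs, ~ length(pool[[.x]])) > 0]
        if (!length(nbrs)) break
        nb <- nbrs[1]
        i <- pool[[tid]][1]; j <- pool[[nb]][1]
        pool[[tid]] <- pool[[tid]][-1]
        pool[[nb]] <- pool[[nb]][-1]
        pairs[[length(pairs) + 1]] <- c(i, j)
      }
      if (length(pairs) >= target) break
    }
  }
  if (!length(pairs)) NULL else do.call(rbind, pairs)
}

build_track_plan <- function(outcomes, pairs) {
  paired_rows <- if (is.null(pairs)) integer() else as.integer(pairs)
  singles <- setdiff(seq_len(nrow(outcomes)), paired_rows)
  plan <- list()
  for (i in singles) {
    plan[[length(plan) + 1]] <- tibble::tibble(
      month_key = outcomes$month_key[i],
      segments = list(outcomes[i, c("turbine_id", "month_key", "y")])
    )
  }
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      rows <- pairs[r, ]
      plan[[length(plan) + 1]] <- tibble::tibble(
        month_key = outcomes$month_key[rows[1]],
        segments = list(outcomes[rows, c("turbine_id", "month_key", "y")])
      )
    }
  }
  out <- dplyr::bind_rows(plan) |> dplyr::arrange(.data$month_key)
  out$track_id <- sprintf("K%05d", seq_len(nrow(out)))
  out
}

#' Simulate a complete synthetic study
#'
#' Chains [simulate_layout()], [simulate_effects()], [simulate_outcomes()]
#' and [simulate_tracks()] with seeds derived from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to the config's).
#' @param tracks Set `FALSE` to skip the (comparatively expensive) track
#'   construction when only the outcome table is needed.
#' @return A list with `config`, `layout`, `truth`, `outcomes` and (unless
#'   disabled) `tracks`.
#' @export
simulate_entry_study <- function(config = sim_config(), seed = config$seed,
                                 tracks = TRUE) {
  layout <- simulate_layout(config, seed)
  truth <- simulate_effects(config, seed + 1)
  outcomes <- simulate_outcomes(truth, config, seed + 2)
  out <- list(config = config, layout = layout, truth = truth, outcomes = outcomes)
  if (tracks) out$tracks <- simulate_tracks(outcomes, layout, config, seed + 3)
  out
}
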
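# The informed-curtailment decision rule: curtailment of a turbine is never
# considered unless a confidently classified eagle is inside the outer
# cylinder; it is always ordered inside the inner cylinder; in between it is
# ordered when the extrapolated trajectory reaches the rotor-swept zone
# within the time-to-collision threshold.

#' Evaluate the curtailment rule for one observation
#'
#' Evaluation order: classification confidence, outer-cylinder gate,
#' inner-cylinder trigger, time-to-collision trigger. The trajectory
#' predictor is a constant-velocity linear extrapolation.
#'
#' @param pos Numeric length-3 ENU position (x, y, z), m.
#' @param vel Numeric length-3 velocity, m/s, or `NULL` when unknown (first
#'   point of a track); without a velocity the time-to-collision trigger
#'   cannot fire.
#' @param confidence Eagle-classification confidence in `[0, 1]`.
#' @param zones Zone list from [build_zones()].
#' @param criteria A [curtailment_criteria()].
#' @return `NA_character_` (no curtailment) or one of `"inner_cylinder"`,
#'   `"time_to_collision"`.
#' @export
curtailment_decision <- function(pos, vel, confidence, zones,
                                 criteria = curtailment_criteria()) {
  if (confidence < criteria$confidence_threshold) return(NA_character_)
  if (!point_in_cylinder(pos[1], pos[2], pos[3], zones$outer)) return(NA_character_)
  if (point_in_cylinder(pos[1], pos[2], pos[3], zones$inner)) return("inner_cylinder")
  if (is.null(vel) || all(vel == 0)) return(NA_character_)
  ttc <- ray_cylinder_entry_time(pos, vel, zones$rsz)
  if (!is.na(ttc) && ttc <= criteria$time_to_collision_threshold) {
    return("time_to_collision")
  }
  NA_character_
}

#' Simulate curtailment orders over a track collection
#'
#' Scans each track point by point against every turbine and records the
#' first trigger per (track, turbine) pair; re-triggers are suppressed, so
#' event counts measure how many track-turbine encounters would have ordered
#' curtailment. Point velocities are backward finite differences, so the
#' first point of a track can only fire the inner-cylinder trigger.
#'
#' @param points A track-point tibble (see [read_tracks()]).
#' @param turbines A [turbine_table()].
#' @param criteria A [curtailment_criteria()].
#' @param altitude_ref See [detect_approaches()].
#' @return A list with `events` (tibble `track_id`, `turbine_id`, `trigger`,
#'   `timestamp`) and `counts` (tibble `turbine_id`, `n_events`).
#' @export
simulate_curtailments <- function(points, turbines,
                                  criteria = curtailment_criteria(),
                                  altitude_ref = c("ground", "sea_level")) {
  altitude_ref <- match.arg(altitude_ref)
  pts <- dplyr::arrange(tibble::as_tibble(points), .data$track_id, .data$timestamp)
  fr <- facility_frame(pts, turbines, altitude_ref)
  # backward finite-difference velocities within track
  g <- pts |>
    dplyr::mutate(px = fr$px, py = fr$py) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      dt = .data$timestamp - dplyr::lag(.data$timestamp),
      vx = (.data$px - dplyr::lag(.data$px)) / .data$dt,
      vy = (.data$py - dplyr::lag(.data$py)) / .data$dt,
      vz = (.data$alt_m - dplyr::lag(.data$alt_m)) / .data$dt
    ) |>
    dplyr::ungroup()

  events <- purrr::map_dfr(seq_len(nrow(turbines)), function(t) {
    z <- g$alt_m
    if (altitude_ref == "sea_level") z <- z - turbines$ground_elevation[t]
    zones <- build_zones(turbines[t, ], criteria, center_xy = c(fr$tx[t], fr$ty[t]))
    dx <- g$px - fr$tx[t]; dy <- g$py - fr$ty[t]
    d2 <- dx^2 + dy^2
    conf_ok <- g$confidence >= criteria$confidence_threshold
    in_outer <- conf_ok & point_in_cylinder(g$px, g$py, z, zones$outer)
    if (!any(in_outer)) return(NULL)
    in_inner <- in_outer & point_in_cylinder(g$px, g$py, z, zones$inner)
    # TTC candidates: inside outer, outside inner, velocity known
    cand <- which(in_outer & !in_inner & !is.na(g$vx))
    ttc_hit <- logical(length(d2))
    for (i in cand) {
      tt <- ray_cylinder_entry_time(c(g$px[i], g$py[i], z[i]),
                                    c(g$vx[i], g$vy[i], g$vz[i]), zones$rsz)
      ttc_hit[i] <- !is.na(tt) && tt <= criteria$time_to_collision_threshold
    }
    trig <- dplyr::case_when(in_inner ~ "inner_cylinder",
                             ttc_hit ~ "time_to_collision",
                             TRUE ~ NA_character_)
    hit <- which(!is.na(trig))
    if (!length(hit)) return(NULL)
    tibble::tibble(track_id = g$track_id[hit],
                   turbine_id = turbines$turbine_id[t],
                   trigger = trig[hit],
                   timestamp = g$timestamp[hit]) |>
      dplyr::group_by(.data$track_id, .data$turbine_id) |>
      dplyr::slice_min(.data$timestamp, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  })
  if (is.null(events) || nrow(events) == 0) {
    events <- tibble::tibble(track_id = character(), turbine_id = character(),
                             trigger = character(), timestamp = numeric())
  }
  counts <- events |>
    dplyr::count(.data$turbine_id, name = "n_events") |>
    dplyr::right_join(tibble::tibble(turbine_id = turbines$turbine_id),
                      by = "turbine_id") |>
    dplyr::mutate(n_events = dplyr::coalesce(.data$n_events, 0L)) |>
    dplyr::arrange(.data$turbine_id)
  list(events = dplyr::arrange(events, .data$track_id, .data$turbine_id),
       counts = counts)
}
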
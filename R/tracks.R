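# Flight-track ingestion and reduction to per-approach entry outcomes.
# A track collection is a plain tibble of 1-Hz points:
#   track_id, unit_id, unit_lat, unit_lon, timestamp (epoch s, UTC),
#   lat, lon, alt_m (above ground), confidence
# so everything composes with dplyr.

TRACK_COLS <- c("track_id", "unit_id", "unit_lat", "unit_lon",
                "timestamp", "lat", "lon", "alt_m", "confidence")

month_key <- function(timestamp) {
  format(as.POSIXct(timestamp, origin = "1970-01-01", tz = "UTC"), "%Y-%m")
}

#' Read flight tracks from CSV
#'
#' Expects columns `track_id,unit_id,unit_lat,unit_lon,timestamp,lat,lon,`
#' `alt_m,confidence`. Timestamps may be numeric epoch seconds or ISO-8601
#' strings (parsed as UTC). Rows are grouped by `track_id` and sorted by time;
#' tracks with fewer than two points are dropped (with a message); altitudes
#' slightly below zero (sensor noise, down to -10 m) are clipped to 0 with a
#' warning, anything lower is an error.
#'
#' @param path Path to the track CSV.
#' @return A tibble of track points with attribute `n_rejected` (number of
#'   tracks dropped for having < 2 points).
#' @export
read_tracks <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(TRACK_COLS, names(raw))
  if (length(missing_cols)) {
    abort(paste0("track CSV is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(raw$timestamp)) {
    x <- as.character(raw$timestamp)
    ts <- as.numeric(strptime(x, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
    alt <- as.numeric(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
    ts[is.na(ts)] <- alt[is.na(ts)]
    bad <- which(is.na(ts) & !is.na(x))
    if (length(bad)) {
      abort(paste0("unparseable timestamp at data line(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    raw$timestamp <- ts
  }
  validate_tracks(raw)
}

#' @rdname read_tracks
#' @param points A data frame already holding the track-point columns.
#' @export
validate_tracks <- function(points) {
  pts <- tibble::as_tibble(points)[, TRACK_COLS]
  pts$track_id <- as.character(pts$track_id)
  pts$unit_id <- as.character(pts$unit_id)
  if (any(pts$alt_m < -10)) abort("altitude below -10 m: not plausible sensor noise")
  n_clip <- sum(pts$alt_m < 0)
  if (n_clip > 0) {
    warn(paste0("clipped ", n_clip, " negative altitude(s) to 0"))
    pts$alt_m[pts$alt_m < 0] <- 0
  }
  pts <- dplyr::arrange(pts, .data$track_id, .data$timestamp)
  pts <- dplyr::distinct(pts, .data$track_id, .data$timestamp, .keep_all = TRUE)
  sizes <- dplyr::count(pts, .data$track_id)
  short <- sizes$track_id[sizes$n < 2]
  if (length(short)) {
    inform(paste0("dropped ", length(short), " track(s) with fewer than 2 points"))
    pts <- dplyr::filter(pts, !.data$track_id %in% short)
  }
  attr(pts, "n_rejected") <- length(short)
  pts
}

unit_reference <- function(points) {
  list(lat = mean(points$unit_lat), lon = mean(points$unit_lon))
}

#' Resolve simultaneous tracking of one eagle by multiple units
#'
#' When two units track the same bird at the same time, the data from the
#' unit nearest to the eagle are kept. Two tracks from different units are
#' treated as the same bird when their time ranges overlap and their matched
#' positions (timestamps binned at `link_time`) lie within `link_distance` of
#' each other on average. Within the overlap, each time bin keeps the point
#' whose recording unit is nearer in 3D line of sight; the surviving points
#' are merged into one track. Ambiguous multi-way overlaps are resolved
#' pairwise in (unit id, track id) order, so the result is deterministic, and
#' the operation is idempotent.
#'
#' @param points A track-point tibble (see [read_tracks()]).
#' @param link_distance Maximum mean 3D separation, m, for two tracks to be
#'   the same bird.
#' @param link_time Timestamp matching bin width, s.
#' @return A track-point tibble with duplicated observations removed.
#' @export
deduplicate_simultaneous <- function(points, link_distance = 50, link_time = 1) {
  pts <- tibble::as_tibble(points)
  if (nrow(pts) == 0) return(pts)
  ref <- unit_reference(pts)
  repeat {
    merged <- dedup_one_pass(pts, ref, link_distance, link_time)
    if (is.null(merged)) break
    pts <- merged
  }
  dplyr::arrange(pts, .data$track_id, .data$timestamp)
}

# One merge per pass; returns NULL when no pair qualifies. Candidate pairs
# come from a sweep over time-sorted tracks, so the cost is proportional to
# the number of genuinely co-occurring tracks, not to all pairs.
dedup_one_pass <- function(pts, ref, link_distance, link_time) {
  info <- pts |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      unit_id = dplyr::first(.data$unit_id),
      t0 = min(.data$timestamp), t1 = max(.data$timestamp),
      .groups = "drop"
    )
  if (nrow(info) < 2) return(NULL)
  cand <- overlapping_pairs(info)
  if (is.null(cand)) return(NULL)
  for (r in seq_len(nrow(cand))) {
    a <- info[cand$i[r], ]; b <- info[cand$j[r], ]
    pa <- dplyr::filter(pts, .data$track_id == a$track_id)
    pb <- dplyr::filter(pts, .data$track_id == b$track_id)
    m <- match_points(pa, pb, ref, link_time)
    if (is.null(m) || mean(m$sep) > link_distance) next
    # same eagle: within matched bins keep the nearer unit's point
    drop_a <- m$ia[m$dist_a > m$dist_b]
    drop_b <- m$ib[m$dist_b >= m$dist_a]
    keep <- dplyr::bind_rows(
      if (length(drop_a)) pa[-drop_a, ] else pa,
      if (length(drop_b)) pb[-drop_b, ] else pb
    )
    keep$track_id <- a$track_id
    rest <- dplyr::filter(pts, !.data$track_id %in% c(a$track_id, b$track_id))
    return(dplyr::bind_rows(rest, keep))
  }
  NULL
}

# Cross-unit track pairs whose time ranges overlap, in deterministic
# (unit id, track id) order. Sweep over tracks sorted by start time.
overlapping_pairs <- function(info) {
  o <- order(info$t0)
  t0 <- info$t0[o]; t1 <- info$t1[o]
  ii <- integer(); jj <- integer()
  active <- integer()  # indices (into o) of tracks whose window may still overlap
  for (k in seq_along(o)) {
    active <- active[t1[active] >= t0[k]]
    for (a in active) {
      if (info$unit_id[o[a]] != info$unit_id[o[k]]) {
        ii <- c(ii, o[a]); jj <- c(jj, o[k])
      }
    }
    active <- c(active, k)
  }
  if (!length(ii)) return(NULL)
  key_a <- paste(info$unit_id[ii], info$track_id[ii])
  key_b <- paste(info$unit_id[jj], info$track_id[jj])
  swap <- key_b < key_a
  tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  ord <- order(paste(info$unit_id[ii], info$track_id[ii]),
               paste(info$unit_id[jj], info$track_id[jj]))
  data.frame(i = ii[ord], j = jj[ord])
}

# Match two point sets by link_time bins; returns per-match indices, the 3D
# separation between the birds' recorded positions, and each unit's
# line-of-sight distance to its own recorded position.
match_points <- function(pa, pb, ref, link_time) {
  bin_a <- round(pa$timestamp / link_time)
  bin_b <- round(pb$timestamp / link_time)
  common <- intersect(bin_a, bin_b)
  if (!length(common)) return(NULL)
  ia <- match(common, bin_a)
  ib <- match(common, bin_b)
  ea <- enu_project(pa$lat[ia], pa$lon[ia], ref$lat, ref$lon)
  eb <- enu_project(pb$lat[ib], pb$lon[ib], ref$lat, ref$lon)
  ua <- enu_project(pa$unit_lat[ia], pa$unit_lon[ia], ref$lat, ref$lon)
  ub <- enu_project(pb$unit_lat[ib], pb$unit_lon[ib], ref$lat, ref$lon)
  list(
    ia = ia, ib = ib,
    sep = sqrt((ea$x - eb$x)^2 + (ea$y - eb$y)^2 + (pa$alt_m[ia] - pb$alt_m[ib])^2),
    dist_a = sqrt((ea$x - ua$x)^2 + (ea$y - ua$y)^2 + pa$alt_m[ia]^2),
    dist_b = sqrt((eb$x - ub$x)^2 + (eb$y - ub$y)^2 + pb$alt_m[ib]^2)
  )
}

# Shared geometry prep: project turbines and points into facility ENU.
facility_frame <- function(points, turbines, altitude_ref = "ground") {
  ref_lat <- mean(turbines$lat); ref_lon <- mean(turbines$lon)
  txy <- enu_project(turbines$lat, turbines$lon, ref_lat, ref_lon)
  pxy <- enu_project(points$lat, points$lon, ref_lat, ref_lon)
  list(ref_lat = ref_lat, ref_lon = ref_lon,
       tx = txy$x, ty = txy$y, px = pxy$x, py = pxy$y,
       altitude_ref = altitude_ref)
}

#' Detect approaches of tracks to turbines
#'
#' An approach is an occasion on which a track comes within the
#' approach/inner-curtailment volume of a turbine (by default horizontal
#' distance <= `inner_radius` with altitude in the hub-centred band; set
#' `approach_mode = "horizontal_only"` in the criteria for a pure horizontal
#' rule). Tracks whose maximum point confidence falls below the
#' classification threshold are ignored. A track near k turbines yields k
#' approach events; entry is assessed against each approached turbine's
#' rotor-swept zone over the whole track.
#'
#' @param points A track-point tibble.
#' @param turbines A [turbine_table()].
#' @param criteria A [curtailment_criteria()].
#' @param altitude_ref `"ground"` (altitudes are above local ground; the
#'   synthetic generator's convention) or `"sea_level"` (per-turbine ground
#'   elevation is subtracted before comparing against zone altitude bands).
#' @return A tibble with one row per (track, turbine) approach: `track_id`,
#'   `turbine_id`, `month_key` (calendar month of the first in-volume point),
#'   `min_horizontal_distance`, `entered` (0/1), `t_first_inside_rsz`
#'   (seconds from track start, `NA` when `entered = 0`).
#' @export
detect_approaches <- function(points, turbines, criteria = curtailment_criteria(),
                              altitude_ref = c("ground", "sea_level")) {
  altitude_ref <- match.arg(altitude_ref)
  if (nrow(turbines) == 0) abort("empty turbine table")
  pts <- tibble::as_tibble(points)
  gate <- pts |>
    dplyr::group_by(.data$track_id) |>
    dplyr::filter(max(.data$confidence) >= criteria$confidence_threshold) |>
    dplyr::ungroup()
  if (nrow(gate) == 0) return(empty_approaches())
  fr <- facility_frame(gate, turbines, altitude_ref)
  track_start <- gate |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(t0 = min(.data$timestamp), .groups = "drop")

  events <- purrr::map_dfr(seq_len(nrow(turbines)), function(t) {
    z <- gate$alt_m
    if (altitude_ref == "sea_level") z <- z - turbines$ground_elevation[t]
    zones <- build_zones(turbines[t, ], criteria, center_xy = c(fr$tx[t], fr$ty[t]))
    d2 <- (fr$px - fr$tx[t])^2 + (fr$py - fr$ty[t])^2
    in_approach <- if (criteria$approach_mode == "horizontal_only") {
      d2 <= criteria$inner_radius^2
    } else {
      d2 <= zones$inner$radius^2 & z >= zones$inner$z_min & z <= zones$inner$z_max
    }
    if (!any(in_approach)) return(NULL)
    in_rsz <- d2 <= zones$rsz$radius^2 & z >= zones$rsz$z_min & z <= zones$rsz$z_max
    app_tracks <- unique(gate$track_id[in_approach])
    on_track <- gate$track_id %in% app_tracks
    tibble::tibble(
      track_id = gate$track_id[on_track],
      turbine_id = turbines$turbine_id[t],
      timestamp = gate$timestamp[on_track],
      dist = sqrt(d2[on_track]),
      in_approach = in_approach[on_track],
      in_rsz = in_rsz[on_track]
    ) |>
      dplyr::group_by(.data$track_id, .data$turbine_id) |>
      dplyr::summarise(
        month_key = month_key(min(.data$timestamp[.data$in_approach])),
        min_horizontal_distance = min(.data$dist),
        entered = as.integer(any(.data$in_rsz)),
        t_rsz = if (any(.data$in_rsz)) min(.data$timestamp[.data$in_rsz]) else NA_real_,
        .groups = "drop"
      )
  })
  if (is.null(events) || nrow(events) == 0) return(empty_approaches())
  events |>
    dplyr::left_join(track_start, by = "track_id") |>
    dplyr::mutate(t_first_inside_rsz = .data$t_rsz - .data$t0) |>
    dplyr::select("track_id", "turbine_id", "month_key",
                  "min_horizontal_distance", "entered", "t_first_inside_rsz") |>
    dplyr::arrange(.data$track_id, .data$turbine_id)
}

empty_approaches <- function() {
  tibble::tibble(track_id = character(), turbine_id = character(),
                 month_key = character(), min_horizontal_distance = numeric(),
                 entered = integer(), t_first_inside_rsz = numeric())
}

#' Build the binary entry dataset from flight tracks
#'
#' Reduces a track collection to the model's observation unit: one row per
#' approach (track x turbine), with `y = 1` if any point of the track lay
#' inside that turbine's rotor-swept zone. Attributes carry the
#' turbine/month index maps and summary counts (number of gated tracks,
#' approaches, entries, and the fraction of tracks approaching exactly one
#' turbine).
#'
#' @inheritParams detect_approaches
#' @return A tibble with columns `track_id`, `turbine_id`, `month_key`, `y`,
#'   `turbine_index`, `month_index`; attributes `turbine_levels`,
#'   `month_levels`, `summary`.
#' @export
build_dataset <- function(points, turbines, criteria = curtailment_criteria(),
                          altitude_ref = "ground") {
  ev <- detect_approaches(points, turbines, criteria, altitude_ref)
  if (nrow(ev) == 0) {
    abort("no approaches detected; supply more tracks or check turbine coordinates")
  }
  out <- ev |>
    dplyr::transmute(.data$track_id, .data$turbine_id, .data$month_key,
                     y = .data$entered)
  out <- index_entry_data(out)
  per_track <- dplyr::count(out, .data$track_id)
  attr(out, "summary") <- list(
    n_tracks = nrow(per_track),
    n_approaches = nrow(out),
    n_entries = sum(out$y),
    entry_rate = sum(out$y) / nrow(out),
    frac_single_turbine = mean(per_track$n == 1),
    frac_multi_turbine = mean(per_track$n >= 2)
  )
  out
}

index_entry_data <- function(df) {
  turbine_levels <- sort(unique(df$turbine_id))
  month_levels <- sort(unique(df$month_key))
  df$turbine_index <- match(df$turbine_id, turbine_levels)
  df$month_index <- match(df$month_key, month_levels)
  attr(df, "turbine_levels") <- turbine_levels
  attr(df, "month_levels") <- month_levels
  df
}

#' Write / read an entry dataset as CSV
#'
#' The on-disk schema is `turbine_id,month_key,y` (plus `track_id` when
#' present).
#'
#' @param data An entry-data tibble from [build_dataset()].
#' @param path File path.
#' @return `read_entry_data()` returns an indexed entry-data tibble.
#' @export
write_entry_data <- function(data, path) {
  keep <- intersect(c("track_id", "turbine_id", "month_key", "y"), names(data))
  readr::write_csv(data[, keep], path)
  invisible(path)
}

#' @rdname write_entry_data
#' @export
read_entry_data <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(turbine_id = "c", month_key = "c"))
  missing_cols <- setdiff(c("turbine_id", "month_key", "y"), names(df))
  if (length(missing_cols)) {
    abort(paste0("entry CSV is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  index_entry_data(tibble::as_tibble(df))
}
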
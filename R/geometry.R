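# Cylinder geometry for rotor-swept zones and curtailment volumes.
# All working coordinates are local east-north-up (ENU) metres about a
# facility reference point; altitudes are metres above local ground.

EARTH_RADIUS_M <- 6371000

#' Project geographic coordinates to a local tangent plane
#'
#' Equirectangular east-north projection about a reference point. Over the
#' few-kilometre extent of a wind facility the distortion of this projection
#' is negligible (sub-metre), which is all the cylinder geometry requires.
#'
#' @param lat,lon Coordinates to project, decimal degrees.
#' @param ref_lat,ref_lon Reference point (projection origin), decimal degrees.
#' @return A tibble with columns `x` (m east) and `y` (m north).
#' @seealso [enu_unproject()] for the inverse.
#' @examples
#' enu_project(42.001, -106, ref_lat = 42, ref_lon = -106)
#' @export
enu_project <- function(lat, lon, ref_lat, ref_lon) {
  if (!all(is.finite(lat), is.finite(lon), is.finite(ref_lat), is.finite(ref_lon))) {
    abort("coordinates must be finite")
  }
  if (any(abs(lat) > 90) || any(abs(ref_lat) > 90)) abort("latitude out of [-90, 90]")
  if (any(abs(lon) > 180) || any(abs(ref_lon) > 180)) abort("longitude out of [-180, 180]")
  deg <- pi / 180
  tibble::tibble(
    x = EARTH_RADIUS_M * (lon - ref_lon) * deg * cos(ref_lat * deg),
    y = EARTH_RADIUS_M * (lat - ref_lat) * deg
  )
}

#' Inverse of [enu_project()]
#'
#' @param x,y Local ENU coordinates, metres.
#' @inheritParams enu_project
#' @return A tibble with columns `lat` and `lon`, decimal degrees.
#' @export
enu_unproject <- function(x, y, ref_lat, ref_lon) {
  deg <- pi / 180
  tibble::tibble(
    lat = ref_lat + y / EARTH_RADIUS_M / deg,
    lon = ref_lon + x / (EARTH_RADIUS_M * cos(ref_lat * deg)) / deg
  )
}

#' Minimum blade height of a turbine
#'
#' The lowest point swept by the blades: the maximum blade height minus twice
#' the blade length, where blade length is half the rotor diameter.
#'
#' @param max_blade_height Maximum blade-tip height above ground, m.
#' @param rotor_diameter Rotor diameter, m.
#' @return Minimum blade height above ground, m.
#' @examples
#' min_blade_height(131.5, 101) # 30.5 for a 101-m rotor topping out at 131.5 m
#' @export
min_blade_height <- function(max_blade_height, rotor_diameter) {
  out <- max_blade_height - rotor_diameter
  if (any(out < 0)) {
    abort("max_blade_height - rotor_diameter < 0: blades would sweep below ground")
  }
  out
}

#' Curtailment criteria
#'
#' The facility-wide parameters of the informed-curtailment rule: two virtual
#' cylinders centred on each turbine hub, a time-to-collision threshold used
#' between them, and the minimum classification confidence required before a
#' detection can trigger curtailment. Defaults are the post-August-2018
#' operating values at the study facility (inner/outer radii 150/350 m,
#' heights 200/400 m, 10 s time to collision, 90% confidence).
#'
#' @param inner_radius,outer_radius Cylinder radii, m.
#' @param inner_height,outer_height Full cylinder heights centred on the hub, m.
#' @param time_to_collision_threshold Seconds; trajectories predicted to enter
#'   the rotor-swept zone within this time trigger curtailment.
#' @param confidence_threshold Minimum eagle-classification confidence in
#'   `[0, 1]`.
#' @param rsz_buffer Extra radius added to the rotor-swept-zone cylinder, m.
#' @param approach_mode How "within 150 m" is evaluated when detecting
#'   approaches: `"inner_cylinder"` (horizontal distance and altitude band)
#'   or `"horizontal_only"`.
#' @return A list of class `curtailment_criteria`.
#' @export
curtailment_criteria <- function(inner_radius = 150, outer_radius = 350,
                                 inner_height = 200, outer_height = 400,
                                 time_to_collision_threshold = 10,
                                 confidence_threshold = 0.90,
                                 rsz_buffer = 0,
                                 approach_mode = c("inner_cylinder", "horizontal_only")) {
  approach_mode <- match.arg(approach_mode)
  vals <- c(inner_radius, outer_radius, inner_height, outer_height,
            time_to_collision_threshold, confidence_threshold)
  if (any(!is.finite(vals)) || any(vals <= 0)) abort("criteria must be positive and finite")
  if (outer_radius <= inner_radius) abort("outer_radius must exceed inner_radius")
  if (outer_height <= inner_height) abort("outer_height must exceed inner_height")
  if (rsz_buffer < 0) abort("rsz_buffer must be >= 0")
  structure(
    list(
      inner_radius = inner_radius, outer_radius = outer_radius,
      inner_height = inner_height, outer_height = outer_height,
      time_to_collision_threshold = time_to_collision_threshold,
      confidence_threshold = confidence_threshold,
      rsz_buffer = rsz_buffer, approach_mode = approach_mode
    ),
    class = "curtailment_criteria"
  )
}

#' Validate a turbine table
#'
#' Checks the physical description of each turbine: positive rotor diameter,
#' hub above blade-tip reach of the ground, and consistency of the maximum
#' blade height with hub height + rotor radius (warned about, not fixed, when
#' violated by more than `tip_tolerance`).
#'
#' @param turbines Data frame with columns `turbine_id`, `model_name`, `lat`,
#'   `lon`, `rotor_diameter`, `hub_height`, `max_blade_height` and optionally
#'   `ground_elevation` (m above sea level, default 0).
#' @param tip_tolerance Permitted discrepancy, m, between `max_blade_height`
#'   and `hub_height + rotor_diameter / 2`. Registered tip heights come from
#'   obstruction databases and routinely differ from the nominal geometry by
#'   up to a metre, so the default is 1.5 m.
#' @return The validated table as a tibble, with `ground_elevation` filled in.
#' @export
turbine_table <- function(turbines, tip_tolerance = 1.5) {
  req <- c("turbine_id", "model_name", "lat", "lon",
           "rotor_diameter", "hub_height", "max_blade_height")
  missing_cols <- setdiff(req, names(turbines))
  if (length(missing_cols)) {
    abort(paste0("turbine table is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(turbines)
  if (!"ground_elevation" %in% names(out)) out$ground_elevation <- 0
  out$ground_elevation[is.na(out$ground_elevation)] <- 0
  if (any(out$rotor_diameter <= 0)) abort("rotor_diameter must be positive")
  if (any(out$hub_height <= out$rotor_diameter / 2)) {
    abort("hub_height must exceed rotor_diameter / 2")
  }
  mismatch <- abs(out$max_blade_height - (out$hub_height + out$rotor_diameter / 2)) >
    tip_tolerance
  if (any(mismatch)) {
    warn(paste0(
      sum(mismatch), " turbine(s) have max_blade_height differing from ",
      "hub_height + rotor_diameter/2 by more than ", tip_tolerance, " m"
    ))
  }
  if (anyDuplicated(out$turbine_id)) abort("duplicate turbine_id")
  out$turbine_id <- as.character(out$turbine_id)
  out
}

#' Read a turbine table from CSV
#'
#' Expects the header `turbine_id,model_name,lat,lon,ground_elevation_m,`
#' `rotor_diameter_m,hub_height_m,max_blade_height_m`.
#'
#' @param path Path to the CSV file.
#' @return A validated turbine tibble (see [turbine_table()]).
#' @export
read_turbines <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  ren <- c(ground_elevation = "ground_elevation_m", rotor_diameter = "rotor_diameter_m",
           hub_height = "hub_height_m", max_blade_height = "max_blade_height_m")
  for (new in names(ren)) {
    if (ren[[new]] %in% names(raw)) names(raw)[names(raw) == ren[[new]]] <- new
  }
  turbine_table(raw)
}

new_cylinder <- function(cx, cy, radius, z_min, z_max) {
  if (radius <= 0 || z_max <= z_min || z_min < 0) abort("invalid cylinder dimensions")
  structure(list(cx = cx, cy = cy, radius = radius, z_min = z_min, z_max = z_max),
            class = "zone_cylinder")
}

#' Build the rotor-swept-zone and curtailment cylinders for one turbine
#'
#' The rotor-swept zone is a cylinder of radius rotor radius (+ optional
#' buffer) spanning the minimum to maximum blade height. The inner and outer
#' curtailment cylinders take their radii from the criteria and span
#' hub height +/- half the criterion height, clipped at ground level.
#'
#' @param turbine One row of a [turbine_table()] (data frame or list).
#' @param criteria A [curtailment_criteria()] object.
#' @param center_xy Numeric length-2 ENU centre of the turbine, m; defaults to
#'   the origin.
#' @return A list with `zone_cylinder` elements `rsz`, `inner`, `outer`.
#' @export
build_zones <- function(turbine, criteria = curtailment_criteria(),
                        center_xy = c(0, 0)) {
  rd <- turbine$rotor_diameter
  hub <- turbine$hub_height
  zmax <- turbine$max_blade_height
  zmin <- min_blade_height(zmax, rd)
  list(
    rsz = new_cylinder(center_xy[1], center_xy[2],
                       rd / 2 + criteria$rsz_buffer, zmin, zmax),
    inner = new_cylinder(center_xy[1], center_xy[2], criteria$inner_radius,
                         max(0, hub - criteria$inner_height / 2),
                         hub + criteria$inner_height / 2),
    outer = new_cylinder(center_xy[1], center_xy[2], criteria$outer_radius,
                         max(0, hub - criteria$outer_height / 2),
                         hub + criteria$outer_height / 2)
  )
}

#' Test points for membership in a cylinder
#'
#' Closed boundaries: a point exactly on the wall or on the top/bottom face
#' is inside.
#'
#' @param x,y,z Point coordinates (vectors recycle), ENU metres.
#' @param cyl A `zone_cylinder` from [build_zones()].
#' @return Logical vector.
#' @export
point_in_cylinder <- function(x, y, z, cyl) {
  (x - cyl$cx)^2 + (y - cyl$cy)^2 <= cyl$radius^2 &
    z >= cyl$z_min & z <= cyl$z_max
}

#' Time for a straight-line trajectory to enter a cylinder
#'
#' Smallest t >= 0 at which the constant-velocity extrapolation
#' `pos + t * vel` lies inside the cylinder, found by solving the horizontal
#' circle-crossing quadratic and intersecting with the altitude band. This is
#' the time-to-collision primitive of the curtailment rule.
#'
#' @param pos Numeric length-3 position (x, y, z), m.
#' @param vel Numeric length-3 velocity, m/s; must not be all zero.
#' @param cyl A `zone_cylinder`.
#' @return Entry time in seconds; 0 if `pos` is already inside; `NA_real_` if
#'   the trajectory never enters.
#' @export
ray_cylinder_entry_time <- function(pos, vel, cyl) {
  if (all(vel == 0)) abort("velocity must not be all zero")
  px <- pos[1] - cyl$cx; py <- pos[2] - cyl$cy; z <- pos[3]
  vx <- vel[1]; vy <- vel[2]; vz <- vel[3]

  # horizontal interval [h1, h2] during which the ray is inside the circle
  a <- vx^2 + vy^2
  if (a == 0) {
    if (px^2 + py^2 > cyl$radius^2) return(NA_real_)
    h1 <- -Inf; h2 <- Inf
  } else {
    b <- 2 * (px * vx + py * vy)
    cc <- px^2 + py^2 - cyl$radius^2
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NA_real_)
    sq <- sqrt(disc)
    h1 <- (-b - sq) / (2 * a); h2 <- (-b + sq) / (2 * a)
  }

  # vertical interval [v1, v2] inside the altitude band
  if (vz == 0) {
    if (z < cyl$z_min || z > cyl$z_max) return(NA_real_)
    v1 <- -Inf; v2 <- Inf
  } else {
    v1 <- (cyl$z_min - z) / vz; v2 <- (cyl$z_max - z) / vz
    if (v1 > v2) { tmp <- v1; v1 <- v2; v2 <- tmp }
  }

  lo <- max(h1, v1, 0); hi <- min(h2, v2)
  if (lo > hi) return(NA_real_)
  lo
}
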
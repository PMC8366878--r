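write_track_csv <- function(pts, path = tempfile(fileext = ".csv")) {
  readr::write_csv(pts, path)
  path
}

test_that("track CSVs are read, sorted, and short tracks rejected", {
  one <- straight_track(-300, 0, 1, 0, n = 2)
  p <- read_tracks(write_track_csv(one))
  expect_equal(nrow(p), 2)
  expect_equal(unique(p$track_id), "trk1")

  # rows out of time order come back sorted
  shuffled <- one[c(2, 1), ]
  p2 <- read_tracks(write_track_csv(shuffled))
  expect_equal(p2$timestamp, sort(one$timestamp))

  # three tracks, one with a single point: two survive, one rejection logged
  multi <- dplyr::bind_rows(
    straight_track(-300, 0, 1, 0, n = 5, track_id = "a"),
    straight_track(-300, 50, 1, 0, n = 5, track_id = "b"),
    straight_track(-300, 90, 1, 0, n = 1, track_id = "c")
  )
  expect_message(p3 <- read_tracks(write_track_csv(multi)), "1 track")
  expect_setequal(unique(p3$track_id), c("a", "b"))
  expect_equal(attr(p3, "n_rejected"), 1)
})

test_that("track reading validates columns, timestamps and altitudes", {
  pts <- straight_track(-300, 0, 1, 0, n = 3)
  expect_error(read_tracks(write_track_csv(pts[, -5])), "timestamp")

  iso <- pts
  iso$timestamp <- format(as.POSIXct(iso$timestamp, origin = "1970-01-01",
                                     tz = "UTC"), "%Y-%m-%dT%H:%M:%S")
  p <- read_tracks(write_track_csv(iso))
  expect_equal(p$timestamp, pts$timestamp)

  bad_ts <- iso
  bad_ts$timestamp[2] <- "not-a-time"
  expect_error(read_tracks(write_track_csv(bad_ts)), "unparseable timestamp")

  noisy <- pts
  noisy$alt_m[1] <- -3
  expect_warning(pn <- validate_tracks(noisy), "clipped")
  expect_equal(pn$alt_m[1], 0)
  deep <- pts; deep$alt_m[1] <- -50
  expect_error(validate_tracks(deep), "-10")
})

test_that("simultaneous tracking keeps the nearest unit's data", {
  # the same pass recorded by a near unit (100 m) and a far unit (900 m)
  path_x <- seq(-100, 100, by = 15)
  near <- track_points(path_x, rep(0, length(path_x)), rep(80, length(path_x)),
                       track_id = "n", unit_id = "U1", unit_xy = c(0, 100))
  far <- track_points(path_x, rep(0, length(path_x)), rep(80, length(path_x)),
                      track_id = "f", unit_id = "U2", unit_xy = c(0, 900))
  both <- dplyr::bind_rows(near, far)
  merged <- deduplicate_simultaneous(both)
  expect_equal(length(unique(merged$track_id)), 1)
  expect_equal(nrow(merged), length(path_x))
  expect_true(all(merged$unit_id == "U1"))
  # idempotent
  expect_equal(deduplicate_simultaneous(merged), merged)
})

test_that("distinct birds and single-unit input pass through deduplication", {
  a <- straight_track(-300, 0, 1, 0, n = 10, track_id = "a", unit_id = "U1")
  b <- straight_track(-300, 500, 1, 0, n = 10, track_id = "b", unit_id = "U2",
                      unit_xy = c(0, 1500))
  out <- deduplicate_simultaneous(dplyr::bind_rows(a, b))
  expect_setequal(unique(out$track_id), c("a", "b"))
  single <- dplyr::bind_rows(a, straight_track(-300, 10, 1, 0, n = 10,
                                               track_id = "c", unit_id = "U1"))
  expect_equal(nrow(deduplicate_simultaneous(single)), nrow(single))
})

test_that("approach detection applies the 150-m rule and whole-track entry", {
  trb <- turbine_at(0, 0, "siemens")

  # straight through the hub at blade height: one approach, entered
  thru <- straight_track(-400, 0, 1, 0, v = 15, n = 55, z = 80)
  ev <- detect_approaches(thru, trb)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$entered, 1L)
  expect_false(is.na(ev$t_first_inside_rsz))
  expect_equal(ev$month_key, month_key(thru$timestamp[1]))

  # holding 160 m off: no approach
  off <- straight_track(-400, 160, 1, 0, v = 15, n = 55, z = 80)
  expect_equal(nrow(detect_approaches(off, trb)), 0)

  # closest approach 100 m at blade height: approach without entry
  miss <- straight_track(-400, 100, 1, 0, v = 15, n = 55, z = 80)
  ev2 <- detect_approaches(miss, trb)
  expect_equal(ev2$entered, 0L)
  expect_true(is.na(ev2$t_first_inside_rsz))
  expect_lte(ev2$min_horizontal_distance, 150)
  expect_gt(ev2$min_horizontal_distance, 99)

  # low confidence never yields events
  lowc <- straight_track(-400, 0, 1, 0, v = 15, n = 55, z = 80, confidence = 0.85)
  expect_equal(nrow(detect_approaches(lowc, trb)), 0)

  # altitude outside the inner band is not an approach under the default
  # rule but is under horizontal_only
  high <- straight_track(-400, 0, 1, 0, v = 15, n = 55, z = 300)
  expect_equal(nrow(detect_approaches(high, trb)), 0)
  expect_equal(nrow(detect_approaches(
    high, trb, curtailment_criteria(approach_mode = "horizontal_only"))), 1)
})

test_that("a track passing between two close turbines yields two approaches", {
  trbs <- dplyr::bind_rows(turbine_at(0, 110, "siemens", id = "A"),
                           turbine_at(0, -110, "ge", id = "B"))
  mid <- straight_track(-400, 0, 1, 0, v = 15, n = 55, z = 80)
  ev <- detect_approaches(mid, trbs)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$turbine_id, c("A", "B"))
  dat <- build_dataset(mid, trbs)
  expect_equal(nrow(dat), 2)
  expect_equal(attr(dat, "summary")$frac_multi_turbine, 1)
})

test_that("dataset construction counts approaches and entries correctly", {
  trb <- turbine_at(0, 0, "siemens")
  tracks <- dplyr::bind_rows(purrr::map(1:10, function(i) {
    # 3 entering passes, 7 at 100 m offset
    off <- if (i <= 3) 0 else 100
    straight_track(-400, off, 1, 0, v = 15, n = 55, z = 80,
                   track_id = paste0("t", i))
  }))
  dat <- build_dataset(tracks, trb)
  expect_equal(nrow(dat), 10)
  expect_equal(sum(dat$y), 3)
  s <- attr(dat, "summary")
  expect_equal(s$entry_rate, 0.3)
  expect_equal(s$frac_single_turbine, 1)
  far <- straight_track(-400, 500, 1, 0, n = 10)
  expect_error(build_dataset(far, trb), "no approaches")
})

test_that("the geometry pipeline reproduces the generator's outcomes exactly", {
  study <- small_study()
  dat <- build_dataset(study$tracks, study$layout$turbines)
  expect_identical(cell_counts(dat), cell_counts(study$outcomes))
  # ... and per track-turbine pair, the entry labels match the assignments
  asg <- attr(study$tracks, "assignments")
  joined <- dplyr::inner_join(
    dat, asg, by = c("track_id" = "track_id", "turbine_id" = "turbine_id"),
    suffix = c("", "_gen"))
  expect_equal(nrow(joined), nrow(dat))
  expect_identical(as.integer(joined$y), as.integer(joined$y_gen))
  # deduplication leaves the simulated (single-unit-per-track) set unchanged
  expect_equal(nrow(deduplicate_simultaneous(study$tracks)), nrow(study$tracks))
})
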
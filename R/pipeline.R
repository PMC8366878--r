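# File-based pipeline orchestration. Stages communicate only via files in
# the output directory, so any stage can be re-run or audited on its own:
#   simulate  -> turbines.csv, tracks.csv, ground_truth.json
#   process   -> entry_data.csv, counts.json
#   curtail   -> curtailment_events.csv
#   fit       -> posterior_scalars.csv, diagnostics.csv, fit.rds
#   summarize -> summary.csv, headline.json
#   report    -> risk_map.geojson, monthly_range.csv

#' Default pipeline configuration
#'
#' @param output_dir Directory for stage artifacts.
#' @param tracks,turbines Input paths (defaults: the simulate stage's
#'   outputs inside `output_dir`).
#' @param criteria,model,sim Component configurations.
#' @param safer_threshold,riskier_threshold Classification thresholds.
#' @param seed Integer seed for the stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = "rszentry_run",
                            tracks = NULL, turbines = NULL,
                            criteria = curtailment_criteria(),
                            model = model_config(),
                            sim = sim_config(),
                            safer_threshold = 0.95, riskier_threshold = 0.05,
                            seed = 1) {
  structure(list(
    output_dir = output_dir,
    tracks = tracks %||% file.path(output_dir, "tracks.csv"),
    turbines = turbines %||% file.path(output_dir, "turbines.csv"),
    criteria = criteria, model = model, sim = sim,
    safer_threshold = safer_threshold, riskier_threshold = riskier_threshold,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `output_dir`, `tracks`, `turbines`, `seed`,
#' `safer_threshold`, `riskier_threshold`, and blocks `criteria`, `model`,
#' `sim` whose entries are passed to [curtailment_criteria()],
#' [model_config()] and [sim_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    output_dir = y$output_dir %||% "rszentry_run",
    tracks = y$tracks, turbines = y$turbines,
    criteria = do.call(curtailment_criteria, y$criteria %||% list()),
    model = do.call(model_config, y$model %||% list()),
    sim = do.call(sim_config, y$sim %||% list()),
    safer_threshold = y$safer_threshold %||% 0.95,
    riskier_threshold = y$riskier_threshold %||% 0.05,
    seed = y$seed %||% 1
  )
  do.call(pipeline_config, args)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = "")))
}

#' Run pipeline stages
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param stages Character vector of stages, or `"run-all"`.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = "run-all") {
  if (is.character(config)) config <- read_pipeline_config(config)
  all_stages <- c("simulate", "process", "curtail", "fit", "summarize", "report")
  if (identical(stages, "run-all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (s in stages) {
    t0 <- Sys.time()
    out[[s]] <- switch(s,
      simulate = stage_simulate(config),
      process = stage_process(config),
      curtail = stage_curtail(config),
      fit = stage_fit(config),
      summarize = stage_summarize(config),
      report = stage_report(config)
    )
    stage_log(s, sprintf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))
  }
  invisible(out)
}

artifact <- function(config, name) file.path(config$output_dir, name)

stage_simulate <- function(config) {
  stage_log("simulate", "seed ", config$seed)
  study <- simulate_entry_study(config$sim, seed = config$seed)
  tpath <- artifact(config, "turbines.csv")
  tb <- study$layout$turbines
  readr::write_csv(dplyr::rename(tb, ground_elevation_m = "ground_elevation",
                                 rotor_diameter_m = "rotor_diameter",
                                 hub_height_m = "hub_height",
                                 max_blade_height_m = "max_blade_height"), tpath)
  kpath <- artifact(config, "tracks.csv")
  readr::write_csv(study$tracks, kpath)
  truth <- study$truth
  gt <- list(
    mu = truth$mu, alpha = as.list(truth$alpha), beta = as.list(truth$beta),
    p_true = as.data.frame(truth$p_true), observed = as.data.frame(truth$observed),
    outcomes = study$outcomes
  )
  gpath <- artifact(config, "ground_truth.json")
  jsonlite::write_json(gt, gpath, digits = NA, auto_unbox = TRUE)
  apath <- artifact(config, "assignments.csv")
  readr::write_csv(attr(study$tracks, "assignments"), apath)
  stage_log("simulate", nrow(study$tracks), " track points, ",
            nrow(study$outcomes), " approaches")
  c(turbines = tpath, tracks = kpath, ground_truth = gpath, assignments = apath)
}

stage_process <- function(config) {
  turbines <- read_turbines(config$turbines)
  pts <- read_tracks(config$tracks)
  stage_log("process", length(unique(pts$track_id)), " tracks, ",
            nrow(turbines), " turbines")
  pts <- deduplicate_simultaneous(pts)
  data <- build_dataset(pts, turbines, config$criteria)
  dpath <- artifact(config, "entry_data.csv")
  write_entry_data(data, dpath)
  cpath <- artifact(config, "counts.json")
  jsonlite::write_json(attr(data, "summary"), cpath, digits = NA, auto_unbox = TRUE)
  stage_log("process", attr(data, "summary")$n_approaches, " approaches, ",
            attr(data, "summary")$n_entries, " entries")
  c(entry_data = dpath, counts = cpath)
}

stage_curtail <- function(config) {
  turbines <- read_turbines(config$turbines)
  pts <- read_tracks(config$tracks)
  res <- simulate_curtailments(pts, turbines, config$criteria)
  epath <- artifact(config, "curtailment_events.csv")
  readr::write_csv(res$events, epath)
  stage_log("curtail", nrow(res$events), " curtailment events")
  c(events = epath)
}

stage_fit <- function(config) {
  data <- read_entry_data(artifact(config, "entry_data.csv"))
  cfg <- config$model
  cfg$seed <- config$seed
  stage_log("fit", nrow(data), " approaches, seed ", cfg$seed)
  fit <- fit_entry_model(data, cfg)
  # scalar-parameter draws as columnar CSV; full object as a binary cache
  scalars <- tibble::tibble(
    chain = rep(fit$chain, 4),
    iter = rep(rep(seq_len(fit$n_keep), fit$config$n_chains), 4),
    parameter = rep(c("mu", "sigma2_turbine", "sigma2_month", "sigma2_cell"),
                    each = length(fit$draws$mu)),
    value = c(fit$draws$mu, fit$draws$sigma2[, 1], fit$draws$sigma2[, 2],
              fit$draws$sigma2[, 3])
  )
  ppath <- artifact(config, "posterior_scalars.csv")
  readr::write_csv(scalars, ppath)
  dpath <- artifact(config, "diagnostics.csv")
  readr::write_csv(diagnostics(fit), dpath)
  fpath <- artifact(config, "fit.rds")
  saveRDS(fit, fpath)
  c(posterior = ppath, diagnostics = dpath, fit = fpath)
}

stage_summarize <- function(config) {
  fit <- readRDS(artifact(config, "fit.rds"))
  summ <- risk_summary(fit, config$safer_threshold, config$riskier_threshold)
  spath <- artifact(config, "summary.csv")
  readr::write_csv(tibble::as_tibble(summ), spath)
  h <- headline_stats(summ)
  h$monthly_range <- NULL
  hpath <- artifact(config, "headline.json")
  jsonlite::write_json(h, hpath, digits = NA, auto_unbox = TRUE)
  c(summary = spath, headline = hpath)
}

stage_report <- function(config) {
  turbines <- read_turbines(config$turbines)
  fit <- readRDS(artifact(config, "fit.rds"))
  summ <- risk_summary(fit, config$safer_threshold, config$riskier_threshold)
  gpath <- artifact(config, "risk_map.geojson")
  write_risk_geojson(turbines, summ, gpath)
  mpath <- artifact(config, "monthly_range.csv")
  readr::write_csv(headline_stats(summ)$monthly_range, mpath)
  c(risk_map = gpath, monthly_range = mpath)
}

#' Write a GeoJSON risk map of the facility
#'
#' One point feature per turbine with its model, posterior-mean entry
#' probability and safer/average/riskier classification (turbines absent
#' from the summary are labelled `"average"` with no estimate).
#'
#' @param turbines A [turbine_table()].
#' @param summary A [risk_summary()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_risk_geojson <- function(turbines, summary, path) {
  cls <- summary |>
    dplyr::filter(.data$scope == "turbine") |>
    dplyr::select("turbine_id", "class", "posterior_mean", "pd")
  df <- dplyr::left_join(turbines, cls, by = "turbine_id")
  features <- purrr::map(seq_len(nrow(df)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(df$lon[i], df$lat[i])),
      properties = list(
        turbine_id = df$turbine_id[i],
        model_name = df$model_name[i],
        rotor_diameter_m = df$rotor_diameter[i],
        posterior_mean = df$posterior_mean[i],
        pd = df$pd[i],
        class = if (is.na(df$class[i] %||% NA)) "average" else df$class[i]
      )
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
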
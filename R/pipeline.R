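#' Configure an end-to-end synthetic pipeline run
#'
#' Bundles the stage toggles, seeds and per-stage settings for
#' [run_pipeline()]. Stage dependencies are validated here: `cost`
#' requires `simulate`, `kde`/`forecast` require `cost`, `effects` and
#' `robustness` require `sdm`.
#'
#' @param out_dir Output directory for stage artifacts (created if
#'   needed).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param stages Character vector of stages to run, from
#'   `c("simulate", "cost", "kde", "forecast", "sdm", "effects",
#'   "robustness")`.
#' @param generator A [generator_config()]; defaults to the reference
#'   29-province 1992-2021 conditions under the master seed.
#' @param truth An [sdm_ground_truth()] for the SDM stage; default
#'   `rho = 0.3`, three covariates.
#' @param kde_years Years for the density curves; default first year,
#'   two interior decades and the last year of the generator span.
#' @param lstm An [lstm_config()]; default protocol under the master
#'   seed.
#' @param effects_draws Simulation draws for effect t-values; default
#'   2000.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed,
                            stages = c("simulate", "cost", "kde", "forecast",
                                       "sdm", "effects", "robustness"),
                            generator = NULL, truth = NULL,
                            kde_years = NULL, lstm = NULL,
                            effects_draws = 2000) {
  all_stages <- c("simulate", "cost", "kde", "forecast", "sdm", "effects",
                  "robustness")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
  needs <- list(cost = "simulate", kde = "cost", forecast = "cost",
                sdm = "simulate", effects = "sdm", robustness = "sdm")
  for (st in intersect(names(needs), stages)) {
    if (!needs[[st]] %in% stages) {
      abort(sprintf("Stage `%s` requires stage `%s`.", st, needs[[st]]))
    }
  }
  generator <- generator %||% generator_config(seed = seed)
  truth <- truth %||% sdm_ground_truth(
    rho = 0.3,
    beta = c(tech = -0.8, social = 0.9, nature = -0.4),
    theta = c(tech = 0.3, social = 0.4, nature = 0.2),
    sigma2 = 1
  )
  yrs <- generator$years
  kde_years <- kde_years %||%
    unique(round(stats::quantile(yrs, c(0, 1 / 3, 2 / 3, 1))))
  lstm <- lstm %||% lstm_config(
    train_span = c(min(yrs), min(yrs) + ceiling(2 * (length(yrs)) / 3) - 1),
    test_span = c(min(yrs) + ceiling(2 * (length(yrs)) / 3), max(yrs)),
    horizon_end = max(yrs) + 9, seed = seed
  )
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
         generator = generator, truth = truth, kde_years = kde_years,
         lstm = lstm, effects_draws = effects_draws),
    class = "pipeline_config"
  )
}

#' Run the synthetic analysis pipeline
#'
#' Executes the configured stages in dependency order — simulate stand
#' inputs and an SDM covariate panel, compute equilibrium costs, estimate
#' per-year density curves, fit and forecast the LSTM, fit the spatial
#' Durbin model, decompose effects, and sweep alternative weight matrices
#' — writing each artifact as CSV/JSON under `out_dir` and returning a
#' manifest. Every artifact is stamped with the configuration hash and
#' seed; an identical configuration reproduces identical artifacts. A
#' failing stage halts its dependents but the manifest reports the
#' stages already completed.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest: a list with the config hash, seed, and per
#'   stage the artifact paths, content hashes and timing. Also written
#'   to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  manifest <- list(config_hash = cfg_hash, seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())

  record <- function(stage, artifacts, t0) {
    manifest$stages[[stage]] <<- list(
      artifacts = lapply(artifacts, function(p) {
        list(path = p, hash = rlang::hash(readLines(p, warn = FALSE)))
      }),
      seconds = round(as.numeric(Sys.time()) - t0, 3)
    )
  }
  path_of <- function(name) file.path(config$out_dir, name)

  stage_runners <- list(
    simulate = function() {
      state$W <- generate_adjacency(config$generator$n_provinces,
                                    "random_planar", seed = config$seed)
      state$Wstd <- new_spatial_weights(state$W$W, "contiguity",
                                        standardize = TRUE)
      state$inputs <- generate_cost_inputs(config$generator)
      state$sim <- generate_sdm_panel(state$Wstd, config$truth,
                                      config$generator)
      p1 <- path_of("cost_inputs.csv")
      readr::write_csv(state$inputs, p1, progress = FALSE)
      p2 <- path_of("sdm_panel.csv")
      write_sdm_panel(state$sim, config$generator, p2)
      c(p1, p2, sub("\\.csv$", ".truth.json", p2))
    },
    cost = function() {
      state$costs <- panel_costs(state$inputs)
      p <- path_of("panel_costs.csv")
      readr::write_csv(
        dplyr::select(state$costs, "province", "year", "region",
                      "carbon_cost", "uptake", "negative_price"),
        p, progress = FALSE)
      p
    },
    kde = function() {
      state$curves <- density_by_group(state$costs, config$kde_years,
                                       grouping = "region")
      national <- density_by_group(state$costs, config$kde_years,
                                   grouping = "national")
      state$curves <- dplyr::bind_rows(state$curves, national)
      p <- path_of("density_curves.csv")
      readr::write_csv(state$curves, p, progress = FALSE)
      p
    },
    forecast = function() {
      series <- state$costs |>
        dplyr::group_by(.data$year) |>
        dplyr::summarise(value = mean(.data$carbon_cost), .groups = "drop")
      state$lstm_fit <- fit_lstm(series, config$lstm)
      state$forecast <- forecast_recursive(state$lstm_fit)
      p1 <- path_of("forecast.csv")
      readr::write_csv(state$forecast, p1, progress = FALSE)
      p2 <- path_of("forecast_manifest.json")
      jsonlite::write_json(
        list(seed = config$lstm$seed,
             hidden_units = config$lstm$hidden_units,
             epochs = config$lstm$epochs,
             dropout_rate = config$lstm$dropout_rate,
             lookback = config$lstm$lookback,
             train_rmse = state$lstm_fit$train_rmse,
             test_rmse = state$lstm_fit$test_rmse),
        p2, auto_unbox = TRUE, digits = NA)
      c(p1, p2)
    },
    sdm = function() {
      covs <- names(config$truth$beta)
      state$fit <- fit_sdm(state$sim$panel, state$Wstd, "lncc", covs,
                           fixed_effects = "twoway")
      p <- path_of("sdm_fit.csv")
      readr::write_csv(tidy(state$fit), p, progress = FALSE)
      p2 <- path_of("sdm_manifest.json")
      jsonlite::write_json(
        c(as.list(glance(state$fit)), list(seed = config$seed)),
        p2, auto_unbox = TRUE, digits = NA)
      c(p, p2)
    },
    effects = function() {
      state$effects <- decompose_effects(state$fit, state$Wstd,
                                         draws = config$effects_draws,
                                         seed = config$seed)
      p <- path_of("effects.csv")
      readr::write_csv(state$effects, p, progress = FALSE)
      p
    },
    robustness = function() {
      coords <- attr(state$W, "coordinates")
      geo <- build_weights(
        tibble::tibble(province = state$W$provinces,
                       lat = coords[, 2] * 10 + 25, lon = coords[, 1] * 30 + 90),
        kind = "geographic")
      econ_ind <- state$sim$panel |>
        dplyr::group_by(.data$province) |>
        dplyr::summarise(value = mean(.data$social), .groups = "drop")
      econ <- build_weights(econ_ind, kind = "economic")
      state$robust <- robustness_sweep(
        state$sim$panel,
        list(contiguity = state$Wstd, geographic = geo, economic = econ),
        outcome = "lncc", covariates = names(config$truth$beta),
        fixed_effects = "twoway", draws = config$effects_draws,
        seed = config$seed)
      p <- path_of("robustness.csv")
      readr::write_csv(state$robust, p, progress = FALSE)
      p
    }
  )

  order <- c("simulate", "cost", "kde", "forecast", "sdm", "effects",
             "robustness")
  failed <- character()
  for (stage in intersect(order, config$stages)) {
    deps_failed <- length(failed) > 0
    if (deps_failed) {
      manifest$stages[[stage]] <- list(skipped = TRUE, reason = paste0(
        "dependent stage(s) failed: ", paste(failed, collapse = ", ")))
      next
    }
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(stage_runners[[stage]](), error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, stage)
      manifest$stages[[stage]] <- list(error = conditionMessage(res))
      warn(sprintf("Stage `%s` failed: %s", stage, conditionMessage(res)))
    } else {
      record(stage, as.list(res), t0)
    }
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Summarise a pipeline run
#'
#' Reads the artifacts recorded in a run manifest back from disk and
#' tabulates the headline numbers: cost summary statistics by year,
#' density-curve moments, the forecast path and RMSE, SDM coefficients
#' and the effect decomposition. Artifacts that are missing are named in
#' the summary rather than raising an error.
#'
#' @param manifest A manifest list from [run_pipeline()] or the path to a
#'   `manifest.json`.
#' @return A named list of tibbles (one per available section) with a
#'   `missing` character vector naming absent artifacts; printed
#'   compactly.
#' @export
report_summary <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  paths <- unlist(lapply(manifest$stages, function(st) {
    vapply(st$artifacts, function(a) a$path, character(1))
  }), use.names = FALSE)
  find <- function(suffix) {
    hit <- paths[endsWith(paths, suffix)]
    if (length(hit) && file.exists(hit[1])) hit[1] else NA_character_
  }
  out <- list(seed = manifest$seed, config_hash = manifest$config_hash)
  missing <- character()

  p <- find("panel_costs.csv")
  if (!is.na(p)) {
    out$costs <- readr::read_csv(p, show_col_types = FALSE) |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(mean_cost = mean(.data$carbon_cost),
                       sd_cost = sd(.data$carbon_cost),
                       n_negative = sum(.data$negative_price),
                       .groups = "drop")
  } else missing <- c(missing, "panel_costs.csv")

  p <- find("density_curves.csv")
  if (!is.na(p)) {
    out$kde <- readr::read_csv(p, show_col_types = FALSE) |>
      dplyr::group_by(.data$year, .data$region) |>
      dplyr::summarise(
        peak_density = max(.data$density),
        mean = sum(.data$x * .data$density) / sum(.data$density),
        .groups = "drop")
  } else missing <- c(missing, "density_curves.csv")

  p <- find("forecast.csv")
  if (!is.na(p)) {
    fc <- readr::read_csv(p, show_col_types = FALSE)
    out$forecast <- dplyr::filter(fc, .data$segment == "forecast")
    pm <- find("forecast_manifest.json")
    if (!is.na(pm)) out$forecast_rmse <- jsonlite::read_json(pm)
  } else missing <- c(missing, "forecast.csv")

  p <- find("sdm_fit.csv")
  if (!is.na(p)) {
    out$sdm <- readr::read_csv(p, show_col_types = FALSE)
  } else missing <- c(missing, "sdm_fit.csv")

  p <- find("effects.csv")
  if (!is.na(p)) {
    out$effects <- readr::read_csv(p, show_col_types = FALSE)
  } else missing <- c(missing, "effects.csv")

  out$missing <- missing
  out
}
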
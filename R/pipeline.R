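#' The default 15-year calibration transition matrix
#'
#' A plausible arid-region calibration-period dynamic used when the pipeline
#' runs on synthetic landscapes: cropland and built-up grow mainly at the
#' expense of bare land, grassland exchanges with cropland and bare land,
#' and water and built-up are nearly inert.
#'
#' @param period_years Calibration period length (years).
#' @return A [transition_matrix()] over [mods_classes()].
#' @export
default_calibration_matrix <- function(period_years = 15) {
  cls <- mods_classes()
  p <- matrix(0, 6, 6, dimnames = list(cls, cls))
  p["cropland", ] <- c(0.93, 0.00, 0.03, 0.00, 0.02, 0.02)
  p["forest", ]   <- c(0.00, 0.97, 0.03, 0.00, 0.00, 0.00)
  p["grassland", ] <- c(0.02, 0.01, 0.95, 0.00, 0.00, 0.02)
  p["water", ]    <- c(0.00, 0.00, 0.00, 0.98, 0.00, 0.02)
  p["built", ]    <- c(0.00, 0.00, 0.00, 0.00, 1.00, 0.00)
  p["bare", ]     <- c(0.02, 0.00, 0.02, 0.00, 0.01, 0.95)
  transition_matrix(p, classes = cls, period_years = period_years)
}

#' Pipeline configuration
#'
#' @param nrow,ncol,pixel_size Synthetic grid definition.
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it, and it is recorded in the manifest.
#' @param scenarios Named list of [scenario_spec()]s; default the three
#'   built-in policy scenarios.
#' @param years Projection years (strictly increasing; spacing must divide
#'   the calibration period).
#' @param calibration_matrix [transition_matrix()] generating the synthetic
#'   calibration-period change; default [default_calibration_matrix()].
#' @param es_params Per-class service parameter table.
#' @param n_factors Driving factors for suitability training.
#' @param min_area_km2 Area filter for the interaction legend.
#' @param epsilon Per-pixel no-change tolerance for the digit reclass.
#' @param unchanged_threshold Regional "virtually unchanged" tolerance.
#' @param field_length RWEQ downwind field length (m).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(nrow = 50, ncol = 50, pixel_size = 100,
                            seed = 1L,
                            scenarios = default_scenarios(),
                            years = seq(2015, 2035, by = 5),
                            calibration_matrix = default_calibration_matrix(),
                            es_params = es_params_default(),
                            n_factors = 16, min_area_km2 = 40,
                            epsilon = 0, unchanged_threshold = 0.01,
                            field_length = 50) {
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")
  structure(list(nrow = nrow, ncol = ncol, pixel_size = pixel_size,
                 seed = as.integer(seed), scenarios = scenarios,
                 years = years, calibration_matrix = calibration_matrix,
                 es_params = es_params, n_factors = n_factors,
                 min_area_km2 = min_area_km2, epsilon = epsilon,
                 unchanged_threshold = unchanged_threshold,
                 field_length = field_length),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

quantify_services <- function(map, bundle, config, year, izrd, usle) {
  wy <- water_yield(bundle$precipitation, map, et0 = bundle$et0,
                    params = config$es_params, year = year)
  cp <- crop_production(map, bundle$temperature, bundle$precipitation,
                        izrd, year = year)
  sc <- usle_soil_conservation(usle$r, usle$k, usle$l, usle$s, map,
                               params = config$es_params, year = year)
  sf <- rweq_sand_fixation(bundle$wind$wf, bundle$wind$ef, bundle$wind$scf,
                           bundle$wind$ka, map, params = config$es_params,
                           field_length = config$field_length, year = year)
  cs <- carbon_sequestration(map, params = config$es_params, year = year)
  av <- aesthetic_value(map, params = config$es_params, year = year)
  list(WY = wy, CP = cp, SC = sc, SF = sf, CS = cs$layer, AV = av)
}

#' Run the full scenario-analysis pipeline on a synthetic landscape
#'
#' Executes synth -> calibrate -> validate -> simulate -> quantify ->
#' interact for every configured scenario, and (optionally) writes all
#' outputs plus a provenance manifest to a run directory. A rerun with the
#' same configuration and seed reproduces every output bit-exactly.
#'
#' Stages: generate the landscape and a calibration-period map pair from the
#' configured calibration matrix; estimate the transition matrix from the
#' pair; train the ANN suitability surface and compute per-class ROC AUC and
#' a CA backcast kappa; per scenario, apply the modifiers, split the matrix
#' to the projection step, project demand, and allocate each step with the
#' CA; quantify the six services for every projection year; classify the
#' regional trend series and build the six-digit overlay with area filtering
#' and land-use cause attribution.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional run directory; created if missing. When given,
#'   land-use and service rasters (`.asc` + JSON sidecars), demand/series/
#'   interaction CSVs, `validation.json` and `manifest.json` are written.
#' @return Invisibly, a list: `bundle`, `transition` (estimated matrix),
#'   `validation` (per-class AUC, kappa), `scenarios` (per scenario: the
#'   modified and step matrices, demand trajectory, land-use maps by year,
#'   service layers for the first and last year, regional `series`,
#'   `trends`, `codes`, `causes`), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  years <- config$years
  gaps <- unique(diff(years))
  if (length(gaps) != 1) stop("projection years must be evenly spaced")
  calib <- config$calibration_matrix
  n_split <- calib$period_years / gaps
  if (abs(n_split - round(n_split)) > 1e-9) {
    stop("year spacing must divide the calibration period")
  }

  bundle <- stage("synth", {
    generate_landscape(synthetic_config(config$nrow, config$ncol,
                                        config$pixel_size, seed = seed))
  })
  lu_start <- bundle$landuse_t0
  lu_t0 <- stage("synth", markov_evolve_map(lu_start, calib, seed + 1L))

  est <- stage("calibrate", {
    estimate_transition_matrix(lu_start, lu_t0, calib$period_years)
  })

  factors <- stage("suitability", {
    generate_driving_factors(bundle, config$n_factors, seed + 2L)
  })
  surface <- stage("suitability", {
    train_suitability(factors, lu_t0, seed = seed + 3L)
  })

  validation <- stage("validate", {
    auc <- roc_auc(surface, lu_t0)
    back <- ca_allocate(lu_start, surface,
                        ca_params(seed = seed + 4L),
                        class_counts(lu_t0))
    list(roc_auc = auc, kappa = kappa_statistic(back, lu_t0),
         backcast_converged = attr(back, "converged"))
  })

  # land-use level index: best in the oasis corridor, fixed over time
  izrd <- pmin(pmax(0.45 + 0.35 * (bundle$zones == 2L), 0), 1)
  usle <- usle_factors_from_landscape(bundle)

  scen_results <- list()
  for (sname in names(config$scenarios)) {
    spec <- config$scenarios[[sname]]
    res <- stage(paste0("simulate:", sname), {
      mod <- apply_scenario_modifiers(est, spec)
      q <- step_split_matrix(mod, round(n_split))
      demand <- project_demand(q, class_counts(lu_t0), years)
      maps <- stats::setNames(vector("list", length(years)),
                              as.character(years))
      maps[[1]] <- lu_t0
      for (i in seq_along(years)[-1]) {
        dem_i <- round(as.numeric(demand[i, est$classes]))
        names(dem_i) <- est$classes
        maps[[i]] <- ca_allocate(maps[[i - 1]], surface,
                                 ca_params(seed = seed + 10L * i +
                                             match(sname, names(config$scenarios))),
                                 dem_i)
      }
      list(modified = mod, step_matrix = q, demand = demand, maps = maps)
    })
    res <- c(res, stage(paste0("quantify:", sname), {
      es_by_year <- lapply(seq_along(years), function(i) {
        quantify_services(res$maps[[i]], bundle, config, years[i], izrd, usle)
      })
      names(es_by_year) <- as.character(years)
      series <- sapply(es_order(), function(es) {
        vapply(es_by_year, function(e) sum(e[[es]]$values), numeric(1))
      })
      list(es_t0 = es_by_year[[1]], es_t1 = es_by_year[[length(years)]],
           series = as.data.frame(series, row.names = as.character(years)))
    }))
    res <- c(res, stage(paste0("interact:", sname), {
      trends <- classify_regional_trends(as.list(res$series),
                                         config$unchanged_threshold)
      digits <- stats::setNames(lapply(es_order(), function(es) {
        reclass_change(res$es_t0[[es]], res$es_t1[[es]], config$epsilon)
      }), es_order())
      codes <- encode_overlay(digits, pixel_size = config$pixel_size)
      codes <- filter_codes_by_area(codes, config$min_area_km2)
      causes <- attribute_causes(codes, res$maps[[1]],
                                 res$maps[[length(years)]])
      normalized <- as.data.frame(lapply(res$series, minmax_normalize),
                                  row.names = rownames(res$series))
      list(trends = trends, codes = codes, causes = causes,
           normalized = normalized)
    }))
    scen_results[[sname]] <- res
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("modses")),
    seed = seed,
    grid = c(config$nrow, config$ncol), pixel_size = config$pixel_size,
    years = years, scenarios = names(config$scenarios),
    calibration_period_years = calib$period_years)

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_ascii_grid(lu_t0, file.path(out_dir, "landuse_t0.asc"))
      for (sname in names(scen_results)) {
        res <- scen_results[[sname]]
        sdir <- file.path(out_dir, sname)
        dir.create(sdir, showWarnings = FALSE)
        for (yr in names(res$maps)) {
          write_ascii_grid(res$maps[[yr]],
                           file.path(sdir, paste0("landuse_", yr, ".asc")))
        }
        for (es in es_order()) {
          write_ascii_grid(res$es_t1[[es]],
                           file.path(sdir, paste0(es, "_final.asc")))
        }
        utils::write.csv(cbind(year = rownames(res$series), res$series),
                         file.path(sdir, "series.csv"), row.names = FALSE)
        utils::write.csv(data.frame(year = rep(rownames(res$series),
                                               length(es_order())),
                                    es = rep(es_order(),
                                             each = nrow(res$series)),
                                    raw = unlist(res$series),
                                    normalized = unlist(res$normalized)),
                         file.path(sdir, "flower_series.csv"),
                         row.names = FALSE)
        utils::write.csv(res$demand, file.path(sdir, "demand.csv"),
                         row.names = FALSE)
        utils::write.csv(res$codes$legend, file.path(sdir, "interactions.csv"),
                         row.names = FALSE)
        utils::write.csv(res$causes$table, file.path(sdir, "causes.csv"),
                         row.names = FALSE)
      }
      jsonlite::write_json(validation, file.path(out_dir, "validation.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
      files <- setdiff(files, file.path(out_dir, "manifest.json"))
      manifest$files <- stats::setNames(
        as.vector(tools::md5sum(files)),
        sub(paste0("^", out_dir, "/?"), "", files))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    })
  }

  invisible(list(bundle = bundle, transition = est, surface = surface,
                 validation = validation, scenarios = scen_results,
                 manifest = manifest, config = config))
}
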
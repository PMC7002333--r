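#' Configuration for the end-to-end analysis pipeline
#'
#' Collects everything [run_pipeline()] needs: either a generative
#' configuration (demo mode, data are simulated) or paths to input CSVs
#' (analysis mode), the kernel treatment, the model ladder, and a master
#' seed from which each stage derives its own seed by name hashing (see
#' [child_seed()]).
#'
#' @param gen A [gen_config()] for demo mode, or `NULL` to read files.
#' @param region A [study_region()].
#' @param census,nests,cones File paths (analysis mode).
#' @param select_kernel If `TRUE`, select the kernel shape by AIC over
#'   `flat_top_grid` x `sd_grid`; otherwise use `kernel` as given.
#' @param kernel A [kernel_params()] (used directly, or as the template
#'   for the grid candidates).
#' @param flat_top_grid,sd_grid Kernel selection grid.
#' @param models Named list of [model_spec()] objects — the model ladder.
#'   The default ladder is (a) independent regression with covariates,
#'   (b) spatiotemporal smoothing-only, (c) spatiotemporal with
#'   covariates.
#' @param covariates Covariate set for the models that use covariates.
#' @param cone_method Interpolation engine for the cone surface.
#' @param n_draws Posterior draws per fitted model.
#' @param seed Master seed.
#' @param out Optional output directory for stage CSV/JSON artefacts.
#' @param verbose Log stage progress to stderr.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(gen = NULL, region = study_region(),
                            census = NULL, nests = NULL, cones = NULL,
                            select_kernel = FALSE,
                            kernel = kernel_params(),
                            flat_top_grid = c(0.5, 1, 1.5, 2, 2.5),
                            sd_grid = 1:4,
                            models = NULL,
                            covariates = c("marten_density",
                                           "goshawk_kernel", "cone_index",
                                           "triangle_type", "temperature",
                                           "precipitation"),
                            cone_method = "gcv", n_draws = 400,
                            seed = 1L, out = NULL, verbose = FALSE) {
  if (is.null(gen)) {
    for (f in c(census, nests, cones)) {
      if (!is.null(f) && !file.exists(f)) {
        stop_snowsync("input file not found: ", f,
                      class = "snowsync_config_error")
      }
    }
    if (is.null(census)) {
      stop_snowsync("either a generative config or a census file is required",
                    class = "snowsync_config_error")
    }
  }
  if (is.null(models)) {
    models <- list(
      a_independent = model_spec(covariates, temporal = "none",
                                 spatial = "none"),
      b_st_smoothing = model_spec(character(), temporal = "ar1",
                                  spatial = "matern"),
      c_st_covariates = model_spec(covariates, temporal = "ar1",
                                   spatial = "matern"))
  }
  if (length(models) == 0L) {
    stop_snowsync("model ladder must be non-empty",
                  class = "snowsync_config_error")
  }
  structure(list(gen = gen, region = region, census = census,
                 nests = nests, cones = cones,
                 select_kernel = select_kernel, kernel = kernel,
                 flat_top_grid = flat_top_grid, sd_grid = sd_grid,
                 models = models, covariates = covariates,
                 cone_method = cone_method, n_draws = n_draws,
                 seed = as.integer(seed), out = out, verbose = verbose),
            class = "pipeline_config")
}

#' A small, fast demo configuration
#'
#' A reduced-scale [pipeline_config()] (few transects, few years, short
#' spatial range) that runs the whole pipeline in well under a minute.
#'
#' @param seed Master seed.
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 1L, ...) {
  gen <- gen_config(n_wildlife = 60, n_field = 25, n_years = 8,
                    census_prob_per_year = 0.8, matern_range_km = 150,
                    ar1_rho = 0.6, field_sd = 0.6,
                    failure_years = c(1990, 1994),
                    seed = child_seed(seed, "simulate"))
  region <- study_region(400, 500, 200)
  pipeline_config(gen = gen, region = region, seed = seed, ...)
}

#' Validate analysis input tables
#'
#' Schema and range checks of the census (and optionally nest and cone)
#' tables: required columns, non-negative integer counts, triangle
#' type/length consistency (wildlife = 12 km, field = 6 km), finite
#' coordinates, logical census flags. Every violation is reported with
#' its table and row number.
#'
#' @param census Census data frame.
#' @param nests,cones Optional nest / cone data frames.
#' @return An object of class `validation_report`: data frame of
#'   violations (zero rows when clean) with attribute `n_censused`.
#' @export
validate_inputs <- function(census, nests = NULL, cones = NULL) {
  v <- list()
  bad <- function(table, rows, msg) {
    if (length(rows)) {
      v[[length(v) + 1L]] <<- data.frame(table = table, row = rows,
                                         message = msg)
    }
  }
  need <- c("triangle_id", "triangle_type", "x_km", "y_km", "length_km",
            "year", "squirrel_tracks")
  absent <- setdiff(need, names(census))
  if (length(absent)) {
    bad("census", 0L, paste("missing column(s):",
                            paste(absent, collapse = ", ")))
  } else {
    cnt <- census$squirrel_tracks
    bad("census", which(!is.na(cnt) & (cnt < 0 | cnt != floor(cnt))),
        "negative or non-integer squirrel count")
    if ("marten_tracks" %in% names(census)) {
      mt <- census$marten_tracks
      bad("census", which(!is.na(mt) & (mt < 0 | mt != floor(mt))),
          "negative or non-integer marten count")
    }
    bad("census",
        which(census$triangle_type == "wildlife" & census$length_km != 12),
        "wildlife triangle must be 12 km")
    bad("census",
        which(census$triangle_type == "field" & census$length_km != 6),
        "field triangle must be 6 km")
    bad("census",
        which(!census$triangle_type %in% c("wildlife", "field")),
        "unknown triangle type")
    bad("census", which(!is.finite(census$x_km) | !is.finite(census$y_km)),
        "non-finite coordinates")
    if ("censused" %in% names(census)) {
      bad("census", which(is.na(census$censused)),
          "censused flag must be TRUE/FALSE")
    }
  }
  if (!is.null(nests)) {
    needn <- c("x_km", "y_km", "year", "occupied")
    absentn <- setdiff(needn, names(nests))
    if (length(absentn)) {
      bad("nests", 0L, paste("missing column(s):",
                             paste(absentn, collapse = ", ")))
    } else {
      bad("nests", which(is.na(nests$occupied)),
          "occupancy flag must be TRUE/FALSE")
    }
  }
  if (!is.null(cones)) {
    needc <- c("x_km", "y_km", "year", "cones_per_tree")
    absentc <- setdiff(needc, names(cones))
    if (length(absentc)) {
      bad("cones", 0L, paste("missing column(s):",
                             paste(absentc, collapse = ", ")))
    } else {
      cp <- cones$cones_per_tree
      bad("cones", which(!is.na(cp) & cp < 0), "negative cone count")
    }
  }
  rep <- if (length(v)) do.call(rbind, v) else
    data.frame(table = character(), row = integer(), message = character())
  attr(rep, "n_censused") <- if ("censused" %in% names(census))
    sum(census$censused, na.rm = TRUE) else nrow(census)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Input validation: clean (", attr(x, "n_censused"),
        "censused records )\n")
  } else {
    cat("Input validation:", nrow(x), "violation(s)\n")
    NextMethod()
  }
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: data simulation (demo mode) or loading,
#' input validation, kernel shape selection (optional), kernel covariate
#' construction, cone-surface interpolation, design assembly, the model
#' ladder fits, WAIC ranking, and per-year Moran's I correlograms of
#' squirrel track density. Deterministic for a fixed config + seed.
#'
#' @param config A [pipeline_config()] (see also [demo_config()]).
#' @return An object of class `ranking_report`: list with `waic_table`
#'   (ascending WAIC, ties broken by fewer covariates), `best_model`,
#'   `coefficients` (of the best model), `range_km` (if the best model is
#'   spatial), `fits`, `kernel`, `kernel_selection`, `design`,
#'   `correlogram`, `validation`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) if (config$verbose) message("[snowsync] ", ...)

  if (!is.null(config$gen)) {
    log_msg("simulating synthetic study")
    dataset <- simulate_dataset(config$gen, config$region, config$kernel)
    census <- dataset$census
    nests <- dataset$nests
    cones <- dataset$cones
  } else {
    log_msg("reading input tables")
    census <- utils::read.csv(config$census)
    nests <- if (!is.null(config$nests)) utils::read.csv(config$nests)
    cones <- if (!is.null(config$cones)) utils::read.csv(config$cones)
  }

  validation <- validate_inputs(census, nests, cones)
  if (nrow(validation) > 0L) {
    stop_snowsync("input validation failed at stage 'validate' (",
                  nrow(validation), " violations); first: ",
                  validation$message[1L],
                  class = "snowsync_validation_error")
  }

  kernel <- config$kernel
  selection <- NULL
  if (config$select_kernel && !is.null(nests)) {
    log_msg("selecting kernel shape by AIC")
    selection <- select_kernel_params(census, nests,
                                      flat_top_grid = config$flat_top_grid,
                                      sd_grid = config$sd_grid,
                                      base_params = config$kernel)
    kernel <- selection$best
  }

  kc <- NULL
  if (!is.null(nests) && "goshawk_kernel" %in% c(config$covariates)) {
    log_msg("computing kernel covariate")
    obs <- if (!is.null(census$censused))
      census[census$censused, , drop = FALSE] else census
    kc <- kernel_covariate(obs, nests, kernel)
  }

  ci <- NULL
  if (!is.null(cones) && "cone_index" %in% config$covariates) {
    log_msg("interpolating cone surfaces")
    obs <- if (!is.null(census$censused))
      census[census$censused, , drop = FALSE] else census
    failure_years <- if (!is.null(config$gen)) config$gen$failure_years else
      c(1990, 1994, 1997, 1999, 2001, 2005, 2009, 2013)
    ci <- build_cone_index(obs, cones, failure_years,
                           config$region$southern_cut_y_km,
                           method = config$cone_method)
  }

  log_msg("assembling design matrix")
  design <- assemble_design(census, kernel_covariate = kc, cone_index = ci,
                            covariates = config$covariates)

  fits <- list()
  for (nm in names(config$models)) {
    log_msg("fitting model ", nm)
    fits[[nm]] <- fit_st_model(design, config$models[[nm]],
                               n_draws = config$n_draws,
                               seed = child_seed(config$seed,
                                                 paste0("fit-", nm)))
  }

  waic_table <- data.frame(
    model = names(fits),
    spatial = vapply(fits, function(f) f$spec$spatial, ""),
    temporal = vapply(fits, function(f) f$spec$temporal, ""),
    n_covariates = vapply(fits, function(f) length(f$spec$covariates), 0L),
    waic = vapply(fits, function(f) f$waic, 0))
  # ascending WAIC; ties broken in favour of fewer covariates
  waic_table <- waic_table[order(waic_table$waic,
                                 waic_table$n_covariates), ]
  rownames(waic_table) <- NULL
  best_name <- waic_table$model[1L]
  best <- fits[[best_name]]

  log_msg("computing correlogram of squirrel track density")
  obs <- design$df
  panel <- data.frame(x_km = obs$x_km, y_km = obs$y_km, year = obs$year,
                      value = obs$squirrel_tracks / obs$length_km)
  max_d <- min(750, max(dist_matrix(obs$x_km, obs$y_km)))
  cg <- correlogram(panel, "value", bin_width_km = 20, max_dist_km = max_d)

  report <- structure(list(
    waic_table = waic_table, best_model = best_name,
    coefficients = best$coefficients,
    range_km = if (best$spec$spatial == "matern") extract_range(best),
    fits = fits, kernel = kernel, kernel_selection = selection,
    design = design, correlogram = cg, validation = validation,
    seed = config$seed), class = "ranking_report")

  if (!is.null(config$out)) write_report(report, config$out)
  report
}

#' @export
print.ranking_report <- function(x, ...) {
  cat("Model ranking (lower WAIC is better):\n")
  print(x$waic_table, row.names = FALSE)
  cat("Best model:", x$best_model, "\n")
  if (!is.null(x$range_km)) {
    cat(sprintf("Spatial range: %.0f km (SD %s)\n", x$range_km$range_km,
                ifelse(is.na(x$range_km$sd), "NA",
                       sprintf("%.0f", x$range_km$sd))))
  }
  invisible(x)
}

#' Write pipeline artefacts as CSV/JSON files
#'
#' @param report A `ranking_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$waic_table, file.path(dir, "waic.csv"),
                   row.names = FALSE)
  utils::write.csv(report$coefficients, file.path(dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$correlogram),
                   file.path(dir, "correlogram.csv"), row.names = FALSE)
  if (!is.null(report$kernel_selection)) {
    utils::write.csv(report$kernel_selection$table,
                     file.path(dir, "kernel_selection.csv"),
                     row.names = FALSE)
  }
  best <- report$fits[[report$best_model]]
  jsonlite::write_json(
    list(best_model = report$best_model,
         hyper = best$hyper, range_km = report$range_km,
         seed = report$seed),
    file.path(dir, "hyper.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  utils::write.csv(best$fitted, file.path(dir, "fitted.csv"),
                   row.names = FALSE)
  utils::write.csv(spatial_residuals(best),
                   file.path(dir, "residuals.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML mirrors the arguments of [pipeline_config()]; the `gen`,
#' `region` and `kernel` blocks are passed to [gen_config()],
#' [study_region()] and [kernel_params()], and each entry of `models`
#' to [model_spec()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$gen)) {
    gen <- raw$gen
    if (!is.null(gen$beta)) gen$beta <- unlist(gen$beta)
    args$gen <- do.call(gen_config, gen)
  }
  if (!is.null(raw$region)) args$region <- do.call(study_region, raw$region)
  if (!is.null(raw$kernel)) args$kernel <- do.call(kernel_params, raw$kernel)
  if (!is.null(raw$models)) {
    args$models <- lapply(raw$models, function(mm) {
      mm$covariates <- as.character(unlist(mm$covariates))
      do.call(model_spec, mm)
    })
  }
  do.call(pipeline_config, args)
}
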
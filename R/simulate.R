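#' Generate triangle transect skeletons over a study region
#'
#' Places `n_wildlife` 12-km forest triangles uniformly over the region and
#' `n_field` 6-km farmland triangles preferentially in the south-western
#' part (at least 85% are forced south of the southern cut, with a western
#' bias, mirroring the concentration of agricultural land). Each triangle
#' keeps fixed coordinates across years; per year it is censused
#' independently with probability `census_prob_per_year`.
#'
#' @param config A [gen_config()] object.
#' @param region A [study_region()] object.
#' @return A data frame with one row per triangle x year: `triangle_id`,
#'   `triangle_type` ("wildlife"/"field"), `x_km`, `y_km`, `length_km`
#'   (12 or 6), `year`, `censused`.
#' @export
generate_region_and_triangles <- function(config, region = study_region()) {
  stopifnot(inherits(config, "gen_config"), inherits(region, "study_region"))
  with_seed(child_seed(config$seed, "triangles"), {
    nw <- config$n_wildlife
    nf <- config$n_field
    wx <- stats::runif(nw, 0, region$width_km)
    wy <- stats::runif(nw, 0, region$height_km)
    n_south <- ceiling(0.85 * nf)
    fx <- c(stats::runif(n_south, 0, 0.7 * region$width_km),
            stats::runif(nf - n_south, 0, region$width_km))
    fy <- c(stats::runif(n_south, 0, region$southern_cut_y_km),
            stats::runif(nf - n_south, 0, region$height_km))
    tri <- data.frame(
      triangle_id = sprintf("T%04d", seq_len(nw + nf)),
      triangle_type = rep(c("wildlife", "field"), c(nw, nf)),
      x_km = c(wx, fx), y_km = c(wy, fy),
      length_km = rep(c(12, 6), c(nw, nf)),
      stringsAsFactors = FALSE)
    years <- config$start_year + seq_len(config$n_years) - 1L
    out <- merge(tri, data.frame(year = years))
    out <- out[order(out$triangle_id, out$year), ]
    rownames(out) <- NULL
    out$censused <- stats::runif(nrow(out)) < config$census_prob_per_year
    out
  })
}

#' Simulate a separable Matern(nu = 1) x AR1 Gaussian field
#'
#' Draws one realisation of a zero-mean Gaussian field over `sites x years`
#' with covariance `field_sd^2 * M(d; range) x AR1(rho)`, where `M` is the
#' Matern(nu = 1) correlation (see [matern_correlation()]). The AR1
#' dimension is initialised at stationarity, so every `w(s, t)` has
#' marginal variance `field_sd^2`.
#'
#' @param x_km,y_km Site coordinates (no duplicates).
#' @param n_years Number of time points.
#' @param range_km,field_sd,rho Field hyperparameters.
#' @param seed Optional integer seed.
#' @return A `length(x_km) x n_years` matrix of field values.
#' @export
simulate_matern_ar1_field <- function(x_km, y_km, n_years, range_km,
                                      field_sd, rho, seed = NULL) {
  n <- length(x_km)
  if (n < 2L) {
    stop_snowsync("need at least two sites", class = "snowsync_geometry_error")
  }
  stopifnot(abs(rho) < 1, range_km > 0, field_sd >= 0, n_years >= 1)
  M <- matern_matrix(x_km, y_km, range_km)
  Ls <- t(chol(M + diag(1e-10, n)))
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n * n_years), n, n_years)
    E <- Ls %*% Z                       # spatially correlated innovations
    W <- matrix(0, n, n_years)
    W[, 1L] <- E[, 1L]
    if (n_years > 1L) {
      s <- sqrt(1 - rho^2)
      for (t in 2:n_years) W[, t] <- rho * W[, t - 1L] + s * E[, t]
    }
    field_sd * W
  })
}

#' Simulate masting cone-count series at research-forest sites
#'
#' Cone counts per tree follow `year_effect * spatial_surface * site_noise`
#' with a shared lognormal year effect (high between-year variance, the
#' masting signature), a smooth positive spatial surface, and mild
#' site-level lognormal noise. In `failure_years` the year effect
#' collapses; southern sites (south of `southern_cut_y_km`) then carry an
#' exact zero crop, and a fraction `missing_frac` of those southern
#' observations is recorded as missing to emulate censuses skipped in the
#' absence of cones.
#'
#' @param sites Data frame with `site_id`, `x_km`, `y_km`.
#' @param years Integer vector of (autumn) years.
#' @param failure_years Subset of `years` with total southern crop failure.
#' @param region A [study_region()] (supplies the southern cut).
#' @param year_sdlog SD (log scale) of the shared year effect.
#' @param site_sdlog SD (log scale) of site-level noise (0 for the
#'   noise-free generative surface).
#' @param missing_frac Fraction of southern failure-year records set `NA`.
#' @param seed Optional integer seed.
#' @return Data frame `site_id`, `x_km`, `y_km`, `year`, `cones_per_tree`
#'   (NA where missing).
#' @export
simulate_cone_series <- function(sites, years, failure_years = integer(),
                                 region = study_region(), year_sdlog = 1.1,
                                 site_sdlog = 0.35, missing_frac = 0.3,
                                 seed = NULL) {
  if (!all(failure_years %in% years)) {
    stop_snowsync("failure_years must be a subset of years",
                  class = "snowsync_config_error")
  }
  with_seed(seed, {
    yr_eff <- stats::rlnorm(length(years), meanlog = log(8), sdlog = year_sdlog)
    names(yr_eff) <- as.character(years)
    # smooth positive surface: gentle diagonal gradient plus a long sinusoid
    surf <- exp(0.4 * sin(2 * pi * sites$x_km / (2 * region$width_km)) +
                  0.3 * (sites$y_km / region$height_km - 0.5))
    out <- expand.grid(site_id = sites$site_id, year = years,
                       stringsAsFactors = FALSE)
    out <- merge(out, sites[, c("site_id", "x_km", "y_km")], by = "site_id")
    out <- out[order(out$year, out$site_id), ]
    rownames(out) <- NULL
    site_noise <- stats::rlnorm(nrow(out), meanlog = 0, sdlog = site_sdlog)
    surf_all <- surf[match(out$site_id, sites$site_id)]
    out$cones_per_tree <- yr_eff[as.character(out$year)] * surf_all * site_noise
    fail <- out$year %in% failure_years
    south <- out$y_km < region$southern_cut_y_km
    out$cones_per_tree[fail & !south] <-
      0.02 * out$cones_per_tree[fail & !south]  # near-total failure up north
    out$cones_per_tree[fail & south] <- 0
    miss <- fail & south & (stats::runif(nrow(out)) < missing_frac)
    out$cones_per_tree[miss] <- NA_real_
    out
  })
}

#' Simulate raptor nesting territories and their yearly occupancy
#'
#' Territories form a homogeneous Poisson point pattern with intensity
#' `nest_density_per_100km2 / 100` per km2. Every territory is occupied in
#' the first year; thereafter occupancy persists year-to-year with
#' probability `persistence_prob` and, once abandoned, stays empty
#' (territory turnover, not re-colonisation, dominates on this timescale).
#'
#' @param region A [study_region()].
#' @param years Integer vector of (summer) years.
#' @param nest_density_per_100km2 Territory density.
#' @param persistence_prob Yearly persistence probability.
#' @param seed Optional integer seed.
#' @return Data frame `nest_id`, `x_km`, `y_km`, `year`, `occupied`.
#' @export
simulate_nests <- function(region, years, nest_density_per_100km2 = 3,
                           persistence_prob = 0.9, seed = NULL) {
  stopifnot(nest_density_per_100km2 > 0)
  with_seed(seed, {
    area <- region$width_km * region$height_km
    n <- stats::rpois(1L, nest_density_per_100km2 * area / 100)
    if (n == 0L) {
      return(data.frame(nest_id = character(), x_km = numeric(),
                        y_km = numeric(), year = integer(),
                        occupied = logical()))
    }
    x <- stats::runif(n, 0, region$width_km)
    y <- stats::runif(n, 0, region$height_km)
    occ <- matrix(FALSE, n, length(years))
    occ[, 1L] <- TRUE
    if (length(years) > 1L) {
      for (t in 2:length(years)) {
        occ[, t] <- occ[, t - 1L] &
          (stats::runif(n) < persistence_prob)
      }
    }
    data.frame(nest_id = rep(sprintf("N%04d", seq_len(n)), length(years)),
               x_km = rep(x, length(years)), y_km = rep(y, length(years)),
               year = rep(years, each = n), occupied = as.vector(occ))
  })
}

# Previous-day weather at the triangles: a north-south winter temperature
# gradient plus cell-level day noise on a 10 x 10 km lattice, and gamma
# precipitation. Emulates gridded weather products sampled at transects.
simulate_weather <- function(triangles, years, region, seed = NULL) {
  with_seed(seed, {
    cell <- paste(floor(triangles$x_km / 10), floor(triangles$y_km / 10))
    cells <- unique(cell)
    out <- expand.grid(idx = seq_len(nrow(triangles)), year = years)
    key <- paste(cell[out$idx], out$year)
    ukey <- unique(key)
    cy <- as.numeric(vapply(strsplit(ukey, " "), `[`, "", 2L)) * 10 + 5
    temp_u <- -4 - 9 * (cy / region$height_km) + stats::rnorm(length(ukey), 0, 2.5)
    prec_u <- stats::rgamma(length(ukey), shape = 1.2, scale = 1.6)
    m <- match(key, ukey)
    data.frame(triangle_id = triangles$triangle_id[out$idx],
               year = out$year,
               temperature_prev_day = temp_u[m],
               precipitation_prev_day = prec_u[m])
  })
}

#' Draw negative-binomial track counts for censused transect-years
#'
#' Counts follow the NB2 distribution with mean
#' `mu = length_km * exp(eta)` and variance `mu + mu^2 / alpha`, where
#' `eta = beta' x_scaled + w(s, t)` combines the 2-SD-scaled covariates
#' and the latent field, and `log(length_km)` is the offset.
#'
#' @param skeletons Data frame of censused transect-years containing the
#'   raw covariate columns named in `config$beta` (besides the intercept)
#'   plus `length_km`.
#' @param field Numeric vector: latent field value for each row (0 for
#'   none).
#' @param config A [gen_config()]; `beta` and `nb_overdispersion` are used.
#' @param seed Optional integer seed.
#' @return `skeletons` with columns `squirrel_tracks` and `mu_true`
#'   appended; the scaling used is attached as attribute `scaling`.
#' @export
simulate_counts <- function(skeletons, field, config, seed = NULL) {
  covars <- setdiff(names(config$beta), "intercept")
  missing_cols <- setdiff(covars, names(skeletons))
  if (length(missing_cols)) {
    stop_snowsync("missing covariate column(s): ",
                  paste(missing_cols, collapse = ", "),
                  class = "snowsync_missing_covariate_error")
  }
  for (cn in covars) {
    bad <- which(is.na(skeletons[[cn]]))
    if (length(bad)) {
      stop_snowsync("missing covariate '", cn, "' for triangle ",
                    skeletons$triangle_id[bad[1L]], ", year ",
                    skeletons$year[bad[1L]],
                    class = "snowsync_missing_covariate_error")
    }
  }
  X <- matrix(0, nrow(skeletons), length(covars),
              dimnames = list(NULL, covars))
  scaling <- list()
  for (cn in covars) {
    v <- skeletons[[cn]]
    if (cn == "triangle_type") {
      v <- as.numeric(skeletons$triangle_type == "wildlife")
      scaling[[cn]] <- c(center = 0, scale = 1)
    } else {
      sc <- two_sd_scaling(v)
      scaling[[cn]] <- sc
      v <- (v - sc["center"]) / sc["scale"]
    }
    X[, cn] <- v
  }
  eta <- config$beta[["intercept"]] + drop(X %*% config$beta[covars]) + field
  mu <- skeletons$length_km * exp(eta)
  out <- skeletons
  out$mu_true <- mu
  out$squirrel_tracks <- with_seed(seed, {
    stats::rnbinom(length(mu), size = config$nb_overdispersion, mu = mu)
  })
  attr(out, "scaling") <- scaling
  out
}

#' Simulate a complete synthetic snow-track census study
#'
#' End-to-end data generation with the structure the spatiotemporal
#' analysis assumes: transect network, raptor territories, masting cone
#' series at research forests, previous-day weather, an (optional) shared
#' habitat surface, an independent log-Gaussian pine-marten track process,
#' a separable Matern x AR1 latent field, and negative-binomial red
#' squirrel counts driven by the 2-SD-scaled covariates. The `cone_index`
#' covariate driving the counts is the *true* generative cone surface of
#' the preceding autumn evaluated at the transects; downstream analysis
#' may instead interpolate the noisy site observations via
#' [interpolate_cone_surface()].
#'
#' @param config A [gen_config()].
#' @param region A [study_region()].
#' @param kernel A [kernel_params()] used for the generative predation
#'   covariate.
#' @return A list of class `snowsync_dataset` with elements `census`
#'   (one row per censused transect-year with counts, weather and the
#'   generative covariates), `nests`, `cones`, `triangles`, and `truth`
#'   (config echo plus realised field and scaling).
#' @export
simulate_dataset <- function(config = gen_config(), region = study_region(),
                             kernel = kernel_params()) {
  skel <- generate_region_and_triangles(config, region)
  tri <- unique(skel[, c("triangle_id", "triangle_type", "x_km", "y_km",
                         "length_km")])
  years <- sort(unique(skel$year))
  # nest summers: need up to max_lag_years before the first census winter
  nest_years <- (min(years) - kernel$max_lag_years):(max(years) - 1L)
  nests <- simulate_nests(region, nest_years,
                          config$nest_density_per_100km2,
                          config$nest_persistence_prob,
                          seed = child_seed(config$seed, "nests"))
  cone_sites <- with_seed(child_seed(config$seed, "cone_sites"), {
    data.frame(site_id = sprintf("C%03d", seq_len(config$n_cone_sites)),
               x_km = stats::runif(config$n_cone_sites, 0, region$width_km),
               y_km = stats::runif(config$n_cone_sites, 0, region$height_km))
  })
  cone_years <- c(min(years) - 1L, years)  # autumns preceding each winter
  failure <- intersect(config$failure_years, cone_years)
  cones <- simulate_cone_series(cone_sites, cone_years, failure, region,
                                missing_frac = config$cone_missing_frac,
                                seed = child_seed(config$seed, "cones"))
  # true cone surface at the transects (previous autumn = year - 1):
  # same year effect and smooth surface, no site noise
  cone_truth <- simulate_cone_series(
    data.frame(site_id = tri$triangle_id, x_km = tri$x_km, y_km = tri$y_km),
    cone_years, failure, region, site_sdlog = 0, missing_frac = 0,
    seed = child_seed(config$seed, "cones"))

  census <- skel[skel$censused, , drop = FALSE]
  weather <- simulate_weather(tri, years, region,
                              seed = child_seed(config$seed, "weather"))
  census <- merge(census, weather, by = c("triangle_id", "year"))

  kv <- kernel_covariate(census, nests, kernel)
  census <- merge(census, kv, by = c("triangle_id", "year"))
  names(census)[names(census) == "kernel_value"] <- "goshawk_kernel"

  ct_key <- paste(cone_truth$site_id, cone_truth$year)
  census$cone_index <- cone_truth$cones_per_tree[
    match(paste(census$triangle_id, census$year - 1L), ct_key)]

  idx_site <- match(census$triangle_id, tri$triangle_id)
  idx_year <- match(census$year, years)
  habitat <- if (config$habitat_sd > 0) {
    simulate_matern_ar1_field(tri$x_km, tri$y_km, 1L, range_km = 150,
                              field_sd = config$habitat_sd, rho = 0,
                              seed = child_seed(config$seed, "habitat"))[, 1L]
  } else rep(0, nrow(tri))

  # independent log-Gaussian marten intensity sharing only the habitat
  census$marten_tracks <- with_seed(child_seed(config$seed, "marten"), {
    eta_m <- log(0.35) + habitat[idx_site] +
      stats::rnorm(nrow(census), 0, 0.4)
    stats::rnbinom(nrow(census), size = 1.5,
                   mu = census$length_km * exp(eta_m))
  })
  census$marten_density <- census$marten_tracks / census$length_km

  W <- simulate_matern_ar1_field(tri$x_km, tri$y_km, length(years),
                                 config$matern_range_km, config$field_sd,
                                 config$ar1_rho,
                                 seed = child_seed(config$seed, "field"))
  field_at_obs <- W[cbind(idx_site, idx_year)] + habitat[idx_site]
  census$temperature <- census$temperature_prev_day
  census$precipitation <- census$precipitation_prev_day
  census <- simulate_counts(census, field_at_obs, config,
                            seed = child_seed(config$seed, "counts"))
  census <- census[order(census$triangle_id, census$year), ]
  rownames(census) <- NULL

  structure(list(census = census, nests = nests, cones = cones,
                 triangles = tri,
                 truth = list(config = config, region = region,
                              kernel = kernel, field = W,
                              habitat = habitat, years = years,
                              scaling = attr(census, "scaling"))),
            class = "snowsync_dataset")
}

#' @export
print.snowsync_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic snow-track study: %d transects, %d censused transect-years, %d nest records, %d cone records\n",
    nrow(x$triangles), nrow(x$census), nrow(x$nests), nrow(x$cones)))
  invisible(x)
}

#' Write a synthetic dataset to delimited text files
#'
#' Writes `census.csv`, `nests.csv`, `cones.csv` (headered CSV, UTF-8,
#' '.' decimal separator) and `truth.json` (generative configuration echo)
#' into `dir`.
#'
#' @param dataset A `snowsync_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "snowsync_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$census, file.path(dir, "census.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$nests, file.path(dir, "nests.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$cones, file.path(dir, "cones.csv"),
                   row.names = FALSE)
  cfg <- dataset$truth$config
  jsonlite::write_json(cfg[setdiff(names(cfg), character())],
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
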
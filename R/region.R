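#' Define a rectangular planar study region
#'
#' The study region is a rectangle in planar km coordinates (x east, y
#' north) standing in for a national projected grid. The horizontal line
#' `southern_cut_y_km` separates the "southern" part of the region, where
#' masting failure-year rules apply and where farmland census triangles
#' concentrate, from the rest.
#'
#' @param width_km,height_km Positive extents in km.
#' @param southern_cut_y_km y-coordinate of the southern boundary rule,
#'   in `[0, height_km]`. Default places it at 40% of the height.
#' @return An object of class `study_region`.
#' @export
#' @examples
#' study_region(600, 1100, 440)
study_region <- function(width_km = 600, height_km = 1100,
                         southern_cut_y_km = 0.4 * height_km) {
  if (!is.numeric(width_km) || !is.numeric(height_km) ||
      width_km <= 0 || height_km <= 0) {
    stop_snowsync("region extents must be positive",
                  class = "snowsync_config_error")
  }
  if (southern_cut_y_km < 0 || southern_cut_y_km > height_km) {
    stop_snowsync("southern_cut_y_km must lie within [0, height_km]",
                  class = "snowsync_config_error")
  }
  structure(list(width_km = width_km, height_km = height_km,
                 southern_cut_y_km = southern_cut_y_km),
            class = "study_region")
}

#' @export
print.study_region <- function(x, ...) {
  cat(sprintf("Study region: %.0f x %.0f km, southern cut at y = %.0f km\n",
              x$width_km, x$height_km, x$southern_cut_y_km))
  invisible(x)
}

#' Generative configuration for the synthetic census simulator
#'
#' Collects every parameter of the synthetic data-generating process. The
#' defaults emulate the Finnish snow-track monitoring scheme: ~1,900
#' triangles of which roughly 550 are censused in a given winter, 29
#' census years, farmland ("field") triangles concentrated in the
#' south-west, a masting cone resource with regional failure years, raptor
#' nest density of ~3 territories per 100 km2, and track counts that are
#' negative-binomial around a log-linear covariate combination plus a
#' separable Matern(nu = 1) x AR1 latent field with the triangle length as
#' offset. Regression weights default to posterior means estimated on the
#' full-scale Finnish monitoring data (covariates on the 2-SD-scaled
#' scale), and the field hyperparameters default to the range and
#' temporal correlation estimated there.
#'
#' @param beta Named numeric vector of log-scale regression weights for the
#'   scaled covariates. Names must come from
#'   `c("intercept", "marten_density", "goshawk_kernel", "cone_index",
#'   "triangle_type", "temperature", "precipitation")`.
#' @param matern_range_km Spatial range (km) of the latent field.
#' @param field_sd Marginal SD of the latent field.
#' @param ar1_rho AR1 coefficient of the latent field, in (-1, 1).
#' @param nb_overdispersion NB2 overdispersion `alpha`
#'   (variance = mu + mu^2/alpha).
#' @param n_wildlife,n_field Numbers of 12-km forest and 6-km farmland
#'   triangles.
#' @param n_years Number of census winters.
#' @param start_year First census year.
#' @param census_prob_per_year Probability that a triangle is censused in
#'   a given winter.
#' @param failure_years Calendar years of total cone-crop failure.
#' @param nest_density_per_100km2 Raptor territory density.
#' @param nest_persistence_prob Year-to-year territory occupancy
#'   persistence probability.
#' @param n_cone_sites Number of cone-count research forests.
#' @param cone_missing_frac Fraction of southern cone observations set
#'   missing in failure years (exercises imputation).
#' @param habitat_sd SD of a shared smooth habitat surface entering both
#'   species' log-intensities (0 disables it).
#' @param seed Integer seed.
#' @return An object of class `gen_config` (a validated list).
#' @export
gen_config <- function(beta = c(intercept = -1.73,
                                marten_density = 0.22,
                                goshawk_kernel = 0.11,
                                cone_index = 0.37,
                                triangle_type = -0.57,
                                temperature = 0.30,
                                precipitation = -0.24),
                       matern_range_km = 655,
                       field_sd = 1,
                       ar1_rho = 0.99,
                       nb_overdispersion = 2,
                       n_wildlife = 1400,
                       n_field = 500,
                       n_years = 29,
                       start_year = 1989,
                       census_prob_per_year = 0.29,
                       failure_years = c(1990, 1994, 1997, 1999, 2001,
                                         2005, 2009, 2013),
                       nest_density_per_100km2 = 3,
                       nest_persistence_prob = 0.9,
                       n_cone_sites = 92,
                       cone_missing_frac = 0.3,
                       habitat_sd = 0.3,
                       seed = 1L) {
  vocab <- c("intercept", "marten_density", "goshawk_kernel", "cone_index",
             "triangle_type", "temperature", "precipitation")
  if (is.null(names(beta)) || !all(names(beta) %in% vocab)) {
    stop_snowsync("beta names must be in the design-matrix vocabulary: ",
                  paste(vocab, collapse = ", "),
                  class = "snowsync_config_error")
  }
  if (n_wildlife < 0 || n_field < 0 || n_wildlife + n_field < 2) {
    stop_snowsync("need at least two triangles in total",
                  class = "snowsync_config_error")
  }
  if (matern_range_km <= 0 || field_sd < 0 || nb_overdispersion <= 0 ||
      abs(ar1_rho) >= 1) {
    stop_snowsync("field/overdispersion parameters out of range",
                  class = "snowsync_config_error")
  }
  if (census_prob_per_year < 0 || census_prob_per_year > 1) {
    stop_snowsync("census_prob_per_year must be a probability",
                  class = "snowsync_config_error")
  }
  if (n_years < 1 || nest_density_per_100km2 <= 0) {
    stop_snowsync("n_years and nest density must be positive",
                  class = "snowsync_config_error")
  }
  structure(list(beta = beta, matern_range_km = matern_range_km,
                 field_sd = field_sd, ar1_rho = ar1_rho,
                 nb_overdispersion = nb_overdispersion,
                 n_wildlife = as.integer(n_wildlife),
                 n_field = as.integer(n_field),
                 n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 census_prob_per_year = census_prob_per_year,
                 failure_years = as.integer(failure_years),
                 nest_density_per_100km2 = nest_density_per_100km2,
                 nest_persistence_prob = nest_persistence_prob,
                 n_cone_sites = as.integer(n_cone_sites),
                 cone_missing_frac = cone_missing_frac,
                 habitat_sd = habitat_sd,
                 seed = as.integer(seed)),
            class = "gen_config")
}

#' @export
print.gen_config <- function(x, ...) {
  cat("Synthetic census configuration\n")
  cat(sprintf("  triangles: %d wildlife (12 km) + %d field (6 km)\n",
              x$n_wildlife, x$n_field))
  cat(sprintf("  years: %d starting %d, census prob %.2f/yr\n",
              x$n_years, x$start_year, x$census_prob_per_year))
  cat(sprintf("  field: range %.0f km, sd %.2f, rho %.2f; NB alpha %.2f\n",
              x$matern_range_km, x$field_sd, x$ar1_rho, x$nb_overdispersion))
  cat("  weights:", paste(sprintf("%s=%.2f", names(x$beta), x$beta),
                          collapse = ", "), "\n")
  invisible(x)
}
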
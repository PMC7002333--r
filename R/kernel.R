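#' Parameters of the flat-top Gaussian predation-pressure kernel
#'
#' The predation-pressure index around an occupied raptor nest is a radial
#' flat-top Gaussian: height 1 out to `flat_top_km`, then a Gaussian decay
#' with standard deviation `sd_km`, truncated to 0 beyond `cutoff_km`.
#' Contributions from nests occupied in earlier summers decay by
#' `yearly_decay` per year of lag and vanish beyond `max_lag_years`.
#'
#' @param flat_top_km Plateau radius in km.
#' @param sd_km Gaussian SD in km beyond the plateau.
#' @param cutoff_km Hard truncation distance in km.
#' @param yearly_decay Fractional decline per year of nest-to-census lag.
#' @param max_lag_years Maximum lag (years) at which a nest contributes.
#' @param combine_rule How overlapping nest contributions combine:
#'   `"max"` (default) or `"complement_product"` (`1 - prod(1 - c_i)`).
#' @param symmetric_window If `TRUE`, nests occupied after the census year
#'   also contribute (lag taken in absolute value). Default `FALSE`: only
#'   past summers exert predation pressure.
#' @return An object of class `kernel_params`.
#' @export
#' @examples
#' kernel_params()                       # the selected shape: 2.5 km, SD 4
#' kernel_params(flat_top_km = 1, sd_km = 2)
kernel_params <- function(flat_top_km = 2.5, sd_km = 4, cutoff_km = 10,
                          yearly_decay = 0.10, max_lag_years = 15,
                          combine_rule = c("max", "complement_product"),
                          symmetric_window = FALSE) {
  combine_rule <- match.arg(combine_rule)
  if (flat_top_km <= 0 || flat_top_km >= cutoff_km) {
    stop_snowsync("need 0 < flat_top_km < cutoff_km",
                  class = "snowsync_config_error")
  }
  if (sd_km <= 0 || yearly_decay < 0 || yearly_decay >= 1 ||
      max_lag_years < 1) {
    stop_snowsync("invalid kernel parameters", class = "snowsync_config_error")
  }
  structure(list(flat_top_km = flat_top_km, sd_km = sd_km,
                 cutoff_km = cutoff_km, yearly_decay = yearly_decay,
                 max_lag_years = as.integer(max_lag_years),
                 combine_rule = combine_rule,
                 symmetric_window = symmetric_window),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf(
    "Flat-top Gaussian kernel: plateau %.1f km, SD %.1f km, cutoff %.0f km\n",
    x$flat_top_km, x$sd_km, x$cutoff_km))
  cat(sprintf("  occupancy decay %.0f%%/yr over %d yr window, combine = %s\n",
              100 * x$yearly_decay, x$max_lag_years, x$combine_rule))
  invisible(x)
}

#' Height of the flat-top Gaussian kernel at a distance
#'
#' @param distance_km Non-negative distances in km (vectorised).
#' @param params A [kernel_params()] object.
#' @return Heights in `[0, 1]`: 1 on the plateau,
#'   `exp(-(d - flat_top)^2 / (2 sd^2))` between plateau and cutoff, 0
#'   beyond the cutoff.
#' @export
#' @examples
#' p <- kernel_params()
#' kernel_height(c(1, 2.5, 6.5, 12), p)  # 1, 1, exp(-0.5), 0
kernel_height <- function(distance_km, params = kernel_params()) {
  if (any(distance_km < 0)) {
    stop_snowsync("distance must be non-negative",
                  class = "snowsync_domain_error")
  }
  h <- exp(-(distance_km - params$flat_top_km)^2 / (2 * params$sd_km^2))
  h[distance_km <= params$flat_top_km] <- 1
  h[distance_km > params$cutoff_km] <- 0
  h
}

#' Temporal decay weight for a nest occupied `lag` years before a census
#'
#' A nest occupied in the summer immediately preceding the winter census
#' (lag 1) carries full weight; each further year of lag multiplies the
#' weight by `1 - yearly_decay`, i.e. weight `(1 - decay)^(lag - 1)`. Lags
#' beyond `max_lag_years` contribute 0. Non-positive lags (same-winter or
#' future nests) contribute 0 with a warning unless `symmetric_window` is
#' set, in which case the absolute lag is used.
#'
#' @param census_year,nest_year Integer years (vectorised).
#' @param params A [kernel_params()] object.
#' @return Weights in `[0, 1]`.
#' @export
#' @examples
#' p <- kernel_params()
#' temporal_weight(2005, 2004, p)  # 1
#' temporal_weight(2005, 2002, p)  # 0.9^2
temporal_weight <- function(census_year, nest_year, params = kernel_params()) {
  lag <- census_year - nest_year
  if (params$symmetric_window) {
    lag <- abs(lag)
    lag[lag == 0] <- 1L  # same-year occupancy treated as adjacent summer
  } else if (any(lag <= 0)) {
    warning("nest records with non-positive lag contribute no weight")
  }
  w <- (1 - params$yearly_decay)^(lag - 1)
  w[lag <= 0 | lag > params$max_lag_years] <- 0
  w
}

#' Predation-pressure kernel value at one transect
#'
#' Combines the contributions `kernel_height(d_i) * temporal_weight(lag_i)`
#' of all occupied nest records within the distance cutoff and lag window,
#' by maximum (default) or complement product. The result lies in
#' `[0, 1]`; 0 means no occupied nest within reach.
#'
#' @param x_km,y_km Transect coordinates.
#' @param census_year Census winter year.
#' @param nests Data frame with columns `x_km`, `y_km`, `year`, `occupied`.
#' @param params A [kernel_params()] object.
#' @return A single value in `[0, 1]`.
#' @export
triangle_kernel_value <- function(x_km, y_km, census_year, nests,
                                  params = kernel_params()) {
  occ <- nests[nests$occupied, , drop = FALSE]
  if (nrow(occ) == 0L) return(0)
  d <- sqrt((occ$x_km - x_km)^2 + (occ$y_km - y_km)^2)
  keep <- d <= params$cutoff_km
  if (!any(keep)) return(0)
  occ <- occ[keep, , drop = FALSE]
  h <- kernel_height(d[keep], params)
  tw <- suppressWarnings(temporal_weight(census_year, occ$year, params))
  contrib <- h * tw
  combine_contributions(contrib, params$combine_rule)
}

combine_contributions <- function(contrib, rule) {
  if (length(contrib) == 0L) return(0)
  if (rule == "max") max(contrib) else 1 - prod(1 - contrib)
}

#' Predation-pressure covariate for every censused transect-year
#'
#' Vectorised construction of the kernel covariate over a census table.
#'
#' @param census Data frame with columns `triangle_id`, `x_km`, `y_km`,
#'   `year` (one row per transect-year; extra columns ignored).
#' @param nests Data frame of nest records (`x_km`, `y_km`, `year`,
#'   `occupied`).
#' @param params A [kernel_params()] object.
#' @return A data frame `triangle_id`, `year`, `kernel_value`.
#' @export
kernel_covariate <- function(census, nests, params = kernel_params()) {
  occ <- nests[nests$occupied, , drop = FALSE]
  out <- data.frame(triangle_id = census$triangle_id, year = census$year,
                    kernel_value = 0)
  if (nrow(occ) == 0L) return(out)
  tri <- unique(census[, c("triangle_id", "x_km", "y_km")])
  # territories recur across years at fixed coordinates: hash them into
  # cutoff-sized cells so each transect only touches nearby nests
  terr_key <- paste(occ$x_km, occ$y_km)
  terr <- which(!duplicated(terr_key))
  occ_by_terr <- split(seq_len(nrow(occ)), match(terr_key, terr_key[terr]))
  cellsize <- params$cutoff_km
  cell_of <- function(x, y) paste(floor(x / cellsize), floor(y / cellsize))
  terr_cells <- split(seq_along(terr), cell_of(occ$x_km[terr], occ$y_km[terr]))
  rows_by_tri <- split(seq_len(nrow(census)),
                       match(census$triangle_id, tri$triangle_id))
  vals <- numeric(nrow(census))
  for (i in seq_len(nrow(tri))) {
    cx <- floor(tri$x_km[i] / cellsize)
    cy <- floor(tri$y_km[i] / cellsize)
    neigh <- as.vector(outer(cx + (-1:1), cy + (-1:1), paste))
    cand <- unlist(terr_cells[neigh], use.names = FALSE)
    if (length(cand) == 0L) next
    tx <- occ$x_km[terr[cand]]
    ty <- occ$y_km[terr[cand]]
    d <- sqrt((tx - tri$x_km[i])^2 + (ty - tri$y_km[i])^2)
    near <- cand[d <= params$cutoff_km]
    if (length(near) == 0L) next
    recs <- unlist(occ_by_terr[as.character(near)], use.names = FALSE)
    h <- kernel_height(
      sqrt((occ$x_km[recs] - tri$x_km[i])^2 +
             (occ$y_km[recs] - tri$y_km[i])^2), params)
    ny <- occ$year[recs]
    for (r in rows_by_tri[[as.character(i)]] %||% integer()) {
      tw <- suppressWarnings(temporal_weight(census$year[r], ny, params))
      vals[r] <- combine_contributions(h * tw, params$combine_rule)
    }
  }
  out$kernel_value <- vals
  out
}

#' Select the kernel shape by AIC over a grid of candidates
#'
#' For each candidate `(flat_top_km, sd_km)` pair, the kernel covariate is
#' computed at every censused transect-year and an independent
#' negative-binomial regression of the squirrel track count on that single
#' covariate (with the log transect length as offset) is fitted; candidates
#' are ranked by AIC. The default grid crosses SDs 1-4 km with plateau
#' radii 0.5-2.5 km in 0.5-km steps (20 candidates).
#'
#' @param census Census data frame with columns `triangle_id`, `x_km`,
#'   `y_km`, `year`, `length_km`, `squirrel_tracks`, and optionally
#'   `censused` (non-censused rows are dropped).
#' @param nests Nest records data frame.
#' @param flat_top_grid,sd_grid Candidate plateau radii and SDs (km).
#' @param base_params Template [kernel_params()] supplying cutoff, decay
#'   and combine rule for every candidate.
#' @return An object of class `kernel_selection`: a list with `table`
#'   (one row per candidate with AIC), `best` ([kernel_params()]) and
#'   `delta_to_second` (AIC gap to the runner-up).
#' @export
select_kernel_params <- function(census, nests,
                                 flat_top_grid = c(0.5, 1, 1.5, 2, 2.5),
                                 sd_grid = 1:4,
                                 base_params = kernel_params()) {
  grid <- expand.grid(flat_top_km = flat_top_grid, sd_km = sd_grid)
  if (nrow(grid) < 2L) {
    stop_snowsync("need at least two kernel candidates",
                  class = "snowsync_config_error")
  }
  if (!is.null(census$censused)) census <- census[census$censused, , drop = FALSE]
  aic <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- kernel_params(flat_top_km = grid$flat_top_km[i],
                       sd_km = grid$sd_km[i],
                       cutoff_km = base_params$cutoff_km,
                       yearly_decay = base_params$yearly_decay,
                       max_lag_years = base_params$max_lag_years,
                       combine_rule = base_params$combine_rule,
                       symmetric_window = base_params$symmetric_window)
    kv <- kernel_covariate(census, nests, p)$kernel_value
    if (stats::var(kv) == 0) {
      stop_snowsync("kernel covariate is constant for candidate (",
                    grid$flat_top_km[i], ", ", grid$sd_km[i],
                    "); no nests within reach?",
                    class = "snowsync_degenerate_error")
    }
    fit <- MASS::glm.nb(census$squirrel_tracks ~ kv +
                          offset(log(census$length_km)))
    aic[i] <- stats::AIC(fit)
  }
  grid$aic <- aic
  ord <- order(grid$aic)
  best_row <- grid[ord[1L], ]
  best <- kernel_params(flat_top_km = best_row$flat_top_km,
                        sd_km = best_row$sd_km,
                        cutoff_km = base_params$cutoff_km,
                        yearly_decay = base_params$yearly_decay,
                        max_lag_years = base_params$max_lag_years,
                        combine_rule = base_params$combine_rule,
                        symmetric_window = base_params$symmetric_window)
  structure(list(table = grid[ord, ], best = best,
                 delta_to_second = grid$aic[ord[2L]] - grid$aic[ord[1L]]),
            class = "kernel_selection")
}

#' @export
print.kernel_selection <- function(x, ...) {
  cat(sprintf(
    "Kernel selection over %d candidates: best plateau %.1f km, SD %.1f km (delta AIC to runner-up %.2f)\n",
    nrow(x$table), x$best$flat_top_km, x$best$sd_km, x$delta_to_second))
  invisible(x)
}
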
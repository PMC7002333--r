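#' Snow-track density per km of census line
#'
#' @param count Non-negative track count(s).
#' @param length_km Positive transect length(s) in km.
#' @return Tracks per km.
#' @export
#' @examples
#' track_density(24, 12)  # 2 tracks/km
track_density <- function(count, length_km) {
  if (any(length_km <= 0)) {
    stop_snowsync("transect length must be positive",
                  class = "snowsync_domain_error")
  }
  count / length_km
}

# 2-SD scaling statistics of a numeric covariate: centre at the mean,
# scale by twice the SD so the weight is comparable to a binary indicator's.
two_sd_scaling <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop_snowsync("cannot 2-SD-scale a constant column",
                  class = "snowsync_scaling_error")
  }
  c(center = mean(x), scale = 2 * s)
}

#' Apply / invert 2-SD covariate scaling
#'
#' @param x Numeric vector.
#' @param scaling Named vector `c(center, scale)` from the design metadata.
#' @return Scaled (`scale_two_sd`) or unscaled (`unscale_two_sd`) values.
#' @export
scale_two_sd <- function(x, scaling = two_sd_scaling(x)) {
  (x - scaling[["center"]]) / scaling[["scale"]]
}

#' @rdname scale_two_sd
#' @export
unscale_two_sd <- function(x, scaling) {
  x * scaling[["scale"]] + scaling[["center"]]
}

#' Replace missing southern cone records by zero in crop-failure years
#'
#' In total-failure years a missing cone census at a southern site implies
#' the census was skipped for want of cones; those records are imputed as
#' exact zeros. All other missing values are kept missing and present
#' values are never altered.
#'
#' @param cones Data frame with `y_km`, `year`, `cones_per_tree`.
#' @param failure_years Integer vector of failure years (defaults to the
#'   documented failure years of the monitoring period).
#' @param southern_cut_y_km y-coordinate below which a site is "southern".
#' @return `cones` with the imputation applied.
#' @export
impute_failure_zeros <- function(cones,
                                 failure_years = c(1990, 1994, 1997, 1999,
                                                   2001, 2005, 2009, 2013),
                                 southern_cut_y_km) {
  idx <- is.na(cones$cones_per_tree) & cones$year %in% failure_years &
    cones$y_km < southern_cut_y_km
  cones$cones_per_tree[idx] <- 0
  cones
}

#' Thin-plate-spline interpolation of a cone-crop surface
#'
#' Fits a thin-plate spline to one year's cone observations and evaluates
#' it at target coordinates. The default engine is a thin-plate regression
#' spline with smoothing chosen by generalised cross-validation
#' (`mgcv::gam`); `method = "exact"` solves the classical interpolating
#' thin-plate system (radial basis `r^2 log r` plus an affine part), which
#' reproduces the observations and any affine trend exactly. Missing
#' observations are excluded from the fit; negative predictions are
#' clamped to zero.
#'
#' @param cones Data frame with `x_km`, `y_km`, `cones_per_tree` for one
#'   year (rows with missing values are dropped).
#' @param targets Data frame with `x_km`, `y_km`.
#' @param method `"gcv"` (default) or `"exact"`.
#' @param year Optional label used in error messages.
#' @return Numeric vector of interpolated values at the targets.
#' @export
interpolate_cone_surface <- function(cones, targets,
                                     method = c("gcv", "exact"),
                                     year = NULL) {
  method <- match.arg(method)
  obs <- cones[!is.na(cones$cones_per_tree), , drop = FALSE]
  ylab <- if (is.null(year)) "" else paste0(" in year ", year)
  if (nrow(obs) < 4L) {
    stop_snowsync("need at least 4 cone sites with data", ylab,
                  class = "snowsync_interpolation_error")
  }
  P <- cbind(1, obs$x_km, obs$y_km)
  if (qr(P)$rank < 3L) {
    stop_snowsync("cone sites are collinear", ylab,
                  class = "snowsync_interpolation_error")
  }
  v <- obs$cones_per_tree
  if (method == "exact") {
    pred <- tps_exact(obs$x_km, obs$y_km, v, targets$x_km, targets$y_km)
  } else {
    if (stats::var(v) == 0) {
      pred <- rep(v[1L], nrow(targets))
    } else {
      k <- min(nrow(obs) - 1L, 50L)
      fit <- mgcv::gam(v ~ s(x, y, bs = "tp", k = k),
                       data = data.frame(x = obs$x_km, y = obs$y_km, v = v),
                       method = "GCV.Cp")
      pred <- as.numeric(stats::predict(
        fit, newdata = data.frame(x = targets$x_km, y = targets$y_km)))
    }
  }
  pmax(pred, 0)
}

# Classical interpolating thin-plate spline in 2D:
# f(p) = sum_i c_i phi(|p - p_i|) + a0 + a1 x + a2 y,  phi(r) = r^2 log r,
# with orthogonality constraints on c; lambda = 0 (exact interpolation).
tps_exact <- function(x, y, v, tx, ty) {
  n <- length(x)
  phi <- function(r2) {
    out <- numeric(length(r2))
    pos <- r2 > 0
    out[pos] <- 0.5 * r2[pos] * log(r2[pos])  # r^2 log r
    out
  }
  D2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  K <- phi(as.vector(D2)); dim(K) <- dim(D2)
  P <- cbind(1, x, y)
  A <- rbind(cbind(K + diag(1e-9 * mean(diag(K) + 1), n), P),
             cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(A, c(v, 0, 0, 0))
  cc <- sol[1:n]; a <- sol[n + 1:3]
  T2 <- outer(tx, x, "-")^2 + outer(ty, y, "-")^2
  G <- phi(as.vector(T2)); dim(G) <- dim(T2)
  drop(G %*% cc) + a[1L] + a[2L] * tx + a[3L] * ty
}

#' Build the cone-index covariate for every censused transect-year
#'
#' Applies failure-year zero imputation, then for each census winter
#' interpolates the previous autumn's cone surface at the transect
#' locations (the lag follows the phenology: cones are counted in autumn
#' of year y, censuses happen in mid-winter of year y + 1).
#'
#' @param census Census data frame (`triangle_id`, `x_km`, `y_km`, `year`).
#' @param cones Cone observations (`site_id`, `x_km`, `y_km`, `year`,
#'   `cones_per_tree`).
#' @param failure_years,southern_cut_y_km Passed to
#'   [impute_failure_zeros()].
#' @param method Interpolation engine, see [interpolate_cone_surface()].
#' @return Data frame `triangle_id`, `year`, `cone_index`.
#' @export
build_cone_index <- function(census, cones, failure_years,
                             southern_cut_y_km, method = "gcv") {
  cones <- impute_failure_zeros(cones, failure_years, southern_cut_y_km)
  out <- data.frame(triangle_id = census$triangle_id, year = census$year,
                    cone_index = NA_real_)
  for (yr in sort(unique(census$year))) {
    rows <- which(census$year == yr)
    cy <- cones[cones$year == yr - 1L, , drop = FALSE]
    out$cone_index[rows] <- interpolate_cone_surface(
      cy, census[rows, c("x_km", "y_km")], method = method, year = yr - 1L)
  }
  out
}

#' Assemble the scaled design matrix for the spatiotemporal model
#'
#' Builds one row per censused transect-year with the model covariates:
#' current-winter pine-marten track density, the previous-summer
#' predation kernel, the previous-autumn cone index, the triangle-type
#' indicator (wildlife = 1, field = 0, left unscaled), previous-day
#' temperature and precipitation, and optionally the planar coordinates
#' and their product. Rows with any missing included covariate are
#' dropped and logged; numeric covariates are centred and divided by two
#' standard deviations (computed on the retained rows) so their weights
#' are comparable to the binary indicator's.
#'
#' @param census Census data frame; non-censused rows (if flagged) are
#'   removed. Must carry `squirrel_tracks`, `length_km`, coordinates and
#'   either raw covariate columns or the pieces below.
#' @param kernel_covariate Optional data frame `triangle_id`, `year`,
#'   `kernel_value` (joined as `goshawk_kernel`).
#' @param cone_index Optional data frame `triangle_id`, `year`,
#'   `cone_index`.
#' @param covariates Character vector of covariate columns to include.
#' @param include_xy If `TRUE`, adds scaled `x`, `y` and `xy` columns.
#' @param marten_lag If `TRUE`, also computes (but does not include) the
#'   previous-winter marten density as column `marten_density_lag1`.
#' @return An object of class `design_matrix`: list with `df` (the
#'   analysis rows incl. scaled covariates), `covariates`, `offset`
#'   (log length), `scaling` (per-column centre/scale), `drops` (ledger
#'   of excluded rows with reasons).
#' @export
assemble_design <- function(census, kernel_covariate = NULL,
                            cone_index = NULL,
                            covariates = c("marten_density",
                                           "goshawk_kernel", "cone_index",
                                           "triangle_type", "temperature",
                                           "precipitation"),
                            include_xy = FALSE, marten_lag = FALSE) {
  df <- census
  if (!is.null(df$censused)) df <- df[df$censused, , drop = FALSE]
  if (!is.null(kernel_covariate)) {
    kc <- kernel_covariate
    names(kc)[names(kc) == "kernel_value"] <- "goshawk_kernel"
    df$goshawk_kernel <- NULL
    df <- merge(df, kc, by = c("triangle_id", "year"), all.x = TRUE)
  }
  if (!is.null(cone_index)) {
    df$cone_index <- NULL
    df <- merge(df, cone_index, by = c("triangle_id", "year"), all.x = TRUE)
  }
  if (!"marten_density" %in% names(df) && "marten_tracks" %in% names(df)) {
    df$marten_density <- track_density(df$marten_tracks, df$length_km)
  }
  if ("temperature" %in% covariates && !"temperature" %in% names(df)) {
    df$temperature <- df$temperature_prev_day
  }
  if ("precipitation" %in% covariates && !"precipitation" %in% names(df)) {
    df$precipitation <- df$precipitation_prev_day
  }
  if (marten_lag) {
    key <- paste(df$triangle_id, df$year - 1L)
    df$marten_density_lag1 <-
      df$marten_density[match(key, paste(df$triangle_id, df$year))]
  }
  if (include_xy) {
    df$x <- df$x_km
    df$y <- df$y_km
    df$xy <- df$x_km * df$y_km
    covariates <- union(covariates, c("x", "y", "xy"))
  }
  missing_cols <- setdiff(covariates, names(df))
  if (length(missing_cols)) {
    stop_snowsync("design covariates not found: ",
                  paste(missing_cols, collapse = ", "),
                  class = "snowsync_assembly_error")
  }
  # complete-case filter with a drop ledger
  drops <- data.frame(triangle_id = character(), year = integer(),
                      reason = character())
  keep <- rep(TRUE, nrow(df))
  check_cols <- c(covariates, "squirrel_tracks")
  for (cn in check_cols) {
    bad <- is.na(df[[cn]]) & keep
    if (any(bad)) {
      drops <- rbind(drops, data.frame(triangle_id = df$triangle_id[bad],
                                       year = df$year[bad],
                                       reason = paste0("missing ", cn)))
      keep <- keep & !bad
    }
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop_snowsync("no complete-case rows left after filtering",
                  class = "snowsync_assembly_error")
  }
  scaling <- list()
  for (cn in covariates) {
    if (cn == "triangle_type") {
      df$triangle_type <- as.numeric(
        if (is.character(df$triangle_type) || is.factor(df$triangle_type))
          df$triangle_type == "wildlife" else df$triangle_type)
      scaling[[cn]] <- c(center = 0, scale = 1)
    } else {
      sc <- two_sd_scaling(df[[cn]])
      df[[cn]] <- scale_two_sd(df[[cn]], sc)
      scaling[[cn]] <- sc
    }
  }
  df <- df[order(df$triangle_id, df$year), ]
  rownames(df) <- NULL
  structure(list(df = df, covariates = covariates,
                 offset = log(df$length_km), scaling = scaling,
                 drops = drops),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d rows x %d covariates (%s); %d rows dropped\n",
              nrow(x$df), length(x$covariates),
              paste(x$covariates, collapse = ", "), nrow(x$drops)))
  invisible(x)
}
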
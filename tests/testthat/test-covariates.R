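test_that("track density standardises counts per km", {
  expect_identical(track_density(24, 12), 2)
  expect_identical(track_density(0, 6), 0)
  expect_identical(track_density(9, 6), 1.5)
  expect_error(track_density(3, 0), class = "snowsync_domain_error")
})

test_that("failure-year imputation only touches southern missing values", {
  cones <- data.frame(
    site_id = c("s1", "n1", "s2", "s3", "s4"),
    x_km = 1, y_km = c(100, 300, 100, 100, 100),
    year = c(1997, 1997, 1998, 1997, 1997),
    cones_per_tree = c(NA, NA, NA, 5, NA))
  out <- impute_failure_zeros(cones, southern_cut_y_km = 200)
  expect_identical(out$cones_per_tree[1], 0)        # southern, failure, NA
  expect_true(is.na(out$cones_per_tree[2]))         # northern stays NA
  expect_true(is.na(out$cones_per_tree[3]))         # 1998 not a failure year
  expect_identical(out$cones_per_tree[4], 5)        # present value untouched
  expect_identical(out$cones_per_tree[5], 0)
})

test_that("2-SD scaling gives mean 0, SD 0.5, and is invertible", {
  with_seed(31, {
    x <- rnorm(200, 3, 2)
    sc <- snowsync:::two_sd_scaling(x)
    z <- scale_two_sd(x, sc)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 0.5, tolerance = 1e-12)
    expect_equal(unscale_two_sd(z, sc), x, tolerance = 1e-12)
  })
  # a value of 7 in a column with mean 3 and SD 2 scales to 1
  expect_identical(scale_two_sd(7, c(center = 3, scale = 4)), 1)
  expect_error(snowsync:::two_sd_scaling(rep(2, 5)),
               class = "snowsync_scaling_error")
})

test_that("thin-plate interpolation reproduces constants, planes and data", {
  with_seed(17, {
    n <- 25
    obs <- data.frame(x_km = runif(n, 0, 100), y_km = runif(n, 0, 100))
    targets <- data.frame(x_km = runif(10, 10, 90), y_km = runif(10, 10, 90))
    # constant surface
    obs$cones_per_tree <- 4.2
    expect_equal(interpolate_cone_surface(obs, targets, "exact"),
                 rep(4.2, 10), tolerance = 1e-6)
    expect_equal(interpolate_cone_surface(obs, targets, "gcv"),
                 rep(4.2, 10), tolerance = 1e-6)
    # affine surface is in the spline's null space: recovered exactly
    obs$cones_per_tree <- 1 + 0.05 * obs$x_km + 0.02 * obs$y_km
    want <- 1 + 0.05 * targets$x_km + 0.02 * targets$y_km
    expect_equal(interpolate_cone_surface(obs, targets, "exact"), want,
                 tolerance = 1e-6)
    # exact mode interpolates the observations themselves
    obs$cones_per_tree <- abs(rnorm(n, 5, 2))
    at_sites <- interpolate_cone_surface(obs, obs[, c("x_km", "y_km")],
                                         "exact")
    expect_equal(at_sites, obs$cones_per_tree, tolerance = 1e-5)
    # permutation invariance in site order
    perm <- sample.int(n)
    expect_equal(interpolate_cone_surface(obs[perm, ], targets, "exact"),
                 interpolate_cone_surface(obs, targets, "exact"),
                 tolerance = 1e-8)
  })
})

test_that("degenerate interpolation inputs are rejected with the year", {
  targets <- data.frame(x_km = 1, y_km = 1)
  few <- data.frame(x_km = 1:3, y_km = 1:3, cones_per_tree = 1:3)
  expect_error(interpolate_cone_surface(few, targets, year = 1999),
               "1999", class = "snowsync_interpolation_error")
  coll <- data.frame(x_km = 1:6, y_km = 2 * (1:6), cones_per_tree = 1:6)
  expect_error(interpolate_cone_surface(coll, targets),
               class = "snowsync_interpolation_error")
})

test_that("the cone index uses the previous autumn's surface", {
  census <- data.frame(triangle_id = c("T1", "T2"), x_km = c(10, 20),
                       y_km = c(10, 20), year = 2001)
  xs <- seq(0, 90, 10)
  ys <- c(5, 40, 12, 33, 8, 27, 45, 3, 21, 36)
  cones <- data.frame(site_id = sprintf("C%d", 1:10),
                      x_km = xs, y_km = ys,
                      year = 2000,
                      cones_per_tree = 2 + 0.1 * xs)
  idx <- build_cone_index(census, cones, failure_years = integer(),
                          southern_cut_y_km = 25, method = "exact")
  # autumn-2000 plane evaluated at the transects
  expect_equal(idx$cone_index, 2 + 0.1 * c(10, 20), tolerance = 1e-6)
  # a census year whose preceding autumn has no data fails loudly
  census2 <- census
  census2$year <- 2000
  expect_error(build_cone_index(census2, cones, integer(), 25),
               class = "snowsync_interpolation_error")
})

test_that("design assembly scales, filters and logs drops", {
  ds <- small_dataset(9)
  census <- ds$census
  # hide some covariate values to exercise the drop ledger
  census$cone_index[1:3] <- NA
  d <- assemble_design(census)
  expect_identical(nrow(d$df) + nrow(d$drops), nrow(census))
  expect_identical(nrow(d$drops), 3L)
  expect_true(all(grepl("missing cone_index", d$drops$reason)))
  for (cn in setdiff(d$covariates, "triangle_type")) {
    expect_equal(mean(d$df[[cn]]), 0, tolerance = 1e-8)
    expect_equal(sd(d$df[[cn]]), 0.5, tolerance = 1e-8)
  }
  expect_true(all(d$df$triangle_type %in% c(0, 1)))
  expect_equal(d$offset, log(d$df$length_km))
  # scaling metadata reverses the transform
  sc <- d$scaling$temperature
  expect_equal(unscale_two_sd(d$df$temperature, sc),
               census$temperature[match(paste(d$df$triangle_id, d$df$year),
                                        paste(census$triangle_id,
                                              census$year))],
               tolerance = 1e-10)
})

test_that("optional coordinate covariates and the marten lag are built", {
  ds <- small_dataset(12)
  d <- assemble_design(ds$census, include_xy = TRUE, marten_lag = TRUE)
  expect_true(all(c("x", "y", "xy") %in% d$covariates))
  expect_equal(mean(d$df$xy), 0, tolerance = 1e-8)
  expect_true("marten_density_lag1" %in% names(d$df))
  expect_false("marten_density_lag1" %in% d$covariates)
  # lag-1 marten values line up with the previous winter where it exists
  i <- which(!is.na(d$df$marten_density_lag1))[1]
  prev <- ds$census[ds$census$triangle_id == d$df$triangle_id[i] &
                      ds$census$year == d$df$year[i] - 1, ]
  expect_equal(d$df$marten_density_lag1[i],
               prev$marten_tracks / prev$length_km)
})
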
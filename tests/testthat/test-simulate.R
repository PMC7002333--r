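test_that("triangle generation respects counts, lengths and placement", {
  cfg <- small_config(1, n_wildlife = 100, n_field = 50, n_years = 3)
  reg <- small_region()
  skel <- generate_region_and_triangles(cfg, reg)
  tri <- unique(skel[, c("triangle_id", "triangle_type", "length_km",
                         "y_km")])
  expect_identical(nrow(tri), 150L)
  expect_identical(sum(tri$triangle_type == "wildlife"), 100L)
  expect_identical(sum(tri$triangle_type == "field"), 50L)
  expect_true(all(tri$length_km[tri$triangle_type == "wildlife"] == 12))
  expect_true(all(tri$length_km[tri$triangle_type == "field"] == 6))
  south_frac <- mean(tri$y_km[tri$triangle_type == "field"] <
                       reg$southern_cut_y_km)
  expect_gte(south_frac, 0.8)
  # coordinates fixed across years
  expect_identical(nrow(unique(skel[, c("triangle_id", "x_km", "y_km")])),
                   150L)
  expect_error(gen_config(n_wildlife = 0, n_field = 1),
               class = "snowsync_config_error")
})

test_that("census probability 1 censuses every triangle every year", {
  cfg <- small_config(2, census_prob_per_year = 1)
  skel <- generate_region_and_triangles(cfg, small_region())
  expect_true(all(skel$censused))
})

test_that("censused-per-year counts behave as the binomial they should be", {
  # pooled over seeds and years: total censused ~ Binomial(N, p)
  p <- 0.3
  total <- 0L
  N <- 0L
  for (seed in 1:5) {
    cfg <- small_config(seed, n_wildlife = 150, n_field = 40, n_years = 4,
                        census_prob_per_year = p)
    skel <- generate_region_and_triangles(cfg, small_region())
    total <- total + sum(skel$censused)
    N <- N + nrow(skel)
  }
  expect_gt(stats::binom.test(total, N, p)$p.value, 0.001)
})

test_that("a 30% census probability over ~1,900 triangles censuses ~570", {
  cfg <- small_config(3, n_wildlife = 1400, n_field = 500, n_years = 2,
                      census_prob_per_year = 0.3)
  skel <- generate_region_and_triangles(cfg, study_region(600, 1100, 440))
  per_year <- tapply(skel$censused, skel$year, sum)
  expect_equal(mean(per_year), 570, tolerance = 0.1)
})

test_that("the latent field simulator has the Matern x AR1 covariance", {
  x <- c(0, 50, 400)
  y <- c(0, 0, 0)
  range_km <- 50
  # with rho = 0 the yearly slices are i.i.d. spatial replicates
  W <- simulate_matern_ar1_field(x, y, 2000, range_km, field_sd = 1.3,
                                 rho = 0, seed = 99)
  v <- apply(W, 1L, var)
  se_var <- 1.3^2 * sqrt(2 / 1999)
  expect_true(all(abs(v - 1.3^2) < 3 * se_var + 0.05))
  # empirical correlation at d = range is ~0.14 (within ~3 SE, absolute)
  r12 <- cor(W[1, ], W[2, ])
  expect_lt(abs(r12 - matern_correlation(50, range_km)), 3 / sqrt(2000))
  expect_equal(matern_correlation(50, 50), sqrt(8) * besselK(sqrt(8), 1),
               tolerance = 1e-12)
  # far pair is uncorrelated
  expect_lt(abs(cor(W[1, ], W[3, ])), 3 / sqrt(2000) + 0.02)
})

test_that("field covariance factorises over space and time", {
  x <- c(0, 30); y <- c(0, 10)
  d <- sqrt(30^2 + 10^2)
  rho <- 0.6
  nrep <- 800
  w11 <- w22 <- numeric(nrep)
  for (r in seq_len(nrep)) {
    W <- simulate_matern_ar1_field(x, y, 2, 40, 1, rho, seed = 1000 + r)
    w11[r] <- W[1, 1]; w22[r] <- W[2, 2]
  }
  want <- matern_correlation(d, 40) * rho
  expect_lt(abs(cor(w11, w22) - want), 3 / sqrt(nrep) + 0.02)
})

test_that("field simulator rejects degenerate geometry", {
  expect_error(simulate_matern_ar1_field(c(0, 0), c(1, 1), 2, 50, 1, 0.5),
               class = "snowsync_geometry_error")
  expect_error(simulate_matern_ar1_field(0, 0, 2, 50, 1, 0.5),
               class = "snowsync_geometry_error")
})

test_that("cone series has masting structure and failure-year rules", {
  reg <- small_region()
  sites <- data.frame(site_id = sprintf("C%02d", 1:30),
                      x_km = runif(30, 0, reg$width_km),
                      y_km = runif(30, 0, reg$height_km))
  years <- 1989:2003
  fails <- c(1990, 1997)
  cones <- simulate_cone_series(sites, years, fails, reg,
                                missing_frac = 0.5, seed = 5)
  south <- cones$y_km < reg$southern_cut_y_km
  fail <- cones$year %in% fails
  expect_true(all(cones$cones_per_tree[fail & south] == 0, na.rm = TRUE))
  expect_true(any(is.na(cones$cones_per_tree[fail & south])))
  expect_true(all(cones$cones_per_tree[!fail] >= 0, na.rm = TRUE))
  expect_false(any(is.na(cones$cones_per_tree[!fail])))
  # masting: between-year CV of the regional mean exceeds the mean
  # within-year spatial CV
  ok <- cones[!fail, ]
  ym <- tapply(ok$cones_per_tree, ok$year, mean)
  cv_between <- sd(ym) / mean(ym)
  cv_within <- mean(tapply(ok$cones_per_tree, ok$year,
                           function(v) sd(v) / mean(v)))
  expect_gt(cv_between, cv_within)
  expect_error(simulate_cone_series(sites, years, failure_years = 1888,
                                    region = reg),
               class = "snowsync_config_error")
})

test_that("nest simulation matches its Poisson/persistence law", {
  reg <- study_region(1000, 600, 300)
  counts <- vapply(1:6, function(s) {
    n <- simulate_nests(reg, 2000L, 3, 1, seed = s)
    nrow(n)
  }, 0L)
  # Poisson mean = 3 * area / 100 = 18,000; pooled exact test
  expect_gt(stats::poisson.test(sum(counts), 6 * 18000)$p.value, 0.001)
  nests <- simulate_nests(study_region(100, 100, 50), 1990:1999, 3,
                          persistence_prob = 1, seed = 2)
  expect_true(all(nests$occupied))
  nests2 <- simulate_nests(study_region(100, 100, 50), 1990:1999, 3,
                           persistence_prob = 0.7, seed = 2)
  occ_per_year <- tapply(nests2$occupied, nests2$year, mean)
  expect_true(all(diff(occ_per_year) <= 0))  # abandoned stays abandoned
})

test_that("counts follow the NB2 law with the length offset", {
  skel <- data.frame(triangle_id = rep(c("A", "B"), each = 1),
                     triangle_type = "wildlife",
                     length_km = c(12, 24), year = 2000)
  cfg <- gen_config(beta = c(intercept = log(0.5)), n_wildlife = 2,
                    n_field = 0, n_years = 1, nb_overdispersion = 1.5,
                    seed = 1)
  reps <- 3000
  cnt <- matrix(0, reps, 2)
  for (r in seq_len(reps)) {
    out <- simulate_counts(skel, field = c(0, 0), cfg, seed = r)
    cnt[r, ] <- out$squirrel_tracks
  }
  mu <- c(12, 24) * 0.5
  # doubling the length doubles the expected count
  expect_equal(colMeans(cnt), mu, tolerance = 0.05)
  # NB2 moment identity: var/mean = 1 + mu/alpha
  vm <- apply(cnt, 2L, var) / colMeans(cnt)
  expect_equal(vm, 1 + mu / 1.5, tolerance = 0.25)
  expect_error(simulate_counts(skel, c(0, 0),
                               small_config(1)),
               class = "snowsync_missing_covariate_error")
})

test_that("simulated count means match the generative mu", {
  ds <- small_dataset(21)
  mu <- ds$census$mu_true
  yy <- ds$census$squirrel_tracks
  alpha <- ds$truth$config$nb_overdispersion
  # pooled z-statistic across observations
  z <- sum(yy - mu) / sqrt(sum(mu + mu^2 / alpha))
  expect_lt(abs(z), 4)
})

test_that("identical configs give byte-identical datasets", {
  d1 <- small_dataset(5)
  d2 <- small_dataset(5)
  expect_identical(d1$census, d2$census)
  expect_identical(d1$nests, d2$nests)
  expect_identical(d1$cones, d2$cones)
  d3 <- small_dataset(6)
  expect_false(identical(d1$census$squirrel_tracks,
                         d3$census$squirrel_tracks))
})

test_that("datasets round-trip to delimited text files", {
  ds <- small_dataset(8, n_wildlife = 10, n_field = 5, n_years = 2)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("census.csv", "nests.csv",
                                               "cones.csv", "truth.json")))))
  back <- read.csv(file.path(dir, "census.csv"))
  expect_equal(nrow(back), nrow(ds$census))
  expect_equal(back$squirrel_tracks, ds$census$squirrel_tracks)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$matern_range_km, ds$truth$config$matern_range_km)
})
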
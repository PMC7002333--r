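test_that("Matern(nu = 1) correlation has its closed-form anchors", {
  expect_identical(matern_correlation(0, 100), 1)
  expect_equal(matern_correlation(1e6, 100), 0)
  expect_equal(matern_correlation(100, 100), sqrt(8) * besselK(sqrt(8), 1),
               tolerance = 1e-14)
  expect_equal(matern_correlation(100, 100), 0.1397, tolerance = 1e-3)
  d <- seq(0, 500, 5)
  r <- matern_correlation(d, 120)
  expect_true(all(diff(r) < 0))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("NB2 log-likelihood normalises and obeys the moment identity", {
  for (pars in list(c(2, 1), c(0.5, 3), c(8, 0.4))) {
    mu <- pars[1]; alpha <- pars[2]
    yy <- 0:500
    pr <- exp(nb_loglik(yy, mu, alpha))
    expect_equal(sum(pr), 1, tolerance = 1e-10)
    expect_equal(sum(yy * pr), mu, tolerance = 1e-8)
    expect_equal(sum((yy - mu)^2 * pr), mu + mu^2 / alpha,
                 tolerance = 1e-6)
  }
  # variance at mu = 2, alpha = 1 is 6; Poisson limit at large alpha
  yy <- 0:400
  pr <- exp(nb_loglik(yy, 2, 1))
  expect_equal(sum((yy - 2)^2 * pr), 6, tolerance = 1e-8)
  expect_equal(nb_loglik(0, 1, 1e9), -1, tolerance = 1e-5)
  expect_equal(nb_loglik(3, 2.5, 1e9), dpois(3, 2.5, log = TRUE),
               tolerance = 1e-5)
})

test_that("the separable covariance is the entrywise Matern x AR1 product", {
  with_seed(41, {
    S <- 6; Tn <- 4
    x <- runif(S, 0, 200); y <- runif(S, 0, 200)
    rho <- 0.55; sigma <- 1.4; range_km <- 80
    M <- snowsync:::matern_matrix(x, y, range_km)
    R <- snowsync:::ar1_matrix(Tn, rho)
    Sigma <- sigma^2 * kronecker(R, M)  # time-major blocks
    for (k in 1:25) {
      s1 <- sample(S, 1); s2 <- sample(S, 1)
      t1 <- sample(Tn, 1); t2 <- sample(Tn, 1)
      i <- (t1 - 1) * S + s1; j <- (t2 - 1) * S + s2
      d <- sqrt((x[s1] - x[s2])^2 + (y[s1] - y[s2])^2)
      expect_equal(Sigma[i, j],
                   sigma^2 * matern_correlation(d, range_km) *
                     rho^abs(t1 - t2), tolerance = 1e-12)
    }
    # AR1 precision inverts the AR1 correlation
    expect_equal(as.matrix(solve(snowsync:::ar1_precision(Tn, rho))), R,
                 tolerance = 1e-10)
  })
})

test_that("the no-process spec reproduces an independent NB regression", {
  ds <- small_dataset(7, census_prob_per_year = 1, n_wildlife = 150,
                      n_field = 50, n_years = 6)
  d <- assemble_design(ds$census)
  fit <- fit_st_model(d, model_spec(d$covariates, temporal = "none",
                                    spatial = "none"), n_draws = 50)
  X <- as.matrix(d$df[, d$covariates])
  oracle <- MASS::glm.nb(d$df$squirrel_tracks ~ X + offset(d$offset))
  expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-4)
  expect_equal(fit$alpha, oracle$theta, tolerance = 1e-4 * oracle$theta)
  expect_equal(fit$loglik_mode, as.numeric(logLik(oracle)),
               tolerance = 1e-6 * abs(logLik(oracle)))
  # mode column of the summary is the penalised optimum itself
  expect_equal(fit$coefficients$mode, unname(fit$beta))
})

test_that("null data give weights whose intervals cover zero", {
  covered <- 0L
  total <- 0L
  for (seed in 1:12) {
    df <- field_panel(25, 4, 100, 0, 0.5, alpha = 2, log_rate = log(0.8),
                      width = 200, height = 200, seed = seed)
    df$z1 <- with_seed(seed + 500, rnorm(nrow(df), 0, 0.5))
    design <- as_design(df, "z1")
    fit <- fit_st_model(design, model_spec("z1", temporal = "none",
                                           spatial = "none"),
                        n_draws = 400, seed = seed)
    ci <- fit$coefficients[fit$coefficients$name == "z1", ]
    covered <- covered + (ci$q2.5 <= 0 && 0 <= ci$q97.5)
    total <- total + 1L
  }
  expect_gte(covered / total, 0.9)
})

test_that("coefficient summaries are internally coherent", {
  ds <- small_dataset(13)
  d <- assemble_design(ds$census)
  fit <- fit_st_model(d, model_spec(d$covariates), n_draws = 400, seed = 4)
  co <- fit$coefficients
  expect_true(all(co$q2.5 <= co$median & co$median <= co$q97.5))
  expect_true(all(is.finite(co$mode)))
  expect_equal(co$mean, co$mode, tolerance = 0.15)  # Gaussian approximation
  h <- fit$hyper
  expect_true(all(h$estimate[h$name != "rho"] > 0))
  expect_true(abs(h$estimate[h$name == "rho"]) < 1)
  # same data + spec + seed reproduce the same summaries
  fit2 <- fit_st_model(d, model_spec(d$covariates), n_draws = 400, seed = 4)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_identical(fit$waic, fit2$waic)
})

test_that("Laplace posterior matches an MCMC oracle on a tiny instance", {
  # 5 sites x 5 years (25 observations), known hyperparameters held
  # fixed in both routes
  with_seed(56, {
    S <- 5; Tn <- 5
    x <- runif(S, 0, 120); y <- runif(S, 0, 120)
    rho <- 0.5; sigma <- 0.5; range_km <- 60; alpha <- 3
    W <- simulate_matern_ar1_field(x, y, Tn, range_km, sigma, rho, seed = 9)
    n <- S * Tn
    X <- cbind(1, rnorm(n, 0, 0.5))
    beta_true <- c(0.3, 0.4)
    cell <- seq_len(n)  # one observation per site-year cell
    off <- rep(log(12), n)
    mu <- exp(off + X %*% beta_true + as.vector(W))
    yy <- rnbinom(n, size = alpha, mu = mu)

    M <- snowsync:::matern_matrix(x, y, range_km)
    R <- snowsync:::ar1_matrix(Tn, rho)
    Sigma_w <- sigma^2 * kronecker(R, M)
    oracle <- mcmc_beta_means(yy, X, off, cell, Sigma_w, prior_sd = 10,
                              alpha = alpha, seeds = 3:5)
    expect_true(all(oracle$accept > 0.2))

    df <- data.frame(triangle_id = rep(sprintf("S%02d", 1:S), Tn),
                     x_km = rep(x, Tn), y_km = rep(y, Tn),
                     year = rep(1:Tn, each = S), length_km = 12,
                     squirrel_tracks = yy, z1 = X[, 2])
    design <- as_design(df, "z1")
    fit <- fit_st_model(design, model_spec("z1"), n_draws = 4000, seed = 5,
                        init = list(range_km = range_km, field_sd = sigma,
                                    rho = rho, alpha = alpha),
                        control = st_control(max_outer = 0, hessian = FALSE))
    # max_outer = 0 keeps the oracle's hyperparameters: Nelder-Mead is
    # never run, the Laplace step happens at the initial values
    expect_true(fit$is_corrected)  # small instance: reweighting engaged
    gap <- abs(fit$coefficients$mean - oracle$beta)
    expect_true(all(gap <= pmax(0.05 * abs(oracle$beta), 0.025)))
  })
})

test_that("WAIC needs at least two draws and is reproducible", {
  ds <- small_dataset(14, n_wildlife = 20, n_field = 10, n_years = 3)
  d <- assemble_design(ds$census)
  fit <- fit_st_model(d, model_spec(d$covariates, temporal = "none",
                                    spatial = "none"), n_draws = 300,
                      seed = 8)
  expect_equal(waic(fit), waic(fit))
  expect_error(waic(fit, n_draws = 1),
               class = "snowsync_estimation_error")
  # subsampling draws moves WAIC only within Monte-Carlo noise
  expect_equal(waic(fit, 150), waic(fit), tolerance = 0.05 * abs(waic(fit)))
})

test_that("the spatial range estimate inverts kappa and flags non-spatial fits", {
  df <- field_panel(60, 5, 100, 0.9, 0.5, alpha = 2, log_rate = log(0.8),
                    width = 400, height = 400, seed = 31)
  design <- as_design(df)
  fit <- fit_st_model(design, model_spec(character()), n_draws = 50,
                      seed = 1)
  r <- extract_range(fit)
  expect_equal(r$range_km, exp(fit$theta[["log_range"]]), tolerance = 1e-10)
  # the fitted correlation at the estimated range is the ~0.14 anchor
  expect_equal(matern_correlation(r$range_km, r$range_km),
               sqrt(8) * besselK(sqrt(8), 1), tolerance = 1e-12)
  # recovery within a factor of two on a modest instance
  expect_gt(r$range_km, 50)
  expect_lt(r$range_km, 200)
  fit0 <- fit_st_model(design, model_spec(character(), temporal = "none",
                                          spatial = "none"), n_draws = 50)
  expect_error(extract_range(fit0),
               class = "snowsync_not_applicable_error")
  expect_error(predict_surface(fit0, data.frame(x_km = 1, y_km = 1), 2001),
               class = "snowsync_not_applicable_error")
})

test_that("surface prediction interpolates the latent field", {
  df <- field_panel(50, 4, 120, 0.8, 0.6, alpha = 3, log_rate = log(1),
                    width = 300, height = 300, seed = 17)
  design <- as_design(df)
  fit <- fit_st_model(design, model_spec(character()), n_draws = 50,
                      seed = 2)
  sites <- fit$sites
  yr <- fit$years[2]
  pred <- predict_surface(fit, sites[, c("x_km", "y_km")], yr,
                          type = "field")
  S <- nrow(sites)
  w_hat <- fit$z_mode[S + seq_len(S)]  # second year block
  expect_equal(pred$field, w_hat, tolerance = 1e-5)
  expect_false(any(pred$extrapolated))
  expect_equal(pred$density, exp(fit$beta[["(Intercept)"]] + pred$field),
               tolerance = 1e-10)
  far <- predict_surface(fit, data.frame(x_km = 5000, y_km = 5000), yr)
  expect_true(far$extrapolated)
  expect_error(predict_surface(fit, sites[, c("x_km", "y_km")], 1900),
               class = "snowsync_domain_error")
})

test_that("spatial residuals average observed minus fitted per transect", {
  ds <- small_dataset(19, n_wildlife = 25, n_field = 10, n_years = 4)
  d <- assemble_design(ds$census)
  fit <- fit_st_model(d, model_spec(d$covariates), n_draws = 200, seed = 3)
  res <- spatial_residuals(fit)
  expect_identical(nrow(res), nrow(fit$sites))
  one <- fit$fitted[fit$fitted$triangle_id == res$triangle_id[1], ]
  expect_equal(res$mean_residual[1],
               mean(one$observed - one$fitted_mean))
  expect_named(attr(res, "halves"), c("south", "north"))
})

test_that("an RW1 temporal process fits and stays comparable by WAIC", {
  df <- field_panel(30, 6, 100, 0.7, 0.8, alpha = 2, log_rate = log(0.8),
                    width = 250, height = 250, seed = 23)
  design <- as_design(df)
  fit_rw <- fit_st_model(design, model_spec(character(), temporal = "rw1"),
                         n_draws = 100, seed = 6,
                         control = st_control(hessian = FALSE))
  expect_true(is.finite(fit_rw$waic))
  expect_true(all(c("range_km", "field_sd", "overdispersion") %in%
                    fit_rw$hyper$name))
  expect_false("rho" %in% fit_rw$hyper$name)
})
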
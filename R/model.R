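#' Negative-binomial (NB2) log-likelihood
#'
#' Log-probability of counts under the NB2 parameterisation with mean
#' `mu` and overdispersion `alpha`, so that the variance is
#' `mu + mu^2 / alpha`. As `alpha` grows the distribution approaches
#' Poisson(`mu`).
#'
#' @param y Non-negative integer count(s).
#' @param mu Positive mean(s).
#' @param alpha Positive overdispersion.
#' @return Log-probabilities (vectorised).
#' @export
#' @examples
#' nb_loglik(0, 1, 1e8)  # ~ -1, the Poisson limit log P(0)
nb_loglik <- function(y, mu, alpha) {
  stopifnot(all(mu > 0), alpha > 0)
  lgamma(y + alpha) - lgamma(alpha) - lgamma(y + 1) +
    alpha * (log(alpha) - log(alpha + mu)) +
    y * (log(mu) - log(alpha + mu))
}

#' Specify a hierarchical count model
#'
#' Defines the structure of the negative-binomial spatiotemporal model:
#' which covariate columns enter the log-linear predictor, and which
#' latent process (if any) is attached. `temporal = "none"` together with
#' `spatial = "none"` reproduces an independent negative-binomial
#' regression; `temporal = "ar1"`, `spatial = "matern"` is the full
#' separable Matern(nu = 1) x AR1 model; `temporal = "rw1"` replaces the
#' stationary AR1 by an intrinsic first-order random walk (with a soft
#' sum-to-zero constraint).
#'
#' @param covariates Character vector of design-matrix columns (may be
#'   empty for a smoothing-only model).
#' @param temporal One of `"ar1"`, `"rw1"`, `"none"`.
#' @param spatial One of `"matern"`, `"none"`.
#' @param prior_sd Gaussian prior SD for the regression weights
#'   (mean 0); weakly informative on the 2-SD-scaled covariate scale.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(covariates = character(),
                       temporal = c("ar1", "rw1", "none"),
                       spatial = c("matern", "none"),
                       prior_sd = 10) {
  temporal <- match.arg(temporal)
  spatial <- match.arg(spatial)
  stopifnot(prior_sd > 0)
  structure(list(covariates = covariates, temporal = temporal,
                 spatial = spatial, prior_sd = prior_sd),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model spec: spatial = %s, temporal = %s, %d covariate(s)\n",
              x$spatial, x$temporal, length(x$covariates)))
  invisible(x)
}

#' Control parameters for the Laplace fitting engine
#'
#' @param max_outer Maximum hyperparameter optimiser iterations.
#' @param reltol Relative tolerance of the outer Nelder-Mead search.
#' @param max_inner Maximum inner Newton iterations for the latent mode.
#' @param grad_tol Inner convergence: infinity-norm of the gradient.
#' @param hessian Estimate hyperparameter SDs from a numerical Hessian.
#' @param verbose Print outer objective values.
#' @return A list of class `st_control`.
#' @export
st_control <- function(max_outer = 400, reltol = 1e-7, max_inner = 60,
                       grad_tol = 1e-6, hessian = TRUE, verbose = FALSE) {
  structure(list(max_outer = max_outer, reltol = reltol,
                 max_inner = max_inner, grad_tol = grad_tol,
                 hessian = hessian, verbose = verbose),
            class = "st_control")
}

# Internal: observation-level NB2 derivatives wrt the linear predictor.
nb_eta_derivs <- function(y, eta, alpha) {
  eta <- pmin(pmax(eta, -40), 40)
  mu <- exp(eta)
  list(ll = nb_loglik(y, mu, alpha),
       g = y - (y + alpha) * mu / (mu + alpha),
       w = alpha * mu * (y + alpha) / (mu + alpha)^2)
}

#' Fit the hierarchical negative-binomial spatiotemporal model
#'
#' Fits count data with `log mu = offset + X beta + w(s, t)` where the
#' counts are NB2 with overdispersion `alpha` and `w` is a zero-mean
#' Gaussian field with separable covariance
#' `sigma^2 * Matern(nu = 1; range) (x) AR1(rho)` over the observed sites
#' and years (dense Matern over sites, sparse Kronecker precision).
#' Hyperparameters (range, field SD, rho, alpha) are estimated by
#' empirical Bayes: a Nelder-Mead search maximises the Laplace-approximate
#' marginal likelihood on log/atanh-transformed scales, with the latent
#' mode found by an inner Newton iteration (warm-started between
#' hyperparameter evaluations). The latent posterior (weights + field) is
#' approximated by a Gaussian at the joint mode; coefficient summaries,
#' fitted counts and pointwise log-likelihoods (for WAIC) come from
#' seeded draws of that Gaussian. When the spec has no latent process,
#' the model reduces to an independent NB regression whose dispersion is
#' estimated by maximum likelihood.
#'
#' @param design A `design_matrix` from [assemble_design()], or a list
#'   with elements `df` (data incl. `squirrel_tracks`, `length_km`,
#'   `x_km`, `y_km`, `year`, `triangle_id` and the covariate columns) and
#'   `offset`.
#' @param spec A [model_spec()].
#' @param control An [st_control()].
#' @param n_draws Number of Gaussian-approximation draws for summaries
#'   and WAIC.
#' @param seed Seed for the summary draws.
#' @param init Optional named list of hyperparameter starting values
#'   (`range_km`, `field_sd`, `rho`, `alpha`).
#' @return An object of class `st_fit` with elements `coefficients`
#'   (posterior summary table), `hyper` (estimates and SDs), `waic`,
#'   `lppd`, `p_waic`, `loglik_draws`, `fitted`, `marginal_loglik`,
#'   `loglik_mode`, plus internals used by [predict_surface()] and
#'   [spatial_residuals()].
#' @export
fit_st_model <- function(design, spec = model_spec(), control = st_control(),
                         n_draws = 1000, seed = 1L, init = NULL) {
  df <- design$df
  y <- df$squirrel_tracks
  n <- length(y)
  off <- design$offset %||% log(df$length_km)
  miss <- setdiff(spec$covariates, names(df))
  if (length(miss)) {
    stop_snowsync("covariates not in design: ", paste(miss, collapse = ", "),
                  class = "snowsync_assembly_error")
  }
  X <- cbind(`(Intercept)` = rep(1, n),
             as.matrix(df[, spec$covariates, drop = FALSE]))
  p <- ncol(X)

  has_field <- !(spec$spatial == "none" && spec$temporal == "none")
  sites <- unique(df[, c("triangle_id", "x_km", "y_km")])
  S <- nrow(sites)
  years <- sort(unique(df$year))
  Tn <- length(years)
  s_i <- match(df$triangle_id, sites$triangle_id)
  t_i <- match(df$year, years)
  time_constant <- has_field && spec$temporal == "none"
  nw <- if (!has_field) 0L else if (time_constant) S else S * Tn
  cell <- if (!has_field) integer(0) else if (time_constant) s_i else
    (t_i - 1L) * S + s_i

  m <- nw + p
  beta_idx <- nw + seq_len(p)
  cell_u <- sort(unique(cell))

  # hyperparameter layout on transformed scales
  theta_names <- c(if (spec$spatial == "matern") "log_range",
                   if (has_field) "log_sigma",
                   if (has_field && spec$temporal == "ar1" && Tn > 1) "zeta",
                   "log_alpha")
  diam <- sqrt(diff(range(df$x_km))^2 + diff(range(df$y_km))^2)
  init <- init %||% list()
  theta0 <- c(log_range = log(init$range_km %||% (diam / 4)),
              log_sigma = log(init$field_sd %||% 0.7),
              zeta = atanh(init$rho %||% 0.5),
              log_alpha = log(init$alpha %||% 1))[theta_names]

  # --- prior precision Q(theta): values are rebuilt into a fixed sparsity
  # pattern (a Kronecker of the temporal precision with the dense inverse
  # Matern correlation, plus the weight-prior diagonal), so each
  # hyperparameter evaluation costs value updates, not structure rebuilds.
  spatial_cache <- new.env(parent = emptyenv())
  spatial_parts <- function(log_range) {
    key <- sprintf("%.12g", log_range)
    if (!is.null(spatial_cache[[key]])) return(spatial_cache[[key]])
    val <- if (spec$spatial == "matern") {
      M <- matern_matrix(sites$x_km, sites$y_km, exp(log_range))
      R <- chol(M + diag(1e-8, S))
      list(Minv = chol2inv(R), logdet_Minv = -2 * sum(log(diag(R))))
    } else {
      list(Minv = diag(S), logdet_Minv = 0)
    }
    if (length(ls(spatial_cache)) > 3) rm(list = ls(spatial_cache),
                                          envir = spatial_cache)
    spatial_cache[[key]] <- val
    val
  }

  kron_struct <- NULL
  if (has_field) {
    qt_rows <- if (time_constant) list(1L) else if (spec$temporal == "rw1") {
      lapply(seq_len(Tn), function(a) seq_len(Tn))   # dense via constraint
    } else if (Tn > 1) {
      lapply(seq_len(Tn), function(a)
        sort(unique(pmax(1L, pmin(Tn, a + (-1:1))))))
    } else list(1L)
    nt_blocks <- if (time_constant) 1L else Tn
    i_field <- unlist(lapply(seq_len(nt_blocks), function(a) {
      ia <- as.vector(outer(seq_len(S), qt_rows[[a]],
                            function(r, t) (t - 1L) * S + r))
      rep(ia, S)
    }))
    j_field <- unlist(lapply(seq_len(nt_blocks), function(a) {
      la <- length(qt_rows[[a]])
      rep((a - 1L) * S + seq_len(S), each = la * S)
    }))
    i_all <- c(i_field, beta_idx)
    j_all <- c(j_field, beta_idx)
    perm <- order(j_all, i_all)
    Q_tpl <- Matrix::sparseMatrix(i = i_all[perm], j = j_all[perm],
                                  x = 1, dims = c(m, m))
    kron_struct <- list(qt_rows = qt_rows, nt_blocks = nt_blocks,
                        perm = perm, tpl = Q_tpl)
  }

  build_Q <- function(theta) {
    if (!has_field) {
      return(list(Q = Matrix::Diagonal(p, 1 / spec$prior_sd^2),
                  logdet = -2 * p * log(spec$prior_sd)))
    }
    sp <- spatial_parts(if (spec$spatial == "matern") theta[["log_range"]]
                        else 0)
    sigma2 <- exp(2 * theta[["log_sigma"]])
    if (time_constant || Tn == 1L) {
      Qt <- matrix(1, 1, 1)
      ld_t <- 0
    } else if (spec$temporal == "ar1") {
      rho <- tanh(theta[["zeta"]])
      Qt <- as.matrix(ar1_precision(Tn, rho))
      ld_t <- -ar1_logdet(Tn, rho)
    } else {
      Qt <- as.matrix(rw1_precision(Tn))
      ld_t <- as.numeric(determinant(Qt, logarithm = TRUE)$modulus)
    }
    x_field <- unlist(lapply(seq_len(kron_struct$nt_blocks), function(a) {
      vals_a <- Qt[kron_struct$qt_rows[[a]], a]
      as.vector(kronecker(sp$Minv, t(vals_a)))  # b outer, t mid, r inner
    })) / sigma2
    Q <- kron_struct$tpl
    Q@x <- c(x_field, rep(1 / spec$prior_sd^2, p))[kron_struct$perm]
    nb <- if (time_constant) 1L else Tn
    ld <- S * ld_t + nb * sp$logdet_Minv - S * nb * log(sigma2)
    list(Q = Q, logdet = ld - 2 * p * log(spec$prior_sd))
  }

  state <- new.env(parent = emptyenv())
  state$z <- rep(0, m)

  lin_pred <- function(z) {
    eta <- off + as.numeric(X %*% z[beta_idx])
    if (nw > 0) eta <- eta + z[cell]
    eta
  }
  latent_grad <- function(g, Q, z) {
    gl <- numeric(m)
    if (nw > 0) {
      rs <- rowsum(g, cell)
      gl[as.integer(rownames(rs))] <- rs
    }
    gl[beta_idx] <- crossprod(X, g)
    gl - as.numeric(Q %*% z)
  }
  obs_hessian <- function(w) {
    # observation curvature: diag over field cells, border to the weights,
    # dense weight corner; assembled as a symmetric sparse increment
    wX <- w * X
    C <- crossprod(X, wX)
    if (nw == 0) {
      return(Matrix::sparseMatrix(i = rep(seq_len(p), p),
                                  j = rep(seq_len(p), each = p),
                                  x = as.vector(C), dims = c(m, m)))
    }
    dw <- rowsum(w, cell)
    cu <- as.integer(rownames(dw))
    B <- rowsum(wX, cell)
    ncu <- length(cu)
    Matrix::sparseMatrix(
      i = c(cu, rep(cu, p), rep(beta_idx, each = ncu),
            rep(seq_len(p), p) + nw),
      j = c(cu, rep(beta_idx, each = ncu), rep(cu, p),
            rep(beta_idx, each = p)),
      x = c(as.vector(dw), as.vector(B), as.vector(B), as.vector(C)),
      dims = c(m, m))
  }

  inner_mode <- function(Q, alpha) {
    z <- state$z
    d <- nb_eta_derivs(y, lin_pred(z), alpha)
    f <- sum(d$ll) - 0.5 * sum(z * as.numeric(Q %*% z))
    conv <- FALSE
    for (it in seq_len(control$max_inner)) {
      grad <- latent_grad(d$g, Q, z)
      if (max(abs(grad)) < control$grad_tol * (1 + abs(f))) {
        conv <- TRUE
        break
      }
      H <- Matrix::forceSymmetric(Q + obs_hessian(d$w))
      ch <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE, super = TRUE)
      step <- as.numeric(Matrix::solve(ch, grad))
      ok <- FALSE
      sfac <- 1
      for (h in 1:30) {
        z_new <- z + sfac * step
        d_new <- nb_eta_derivs(y, lin_pred(z_new), alpha)
        f_new <- sum(d_new$ll) - 0.5 * sum(z_new * as.numeric(Q %*% z_new))
        if (is.finite(f_new) && f_new >= f - 1e-10) {
          ok <- TRUE
          break
        }
        sfac <- sfac / 2
      }
      if (!ok) break  # no ascent possible: accept current mode
      z <- z_new; d <- d_new; f <- f_new
      if (max(abs(step * sfac)) < 1e-9) {
        conv <- TRUE
        break
      }
    }
    grad <- latent_grad(d$g, Q, z)
    if (!conv && max(abs(grad)) > 1e-2 * (1 + abs(f))) {
      stop_snowsync("inner Newton iterations failed to converge ",
                    "(gradient norm ", signif(max(abs(grad)), 3), ")",
                    class = "snowsync_convergence_error")
    }
    state$z <- z
    H <- Matrix::forceSymmetric(Q + obs_hessian(d$w))
    ch <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE, super = TRUE)
    list(z = z, f = f, ll = sum(d$ll), ch = ch,
         logdet_H = chm_logdet(ch))
  }

  neg_lml <- function(theta) {
    names(theta) <- theta_names
    if (any(!is.finite(theta)) || any(abs(theta) > 30)) return(1e10)
    alpha <- exp(theta[["log_alpha"]])
    qq <- build_Q(theta)
    res <- tryCatch(inner_mode(qq$Q, alpha), error = function(e) NULL)
    if (is.null(res)) {
      state$z <- rep(0, m)
      return(1e10)
    }
    lml <- if (has_field) {
      res$f + 0.5 * qq$logdet - 0.5 * res$logdet_H
    } else {
      # no latent process: dispersion by plain (penalised) profile likelihood
      res$f
    }
    if (control$verbose) {
      message(sprintf("theta = [%s]  lml = %.4f",
                      paste(sprintf("%.3f", theta), collapse = ", "), lml))
    }
    -lml
  }

  opt <- if (control$max_outer == 0L) {
    # hold the hyperparameters at their initial values (e.g. known truth)
    list(par = theta0, value = neg_lml(theta0), convergence = 0L)
  } else if (length(theta0) > 1L) {
    stats::optim(theta0, neg_lml, method = "Nelder-Mead",
                 control = list(maxit = control$max_outer,
                                reltol = control$reltol))
  } else {
    stats::optim(theta0, neg_lml, method = "Brent",
                 lower = theta0 - 8, upper = theta0 + 8)
  }
  theta_hat <- opt$par
  names(theta_hat) <- theta_names

  # hyperparameter uncertainty from a numerical Hessian on the working scale
  theta_vcov <- NULL
  if (control$hessian) {
    Hh <- tryCatch(num_hessian(neg_lml, theta_hat, h = 0.03),
                   error = function(e) NULL)
    if (!is.null(Hh)) {
      theta_vcov <- tryCatch(solve(Hh), error = function(e) NULL)
      if (!is.null(theta_vcov) && any(diag(theta_vcov) <= 0)) theta_vcov <- NULL
    }
  }

  alpha_hat <- exp(theta_hat[["log_alpha"]])
  qq <- build_Q(theta_hat)
  mode <- inner_mode(qq$Q, alpha_hat)
  z_hat <- mode$z
  beta_hat <- z_hat[beta_idx]
  names(beta_hat) <- colnames(X)

  # seeded draws from the Gaussian approximation at the joint mode;
  # the generating normals also give the Gaussian quadratic form
  # (z - zhat)' H (z - zhat) = |e|^2 for free
  E <- with_seed(seed, matrix(stats::rnorm(m * n_draws), m, n_draws))
  quad_gauss <- colSums(E^2)
  Z1 <- Matrix::solve(mode$ch, E, system = "Lt")
  draws <- as.matrix(Matrix::solve(mode$ch, Z1, system = "Pt")) + z_hat
  rm(E, Z1)
  beta_draws <- draws[beta_idx, , drop = FALSE]
  eta_draws <- as.matrix(X %*% beta_draws) + off
  if (nw > 0) eta_draws <- eta_draws + draws[cell, , drop = FALSE]
  eta_draws <- pmin(pmax(eta_draws, -40), 40)
  mu_draws <- exp(eta_draws)
  ll_draws <- matrix(nb_loglik(rep(y, n_draws), as.vector(mu_draws),
                               alpha_hat), n, n_draws)

  # importance reweighting towards the exact joint posterior: corrects the
  # Gaussian approximation's mode/mean gap where the weights are stable
  # (small latent dimension); with unstable weights (effective sample size
  # below the guard) the plain Gaussian draws are kept.
  quad_prior <- colSums(draws * as.matrix(qq$Q %*% draws))
  logw <- colSums(ll_draws) - 0.5 * quad_prior + 0.5 * quad_gauss
  logw <- logw - max(logw)
  wts <- exp(logw)
  wts <- wts / sum(wts)
  ess <- 1 / sum(wts^2)
  is_active <- is.finite(ess) && ess >= max(50, n_draws / 20)
  if (!is_active) wts <- rep(1 / n_draws, n_draws)

  qs <- t(apply(beta_draws, 1L, weighted_quantile, w = wts,
                probs = c(0.025, 0.5, 0.975)))
  bmean <- as.vector(beta_draws %*% wts)
  bsd <- sqrt(pmax(as.vector(beta_draws^2 %*% wts) - bmean^2, 0))
  coefficients <- data.frame(
    name = colnames(X),
    mean = bmean,
    sd = bsd,
    q2.5 = qs[, 1L], median = qs[, 2L], q97.5 = qs[, 3L],
    mode = beta_hat, row.names = NULL)

  hyper <- data.frame(name = character(), estimate = numeric(),
                      sd = numeric())
  add_hyper <- function(nm, est, sd) {
    rbind(hyper, data.frame(name = nm, estimate = est, sd = sd))
  }
  sd_of <- function(tn, transform_deriv) {
    if (is.null(theta_vcov)) return(NA_real_)
    i <- match(tn, theta_names)
    sqrt(theta_vcov[i, i]) * abs(transform_deriv)
  }
  if (spec$spatial == "matern") {
    range_hat <- exp(theta_hat[["log_range"]])
    hyper <- add_hyper("range_km", range_hat, sd_of("log_range", range_hat))
  }
  if (has_field) {
    sig_hat <- exp(theta_hat[["log_sigma"]])
    hyper <- add_hyper("field_sd", sig_hat, sd_of("log_sigma", sig_hat))
  }
  if ("zeta" %in% theta_names) {
    rho_hat <- tanh(theta_hat[["zeta"]])
    hyper <- add_hyper("rho", rho_hat, sd_of("zeta", 1 - rho_hat^2))
  }
  hyper <- add_hyper("overdispersion", alpha_hat,
                     sd_of("log_alpha", alpha_hat))

  fmean <- as.vector(mu_draws %*% wts)
  fitted <- data.frame(triangle_id = df$triangle_id, year = df$year,
                       observed = y,
                       fitted_mean = fmean,
                       fitted_sd = sqrt(pmax(
                         as.vector(mu_draws^2 %*% wts) - fmean^2, 0)))

  fit <- structure(list(
    coefficients = coefficients, hyper = hyper,
    spec = spec, theta = theta_hat, theta_vcov = theta_vcov,
    marginal_loglik = -opt$value, loglik_mode = mode$ll,
    loglik_draws = ll_draws, draw_weights = wts, ess = ess,
    is_corrected = is_active, fitted = fitted,
    z_mode = z_hat, beta = beta_hat, alpha = alpha_hat,
    sites = sites, years = years, nw = nw, p = p,
    time_constant = time_constant,
    df = df, offset = off, X = X,
    n_draws = n_draws, convergence = opt$convergence,
    n_obs = n), class = "st_fit")
  fit$waic <- waic(fit)
  fit
}

# log-determinant of the matrix factored by a CHOLMOD Cholesky object
chm_logdet <- function(ch) {
  d <- tryCatch(Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE),
                error = function(e) NULL)
  if (!is.null(d)) return(as.numeric(d$modulus))
  2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE)$modulus)
}

# Central-difference numerical Hessian.
num_hessian <- function(f, x, h = 1e-3) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(k), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
           f(x - ei - ej)) / (4 * h^2)
    }
  }
  H
}

#' Watanabe-Akaike information criterion of a fitted model
#'
#' `WAIC = -2 (lppd - p_waic)` with
#' `lppd = sum_i log mean_draws p(y_i | draw)` and
#' `p_waic = sum_i var_draws log p(y_i | draw)`, computed over the
#' fit's stored pointwise log-likelihood draws. Lower is better.
#'
#' @param fit An `st_fit`.
#' @param n_draws Optionally restrict to the first `n_draws` draws.
#' @return The WAIC (a single number).
#' @export
waic <- function(fit, n_draws = NULL) {
  ll <- fit$loglik_draws
  w <- fit$draw_weights %||% rep(1 / ncol(ll), ncol(ll))
  if (!is.null(n_draws)) {
    keep <- seq_len(min(n_draws, ncol(ll)))
    ll <- ll[, keep, drop = FALSE]
    w <- w[keep] / sum(w[keep])
  }
  if (ncol(ll) < 2L) {
    stop_snowsync("need at least two posterior draws for WAIC",
                  class = "snowsync_estimation_error")
  }
  mx <- apply(ll, 1L, max)
  lppd <- sum(mx + log(as.vector(exp(ll - mx) %*% w)))
  llm <- as.vector(ll %*% w)
  p_waic <- sum(as.vector((ll - llm)^2 %*% w) / (1 - sum(w^2)))
  -2 * (lppd - p_waic)
}

# weighted quantiles of a vector (type-1 inverse of the weighted ECDF)
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o])
  cw <- cw / cw[length(cw)]
  vapply(probs, function(p) x[o][which(cw >= p)[1L]], 0)
}

#' Extract the estimated Matern spatial range
#'
#' Returns the range `sqrt(8)/kappa` (km) — the distance at which the
#' Matern(nu = 1) correlation drops to about 0.14 — with a delta-method
#' SD from the hyperparameter Hessian.
#'
#' @param fit An `st_fit` with a spatial process.
#' @return A list with `range_km` and `sd`.
#' @export
extract_range <- function(fit) {
  if (fit$spec$spatial != "matern") {
    stop_snowsync("model has no spatial process",
                  class = "snowsync_not_applicable_error")
  }
  row <- fit$hyper[fit$hyper$name == "range_km", ]
  list(range_km = row$estimate, sd = row$sd)
}

#' Per-triangle mean residuals of a fitted model
#'
#' Averages observed-minus-fitted counts per transect across years —
#' the map of where the model over- or under-estimates. North and south
#' half totals (split at the median y) are attached as attribute
#' `halves`.
#'
#' @param fit An `st_fit`.
#' @return Data frame `triangle_id`, `x_km`, `y_km`, `mean_residual`,
#'   `n_years`.
#' @export
spatial_residuals <- function(fit) {
  r <- fit$fitted$observed - fit$fitted$fitted_mean
  agg <- stats::aggregate(r, by = list(triangle_id = fit$fitted$triangle_id),
                          FUN = mean)
  names(agg)[2L] <- "mean_residual"
  nyr <- stats::aggregate(r, by = list(triangle_id = fit$fitted$triangle_id),
                          FUN = length)
  out <- merge(merge(agg, fit$sites, by = "triangle_id"),
               stats::setNames(nyr, c("triangle_id", "n_years")),
               by = "triangle_id")
  out <- out[, c("triangle_id", "x_km", "y_km", "mean_residual", "n_years")]
  cut_y <- stats::median(out$y_km)
  attr(out, "halves") <- c(south = sum(out$mean_residual[out$y_km <= cut_y]),
                           north = sum(out$mean_residual[out$y_km > cut_y]))
  out
}

#' Predict the expected track density over a grid
#'
#' Kriges the posterior-mean latent field of one year to new locations
#' through the fitted Matern covariance and combines it with the
#' intercept (and, for `type = "wildlife"`, the triangle-type weight);
#' the scaled covariates sit at their sample means, so their contribution
#' is absorbed by the intercept. The result is on the tracks-per-km
#' scale. Nodes farther than `extrapolation_km` from every observed site
#' are flagged.
#'
#' @param fit An `st_fit` with a Matern spatial process.
#' @param grid Data frame with `x_km`, `y_km`.
#' @param year Year within the fitted span.
#' @param type Transect type whose indicator effect to include.
#' @param extrapolation_km Distance beyond which a node is flagged.
#' @return Data frame `x_km`, `y_km`, `density`, `field`, `extrapolated`.
#' @export
predict_surface <- function(fit, grid, year, type = c("wildlife", "field"),
                            extrapolation_km = 50) {
  type <- match.arg(type)
  if (fit$spec$spatial != "matern") {
    stop_snowsync("model has no spatial process",
                  class = "snowsync_not_applicable_error")
  }
  if (!year %in% fit$years) {
    stop_snowsync("year outside the fitted span",
                  class = "snowsync_domain_error")
  }
  S <- nrow(fit$sites)
  t_idx <- match(year, fit$years)
  w_hat <- if (fit$time_constant) fit$z_mode[seq_len(S)] else
    fit$z_mode[(t_idx - 1L) * S + seq_len(S)]
  range_hat <- fit$hyper$estimate[fit$hyper$name == "range_km"]
  M <- matern_matrix(fit$sites$x_km, fit$sites$y_km, range_hat) +
    diag(1e-8, S)
  Dg <- sqrt(outer(grid$x_km, fit$sites$x_km, "-")^2 +
               outer(grid$y_km, fit$sites$y_km, "-")^2)
  Cg <- matern_correlation(Dg, range_hat)
  dim(Cg) <- dim(Dg)
  w_grid <- drop(Cg %*% solve(M, w_hat))
  eta <- fit$beta[["(Intercept)"]] + w_grid
  if (type == "wildlife" && "triangle_type" %in% names(fit$beta)) {
    eta <- eta + fit$beta[["triangle_type"]]
  }
  data.frame(x_km = grid$x_km, y_km = grid$y_km,
             density = exp(eta), field = w_grid,
             extrapolated = apply(Dg, 1L, min) > extrapolation_km)
}

#' @export
print.st_fit <- function(x, ...) {
  cat(sprintf("Hierarchical NB model (spatial = %s, temporal = %s), %d obs\n",
              x$spec$spatial, x$spec$temporal, x$n_obs))
  cat(sprintf("  WAIC %.1f, marginal log-lik %.1f\n", x$waic,
              x$marginal_loglik))
  cat("Coefficients (posterior mean +- sd):\n")
  for (i in seq_len(nrow(x$coefficients))) {
    cat(sprintf("  %-18s %8.3f +- %.3f\n", x$coefficients$name[i],
                x$coefficients$mean[i], x$coefficients$sd[i]))
  }
  cat("Hyperparameters:\n")
  for (i in seq_len(nrow(x$hyper))) {
    cat(sprintf("  %-18s %8.3f +- %s\n", x$hyper$name[i],
                x$hyper$estimate[i],
                ifelse(is.na(x$hyper$sd[i]), "NA",
                       sprintf("%.3f", x$hyper$sd[i]))))
  }
  invisible(x)
}
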
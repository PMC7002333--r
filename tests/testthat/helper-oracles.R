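# Independent oracles used by the model tests.

# Metropolis-Hastings over the joint latent (field values + weights) at
# fixed hyperparameters, for tiny instances: the brute-force posterior
# oracle for the Laplace/Gaussian route. The proposal may be
# preconditioned by any fixed matrix (this does not change the
# stationary distribution); the default uses the prior Cholesky for the
# field block, which mixes far better than a spherical walk.
mcmc_latent_oracle <- function(y, X, off, cell, Sigma_w, prior_sd, alpha,
                               n_iter = 150000, burn = 30000, step = 0.25,
                               seed = 1, thin = 5) {
  nw <- if (is.null(Sigma_w)) 0L else nrow(Sigma_w)
  p <- ncol(X)
  m <- nw + p
  Qw <- if (nw > 0) solve(Sigma_w)
  Cp <- if (nw > 0) {
    as.matrix(Matrix::bdiag(t(chol(Sigma_w)), diag(p) * 0.5))
  } else diag(p) * 0.5
  logpost <- function(z) {
    beta <- z[nw + seq_len(p)]
    eta <- off + as.numeric(X %*% beta)
    if (nw > 0) eta <- eta + z[cell]
    lp <- sum(nb_loglik(y, exp(eta), alpha)) -
      0.5 * sum(beta^2) / prior_sd^2
    if (nw > 0) {
      w <- z[seq_len(nw)]
      lp <- lp - 0.5 * sum(w * as.numeric(Qw %*% w))
    }
    lp
  }
  with_seed(seed, {
    z <- rep(0, m)
    lp <- logpost(z)
    keep <- matrix(0, m, (n_iter - burn) %/% thin)
    k <- 0
    acc <- 0
    for (it in seq_len(n_iter)) {
      prop <- z + step * as.numeric(Cp %*% rnorm(m))
      lp_prop <- logpost(prop)
      if (log(runif(1)) < lp_prop - lp) {
        z <- prop; lp <- lp_prop; acc <- acc + 1
      }
      if (it > burn && (it - burn) %% thin == 0) {
        k <- k + 1
        keep[, k] <- z
      }
    }
    list(draws = keep, accept = acc / n_iter)
  })
}

# pooled posterior weight means over independent oracle chains
mcmc_beta_means <- function(y, X, off, cell, Sigma_w, prior_sd, alpha,
                            seeds = 1:3, ...) {
  nw <- if (is.null(Sigma_w)) 0L else nrow(Sigma_w)
  p <- ncol(X)
  acc <- numeric(0)
  means <- matrix(0, p, length(seeds))
  for (i in seq_along(seeds)) {
    o <- mcmc_latent_oracle(y, X, off, cell, Sigma_w, prior_sd, alpha,
                            seed = seeds[i], ...)
    acc <- c(acc, o$accept)
    means[, i] <- rowMeans(o$draws[nw + seq_len(p), , drop = FALSE])
  }
  list(beta = rowMeans(means), per_chain = means, accept = acc)
}
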
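#' Matern (nu = 1) spatial correlation
#'
#' Stationary Matern correlation with smoothness fixed at `nu = 1`,
#' \deqn{r(d) = (\kappa d) K_1(\kappa d), \qquad \kappa = \sqrt{8}/\rho,}
#' where \eqn{K_1} is the modified Bessel function of the second kind and
#' \eqn{\rho} is the spatial range in km. With this convention the
#' correlation at `d = range_km` is \eqn{\sqrt{8} K_1(\sqrt{8}) \approx
#' 0.14}, the conventional "distance at which correlation becomes
#' negligible".
#'
#' @param d_km Non-negative distances in km (vectorised).
#' @param range_km Positive spatial range in km.
#' @return Correlations in `[0, 1]`.
#' @export
#' @examples
#' matern_correlation(0, 100)              # 1
#' matern_correlation(100, 100)            # ~0.139
matern_correlation <- function(d_km, range_km) {
  stopifnot(is.numeric(d_km), is.numeric(range_km), length(range_km) == 1L,
            range_km > 0)
  if (any(d_km < 0)) {
    stop_snowsync("distances must be non-negative", class = "snowsync_domain_error")
  }
  kd <- sqrt(8) / range_km * d_km
  out <- numeric(length(kd))
  zero <- kd == 0
  out[zero] <- 1
  # besselK underflows to 0 for large kd; the product then correctly -> 0
  out[!zero] <- kd[!zero] * besselK(kd[!zero], nu = 1)
  out[!is.finite(out)] <- 0
  pmin(pmax(out, 0), 1)
}

# Dense Matern(nu=1) correlation matrix over planar sites; errors on
# duplicate sites, which make the covariance singular.
matern_matrix <- function(x, y, range_km) {
  D <- dist_matrix(x, y)
  if (any(D[upper.tri(D)] == 0)) {
    stop_snowsync("duplicate site coordinates give a singular covariance",
                  class = "snowsync_geometry_error")
  }
  M <- matern_correlation(D, range_km)
  dim(M) <- dim(D)
  M
}

# Stationary AR1 correlation matrix rho^|t - t'| over nt time points.
ar1_matrix <- function(nt, rho) {
  stopifnot(nt >= 1, abs(rho) < 1)
  rho^abs(outer(seq_len(nt), seq_len(nt), "-"))
}

# Tridiagonal precision of a stationary unit-variance AR1 process.
ar1_precision <- function(nt, rho) {
  stopifnot(nt >= 1, abs(rho) < 1)
  if (nt == 1L) return(Matrix::Diagonal(1))
  d <- c(1, rep(1 + rho^2, nt - 2L), 1) / (1 - rho^2)
  o <- rep(-rho / (1 - rho^2), nt - 1L)
  Matrix::bandSparse(nt, k = c(0L, 1L), diagonals = list(d, o), symmetric = TRUE)
}

# log det of the stationary AR1 correlation matrix: (nt-1) * log(1 - rho^2).
ar1_logdet <- function(nt, rho) (nt - 1) * log(1 - rho^2)

# Intrinsic first-order random-walk precision with a soft sum-to-zero
# constraint making it proper: Q = D'D + c * 11'/nt. Unit increment variance.
rw1_precision <- function(nt, constraint_weight = 1) {
  stopifnot(nt >= 2)
  D <- diff(diag(nt))
  Q <- crossprod(D) + constraint_weight * matrix(1 / nt, nt, nt)
  Matrix::forceSymmetric(Matrix::Matrix(Q, sparse = TRUE))
}
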
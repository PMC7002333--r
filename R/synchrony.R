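#' Moran's I over a distance bin
#'
#' Binary-weight Moran's I with weights `w_ij = 1` when the pair distance
#' falls in the half-open interval `(bin_lo, bin_hi]` and `i != j`:
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \frac{\sum_{ij} w_{ij}(x_i -
#' \bar x)(x_j - \bar x)}{\sum_i (x_i - \bar x)^2}.}
#' Under spatial independence its expectation is `-1/(n-1)`.
#'
#' @param values Numeric values at the sites (no missing values).
#' @param x_km,y_km Site coordinates.
#' @param bin_lo,bin_hi Bin bounds in km (lower exclusive, upper
#'   inclusive).
#' @return Moran's I, or `NA` when no pair falls in the bin.
#' @export
morans_i <- function(values, x_km, y_km, bin_lo, bin_hi) {
  n <- length(values)
  stopifnot(length(x_km) == n, length(y_km) == n, bin_hi > bin_lo)
  if (n < 2L) {
    stop_snowsync("need at least two sites", class = "snowsync_domain_error")
  }
  dev <- values - mean(values)
  ss <- sum(dev^2)
  if (ss == 0) {
    stop_snowsync("Moran's I is undefined for constant values",
                  class = "snowsync_undefined_statistic_error")
  }
  D <- dist_matrix(x_km, y_km)
  W <- D > bin_lo & D <= bin_hi
  diag(W) <- FALSE
  s0 <- sum(W)
  if (s0 == 0) return(NA_real_)
  (n / s0) * sum(W * outer(dev, dev)) / ss
}

#' Per-year Moran's I correlogram with pooled across-year SD
#'
#' Computes Moran's I in successive distance bins of width `bin_width_km`
#' up to `max_dist_km` (half-open bins `(lo, hi]`, first bin
#' `(0, bin_width]`), for each year separately, using only sites with a
#' value observed that year. A bin-year cell is missing when fewer than
#' `min_pairs` site pairs fall in the bin (or when that year's values are
#' constant). The pooled SD per bin is the plain across-year standard
#' deviation of the per-year I estimates.
#'
#' @param panel Data frame with columns `x_km`, `y_km`, `year`, and the
#'   value column named by `value_col`; missing values are dropped
#'   year by year.
#' @param value_col Name of the value column.
#' @param bin_width_km Bin width (km).
#' @param max_dist_km Largest distance considered (km); a partial final
#'   bin is kept.
#' @param min_pairs Minimum site pairs for a bin-year estimate.
#' @return An object of class `correlogram`: data frame `bin_lo`,
#'   `bin_hi`, `year`, `I`, `n_pairs` with per-bin `pooled_sd` merged in.
#' @export
correlogram <- function(panel, value_col = "value", bin_width_km = 20,
                        max_dist_km = 750, min_pairs = 10) {
  years <- sort(unique(panel$year))
  if (length(years) < 2L) {
    stop_snowsync("need at least two years", class = "snowsync_domain_error")
  }
  edges <- seq(0, max_dist_km, by = bin_width_km)
  if (edges[length(edges)] < max_dist_km) edges <- c(edges, max_dist_km)
  nb <- length(edges) - 1L
  out <- expand.grid(bin = seq_len(nb), year = years)
  out$bin_lo <- edges[out$bin]
  out$bin_hi <- edges[out$bin + 1L]
  out$I <- NA_real_
  out$n_pairs <- 0L
  for (yr in years) {
    sub <- panel[panel$year == yr & !is.na(panel[[value_col]]), ,
                 drop = FALSE]
    if (nrow(sub) < 2L) next
    v <- sub[[value_col]]
    dev <- v - mean(v)
    ss <- sum(dev^2)
    D <- dist_matrix(sub$x_km, sub$y_km)
    cp <- outer(dev, dev)
    diag(D) <- -1  # exclude self-pairs from every bin
    for (b in seq_len(nb)) {
      W <- D > edges[b] & D <= edges[b + 1L]
      s0 <- sum(W)
      row <- which(out$bin == b & out$year == yr)
      out$n_pairs[row] <- s0
      if (s0 < max(min_pairs, 1L) || ss == 0) next
      out$I[row] <- (nrow(sub) / s0) * sum(W * cp) / ss
    }
  }
  pooled <- stats::aggregate(I ~ bin, data = out,
                             FUN = function(v) stats::sd(v, na.rm = TRUE),
                             na.action = stats::na.pass)
  names(pooled)[2L] <- "pooled_sd"
  out <- merge(out, pooled, by = "bin", all.x = TRUE)
  out <- out[order(out$year, out$bin),
             c("bin_lo", "bin_hi", "year", "I", "n_pairs", "pooled_sd")]
  rownames(out) <- NULL
  class(out) <- c("correlogram", "data.frame")
  out
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf(
    "Moran's I correlogram: %d bins x %d years (%d estimates defined)\n",
    length(unique(x$bin_lo)), length(unique(x$year)), sum(!is.na(x$I))))
  NextMethod()
}
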
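# Small seeded synthetic studies shared across test files. Everything is
# generated in code; sizes are kept small so the whole suite runs quickly.

small_config <- function(seed = 7, ...) {
  args <- list(n_wildlife = 40, n_field = 20, n_years = 5,
               census_prob_per_year = 0.9, matern_range_km = 150,
               ar1_rho = 0.6, field_sd = 0.6, n_cone_sites = 30,
               failure_years = 1990L, habitat_sd = 0, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(gen_config, args)
}

small_region <- function() study_region(300, 400, 160)

small_dataset <- function(seed = 7, ...) {
  simulate_dataset(small_config(seed, ...), small_region())
}

# a minimal design_matrix-shaped object built directly from a data frame
as_design <- function(df, covariates = character()) {
  structure(list(df = df, covariates = covariates,
                 offset = log(df$length_km), scaling = list(),
                 drops = data.frame()),
            class = "design_matrix")
}

# bare field + counts panel: intercept-only NB counts over a latent field
field_panel <- function(n_sites, n_years, range_km, field_sd, rho, alpha,
                        log_rate, width = 600, height = 1100, seed = 1) {
  with_seed(seed, {
    x <- stats::runif(n_sites, 0, width)
    y <- stats::runif(n_sites, 0, height)
    W <- simulate_matern_ar1_field(x, y, n_years, range_km, field_sd, rho,
                                   seed = seed + 1)
    df <- data.frame(
      triangle_id = rep(sprintf("S%04d", seq_len(n_sites)), n_years),
      triangle_type = "wildlife",
      x_km = rep(x, n_years), y_km = rep(y, n_years), length_km = 12,
      year = rep(seq_len(n_years) + 2000L, each = n_sites))
    mu <- df$length_km * exp(log_rate + as.vector(W))
    df$squirrel_tracks <- stats::rnbinom(nrow(df), size = alpha, mu = mu)
    attr(df, "field") <- W
    df
  })
}
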
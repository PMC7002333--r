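#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded simulators do not perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
#' @examples
#' with_seed(1, rnorm(2))
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed from a master seed and a stage name
#'
#' A single pipeline seed fans out to per-stage seeds by hashing the stage
#' name, so inserting a stage never perturbs the seeds of earlier stages.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "simulate")
#' child_seed(1, "fit")
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- as.double(seed %% 2147483647)
  for (k in codes) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Euclidean distance matrix on planar km coordinates.
dist_matrix <- function(x, y) {
  as.matrix(stats::dist(cbind(x, y)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_snowsync <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "snowsync_error")))
}
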
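# Factor-structured feature matrices simulated from a loading matrix, and
# the packaged loading fixtures for the three instrumented tests.

#' Specification for a factor-structured simulation
#'
#' Defines the common factor model `X = F Lambda' + E diag(sqrt(Psi))` used
#' to simulate feature matrices: `Lambda` is a p x k loading matrix, the
#' uniquenesses are `Psi_j = max(1 - sum_f Lambda_jf^2, floor)`, and `F`
#' and `E` are independent standard normal. The floor keeps the implied
#' covariance positive definite even for measures whose printed communality
#' is close to 1.
#'
#' @param loadings numeric p x k matrix with measure rownames and factor
#'   colnames.
#' @param n number of subjects to simulate.
#' @param floor lower bound on the uniquenesses.
#' @param seed integer seed.
#' @return list of class `synthetic_factor_spec`.
#' @export
synthetic_factor_spec <- function(loadings, n, floor = 0.05, seed = NULL) {
  loadings <- as.matrix(loadings)
  if (floor <= 0) stop("uniqueness floor must be positive", call. = FALSE)
  if (n < 1) stop("need at least one subject", call. = FALSE)
  psi <- pmax(1 - rowSums(loadings^2), floor)
  structure(list(loadings = loadings, psi = psi, n = as.integer(n),
                 floor = floor, seed = seed),
            class = "synthetic_factor_spec")
}

#' Simulate a feature table from a factor specification
#'
#' Draws `X = F Lambda' + E diag(sqrt(Psi))` with independent standard
#' normal latent factors `F` and unique errors `E`. The sample covariance of
#' `X` converges to `Lambda Lambda' + diag(Psi)` as n grows, so printed
#' loading matrices can serve as generative fixtures for recovery
#' experiments.
#'
#' @param spec a [synthetic_factor_spec()].
#' @return A data frame (subjects x measures, columns named after the
#'   loading rows) with the simulated latent scores in
#'   `attr(, "latent_scores")`.
#' @export
simulate_feature_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_factor_spec"))
  with_seed(spec$seed, {
    p <- nrow(spec$loadings); k <- ncol(spec$loadings); n <- spec$n
    F <- matrix(stats::rnorm(n * k), n, k)
    E <- matrix(stats::rnorm(n * p), n, p)
    X <- F %*% t(spec$loadings) + E %*% diag(sqrt(spec$psi), p)
    colnames(X) <- rownames(spec$loadings)
    out <- as.data.frame(X, check.names = FALSE)
    rownames(out) <- sprintf("S%04d", seq_len(n))
    attr(out, "latent_scores") <- F
    out
  })
}

#' Packaged loading-matrix fixtures
#'
#' Returns the published varimax loading matrix for one of the three
#' instrumented tests (quiet standing: 23 measures x 4 factors; 7-meter
#' walk: 19 x 5; chair stand: 31 x 6), keyed by the printed measure names.
#' These matrices drive the simulation-based factor-recovery experiments.
#'
#' @param test `"qs"`, `"7mw"` or `"cst"`.
#' @return numeric matrix with measure rownames and factor colnames.
#' @examples
#' L <- load_loading_matrix("qs")
#' dim(L)
#' @export
load_loading_matrix <- function(test = c("qs", "7mw", "cst")) {
  test <- match.arg(test)
  path <- system.file("extdata", sprintf("loadings_%s.csv", test),
                      package = "physcap", mustWork = TRUE)
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  m
}

#' Study subgroup sizes for the three tests
#'
#' Number of subjects who completed each instrumented test in the reference
#' cohort; used as default sample sizes for the recovery simulations.
#'
#' @return named integer vector (`qs`, `7mw`, `cst`).
#' @export
subgroup_sizes <- function() c(qs = 204L, `7mw` = 201L, cst = 173L)
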
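# Exploratory-factor-analysis conceptual model: preprocessing, factor
# retention by parallel analysis, principal-axis extraction with varimax
# rotation, loading-based measure assignment, variance check and Thurstone
# regression factor scores.

#' Preprocess a feature table for factor analysis
#'
#' Jerk scores are strongly right-skewed and are natural-log transformed;
#' every measure is then standardized to zero mean and unit variance
#' (sample SD). Constant columns cannot be standardized and raise an error.
#'
#' @param ft data frame or matrix, subjects x measures.
#' @param jerk_measures names of columns to log-transform (must be strictly
#'   positive).
#' @return numeric matrix of standardized measures, with attributes
#'   `center` and `scale`.
#' @export
preprocess_features <- function(ft, jerk_measures = character()) {
  X <- as.matrix(ft)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) stop("measures must be named", call. = FALSE)
  for (m in intersect(jerk_measures, colnames(X))) {
    if (any(X[, m] <= 0, na.rm = TRUE))
      stop("non-positive jerk value in measure '", m,
           "': cannot log-transform", call. = FALSE)
    X[, m] <- log(X[, m])
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  Xs <- scale(X)
  out <- Xs[, , drop = FALSE]
  attr(out, "center") <- attr(Xs, "scaled:center")
  attr(out, "scale") <- attr(Xs, "scaled:scale")
  out
}

# inverse with a small ridge fallback: exactly collinear measures (e.g. a
# velocity that is a path length divided by a fixed duration) make R
# singular, in which case their squared multiple correlations approach 1
safe_solve <- function(R, b = diag(nrow(R))) {
  tryCatch(solve(R, b),
           error = function(e) solve(R + 1e-8 * diag(nrow(R)), b))
}

squared_multiple_correlations <- function(R) {
  pmin(pmax(1 - 1 / diag(safe_solve(R)), 0), 1)
}

reduced_eigenvalues <- function(R) {
  # correlation matrix with squared-multiple-correlation communalities on
  # the diagonal -- the common-factor analogue of the scree eigenvalues
  diag(R) <- squared_multiple_correlations(R)
  eigen(R, symmetric = TRUE, only.values = TRUE)$values
}

#' Parallel analysis for factor retention
#'
#' Compares the eigenvalues of the observed correlation structure with the
#' distribution of the same eigenvalues from random standard-normal
#' matrices of identical shape; the retained count is the number of leading
#' observed eigenvalues exceeding the chosen null quantile (counted until
#' the first failure). The default compares eigenvalues of the reduced
#' correlation matrix (squared multiple correlations on the diagonal), the
#' common-factor form of the criterion, which is sensitive to factors
#' carried by only a few measures; `eigen_type = "full"` gives the
#' principal-component variant on the unreduced correlation matrix.
#'
#' @param X standardized feature matrix (subjects x measures).
#' @param n_iter number of null replicates.
#' @param quantile null quantile (0.95 by default; `NA` uses the null mean).
#' @param seed integer seed for the null replicates.
#' @param eigen_type `"reduced"` (default) or `"full"`.
#' @return integer, the number of factors to retain (possibly 0).
#' @export
parallel_analysis <- function(X, n_iter = 100, quantile = 0.95, seed = NULL,
                              eigen_type = c("reduced", "full")) {
  eigen_type <- match.arg(eigen_type)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ev <- switch(eigen_type,
               reduced = reduced_eigenvalues,
               full = function(R) eigen(R, symmetric = TRUE,
                                        only.values = TRUE)$values)
  with_seed(seed, {
    obs <- ev(stats::cor(X))
    null <- replicate(n_iter,
                      ev(stats::cor(matrix(stats::rnorm(n * p), n, p))))
    thr <- if (is.na(quantile)) rowMeans(null)
           else apply(null, 1, stats::quantile, probs = quantile)
    as.integer(sum(cumprod(obs > thr)))
  })
}

#' Varimax rotation by pairwise planar sweeps
#'
#' Kaiser's planar algorithm: for every pair of factors the rotation angle
#' maximizing the varimax simplicity criterion is computed in closed form
#' and applied, sweeping the pairs until no pair moves. Rows are Kaiser
#' normalized (scaled to unit communality) during rotation by default.
#' Unlike the fixed-point iteration behind [stats::varimax()], the pairwise
#' sweep does not stall at symmetric saddle configurations such as two
#' equal-strength factors mixed at 45 degrees.
#'
#' @param L p x k loading matrix.
#' @param normalize Kaiser-normalize rows during rotation.
#' @param eps convergence threshold on the total rotation angle of a sweep.
#' @param max_sweep maximum number of sweeps.
#' @return list with `loadings` (rotated) and `rotmat` such that
#'   `loadings = L %*% rotmat`.
#' @export
varimax_rotate <- function(L, normalize = TRUE, eps = 1e-8, max_sweep = 100) {
  p <- nrow(L); k <- ncol(L)
  if (k < 2) return(list(loadings = L, rotmat = diag(k)))
  h <- if (normalize) sqrt(rowSums(L^2)) else rep(1, p)
  h[h == 0] <- 1
  A <- L / h
  R <- diag(k)
  for (sweep in seq_len(max_sweep)) {
    total <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      x <- A[, i]; y <- A[, j]
      u <- x^2 - y^2; v <- 2 * x * y
      num <- 2 * (p * sum(u * v) - sum(u) * sum(v))
      den <- p * sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2)
      theta <- atan2(num, den) / 4
      if (abs(theta) > eps) {
        G <- diag(k)
        G[i, i] <- G[j, j] <- cos(theta)
        G[i, j] <- -sin(theta); G[j, i] <- sin(theta)
        A <- A %*% G
        R <- R %*% G
        total <- total + abs(theta)
      }
    }
    if (total < eps) break
  }
  list(loadings = A * h, rotmat = R)
}

#' Fit a common-factor model with varimax rotation
#'
#' Principal-axis factoring with iterated communalities: starting from
#' squared multiple correlations, the correlation matrix with communalities
#' on the diagonal is eigen-decomposed, loadings taken from the k leading
#' components, and the communalities updated until convergence. The loading
#' matrix is then varimax-rotated (Kaiser normalization); orthogonal
#' rotation leaves the communalities, and hence the explained variance,
#' unchanged. This is a common-factor extraction, not principal components:
#' unique variance is excluded from the factors. Cumulative variance is the
#' sum of communalities divided by the number of measures.
#'
#' @param X standardized feature matrix (subjects x measures).
#' @param k number of factors (>= 1).
#' @param max_iter,tol iteration control for the communality loop.
#' @param rotate apply varimax rotation (`TRUE` by default).
#' @return An object of class `efa_result`: list with `k`, `loadings`
#'   (p x k, measures in rows), `communalities`, `uniquenesses`,
#'   `variance_fraction` (per factor), `cumulative_variance`, `R` (the
#'   correlation matrix), `n` and `iterations`.
#' @export
fit_efa <- function(X, k, max_iter = 500, tol = 1e-5, rotate = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (p < k + 1) stop("too few measures for ", k, " factors", call. = FALSE)
  if (n <= p)
    warning("fewer subjects than measures: factor solution may be unstable")
  R <- stats::cor(X)
  h2 <- squared_multiple_correlations(R)
  L <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(k)], 0)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
    h2_new <- pmin(rowSums(L^2), 1)  # clamp Heywood communalities
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      converged <- TRUE
      break
    }
    h2 <- h2_new
  }
  if (!converged)
    stop("principal-axis factoring did not converge in ", max_iter,
         " iterations", call. = FALSE)
  if (rotate && k > 1) L <- varimax_rotate(L)$loadings
  # order factors by explained variance for a stable presentation
  ssl <- colSums(L^2)
  ord <- order(ssl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  ssl <- ssl[ord]
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("F", seq_len(k))
  structure(list(k = k, loadings = L, communalities = h2,
                 uniquenesses = 1 - h2,
                 variance_fraction = ssl / p,
                 cumulative_variance = sum(h2) / p,
                 R = R, n = n, iterations = it),
            class = "efa_result")
}

#' @export
print.efa_result <- function(x, ...) {
  cat(sprintf("<efa_result> %d factors over %d measures; cumulative variance %.1f%%\n",
              x$k, nrow(x$loadings), 100 * x$cumulative_variance))
  invisible(x)
}

#' Assign measures to factors by their dominant loading
#'
#' A measure is considered relevant for the factor on which it has its
#' maximum absolute loading, provided that maximum exceeds the threshold;
#' otherwise it stays unassigned. Each measure is assigned to at most one
#' factor (a measure loading above the threshold on two factors goes to the
#' larger one).
#'
#' @param loadings p x k loading matrix (or an `efa_result`).
#' @param threshold absolute-loading threshold.
#' @return data frame with `measure`, `factor` (`NA` when unassigned) and
#'   `loading` (the signed dominant loading).
#' @export
assign_measures <- function(loadings, threshold = 0.5) {
  if (inherits(loadings, "efa_result")) loadings <- loadings$loadings
  L <- as.matrix(loadings)
  best <- apply(abs(L), 1, which.max)
  best_val <- L[cbind(seq_len(nrow(L)), best)]
  assigned <- abs(best_val) > threshold
  data.frame(measure = rownames(L),
             factor = ifelse(assigned, colnames(L)[best], NA_character_),
             loading = best_val,
             row.names = NULL)
}

#' Thurstone regression factor scores
#'
#' Least-squares prediction of each subject's position on the latent
#' factors from the standardized measures: `S = X R^-1 Lambda`, where `R`
#' is the measure correlation matrix. Score columns have zero mean.
#'
#' @param X standardized feature matrix used for the fit.
#' @param result an `efa_result` from [fit_efa()].
#' @return n x k matrix of factor scores.
#' @export
factor_scores <- function(X, result) {
  stopifnot(inherits(result, "efa_result"))
  X <- as.matrix(X)
  S <- X %*% safe_solve(result$R, result$loadings)
  colnames(S) <- colnames(result$loadings)
  rownames(S) <- rownames(X)
  S
}

#' Check the explained-variance requirement
#'
#' The factor structure is accepted when it explains at least the required
#' fraction of the total variance.
#'
#' @param result an `efa_result`.
#' @param min_fraction minimum cumulative variance fraction.
#' @return logical.
#' @export
check_variance <- function(result, min_fraction = 0.70) {
  stopifnot(inherits(result, "efa_result"))
  result$cumulative_variance >= min_fraction
}

#' Build the conceptual model for one test
#'
#' Runs the full model-building sequence on a feature table: preprocessing
#' (log jerk scores, standardization), parallel analysis for the factor
#' count, principal-axis extraction with varimax rotation, loading-based
#' measure assignment, explained-variance check, and regression factor
#' scores.
#'
#' @param ft feature table (subjects x measures).
#' @param jerk_measures columns to log-transform.
#' @param threshold loading threshold for assignment.
#' @param min_fraction required cumulative variance.
#' @param seed seed for the parallel-analysis null.
#' @param k optional fixed factor count (skips parallel analysis).
#' @param ... passed to [parallel_analysis()].
#' @return list with `k`, `efa` (`efa_result`), `assignment`, `scores`,
#'   `variance_ok`.
#' @examples
#' L <- load_loading_matrix("qs")
#' ft <- simulate_feature_matrix(synthetic_factor_spec(L, 204, seed = 1))
#' m <- build_conceptual_model(ft, seed = 1)
#' m$k; round(m$efa$cumulative_variance, 2)
#' @export
build_conceptual_model <- function(ft, jerk_measures = character(),
                                   threshold = 0.5, min_fraction = 0.70,
                                   seed = NULL, k = NULL, ...) {
  X <- preprocess_features(ft, jerk_measures)
  if (is.null(k)) k <- parallel_analysis(X, seed = seed, ...)
  if (k < 1)
    stop("parallel analysis retained no factors", call. = FALSE)
  efa <- fit_efa(X, k)
  list(k = k,
       efa = efa,
       assignment = assign_measures(efa, threshold),
       scores = factor_scores(X, efa),
       variance_ok = check_variance(efa, min_fraction))
}
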
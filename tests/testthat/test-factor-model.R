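# Conceptual-model construction: preprocessing, factor retention,
# extraction + rotation, assignment and scores.

test_that("preprocessing standardizes and log-transforms jerk columns", {
  set.seed(71)
  ft <- data.frame(a = rnorm(200, 5, 2), b = runif(200),
                   `NJS X` = exp(rnorm(200)), check.names = FALSE)
  X <- preprocess_features(ft, jerk_measures = "NJS X")
  expect_lt(max(abs(colMeans(X))), 1e-10)
  expect_equal(unname(apply(X, 2, sd)), rep(1, 3))
  # log of a log-normal is normal: skewness near zero at large n
  set.seed(72)
  big <- data.frame(`NJS X` = exp(rnorm(5000)), z = rnorm(5000),
                    check.names = FALSE)
  Xb <- preprocess_features(big, "NJS X")
  x <- Xb[, "NJS X"]
  skew <- mean(x^3)  # already standardized
  expect_lt(abs(skew), 0.2)
})

test_that("preprocessing rejects impossible inputs by name", {
  ft <- data.frame(a = rnorm(50), `NJS X` = c(-1, rexp(49)),
                   check.names = FALSE)
  expect_error(preprocess_features(ft, "NJS X"), "NJS X")
  ft2 <- data.frame(a = rnorm(50), flat = 1)
  expect_error(preprocess_features(ft2), "flat")
})

test_that("parallel analysis retains nothing on pure noise", {
  set.seed(73)
  X <- matrix(rnorm(500 * 20), 500, 20)
  expect_equal(parallel_analysis(X, seed = 1), 0L)
  expect_equal(parallel_analysis(X, seed = 1, eigen_type = "full"), 0L)
})

test_that("parallel analysis finds a planted two-factor structure", {
  L <- matrix(0, 10, 2)
  L[1:5, 1] <- 0.8
  L[6:10, 2] <- 0.8
  rownames(L) <- paste0("m", 1:10); colnames(L) <- c("F1", "F2")
  X <- simulate_feature_matrix(synthetic_factor_spec(L, 500, seed = 74))
  expect_equal(parallel_analysis(as.matrix(X), seed = 2), 2L)
})

test_that("parallel analysis is monotone in loading strength", {
  make_k <- function(strength, seed) {
    L <- matrix(0, 12, 3)
    L[1:4, 1] <- L[5:8, 2] <- L[9:12, 3] <- strength
    X <- simulate_feature_matrix(
      synthetic_factor_spec(L, 300, seed = seed))
    parallel_analysis(as.matrix(X), seed = seed)
  }
  for (seed in 1:5)
    expect_gte(make_k(0.9, seed), make_k(0.3, seed))
})

test_that("varimax rotation preserves communalities", {
  X <- as.matrix(recovery_matrix("qs", seed = 75))
  Xs <- preprocess_features(X)
  raw <- fit_efa(Xs, 4, rotate = FALSE)
  rot <- fit_efa(Xs, 4, rotate = TRUE)
  expect_lt(max(abs(rowSums(raw$loadings^2) - rowSums(rot$loadings^2))),
            1e-8)
  expect_equal(raw$cumulative_variance, rot$cumulative_variance,
               tolerance = 1e-10)
})

test_that("pairwise varimax agrees with the reference rotation and escapes saddles", {
  set.seed(70)
  L <- matrix(rnorm(60), 20, 3) %*% diag(c(1, 0.8, 0.6))
  ours <- varimax_rotate(L)$loadings
  ref <- unclass(stats::varimax(L, normalize = TRUE, eps = 1e-10)$loadings)
  # same rotated factors up to column order and sign
  match <- abs(cor(ours, ref))
  expect_true(all(apply(match, 2, max) > 0.9999))
  # communalities preserved
  expect_lt(max(abs(rowSums(ours^2) - rowSums(L^2))), 1e-10)
  # two equal blocks mixed at 45 degrees: recover the simple structure
  mix <- rbind(matrix(rep(c(0.7, -0.7), each = 4), 4, 2),
               matrix(rep(c(0.7, 0.7), each = 4), 4, 2))
  mix <- mix + matrix(rnorm(16, sd = 0.003), 8, 2)
  simple <- varimax_rotate(mix)$loadings
  expect_gt(sum(apply(simple^2, 2, var)), 0.5)
})

test_that("planted loadings are recovered with high congruence", {
  L <- load_loading_matrix("qs")
  X <- simulate_feature_matrix(synthetic_factor_spec(L, 2000, seed = 76))
  fit <- fit_efa(preprocess_features(as.matrix(X)), ncol(L))
  # align factors by maximum absolute Tucker congruence, any sign
  congr <- abs(crossprod(fit$loadings, L)) /
    outer(sqrt(colSums(fit$loadings^2)), sqrt(colSums(L^2)))
  best <- apply(congr, 2, max)
  expect_true(all(best > 0.95))
  expect_equal(sort(unname(apply(congr, 2, which.max))), 1:4)
})

test_that("maximum-likelihood extraction corroborates the principal-axis fit", {
  # independent route: ML factor analysis from stats on the same data
  L <- load_loading_matrix("7mw")
  X <- as.matrix(simulate_feature_matrix(synthetic_factor_spec(L, 2000,
                                                               seed = 77)))
  Xs <- preprocess_features(X)
  paf <- fit_efa(Xs, 5)
  ml <- stats::factanal(Xs, factors = 5, rotation = "varimax")
  h2_paf <- rowSums(paf$loadings^2)
  h2_ml <- rowSums(unclass(ml$loadings)^2)
  expect_lt(max(abs(h2_paf - h2_ml)), 0.1)
  expect_equal(sum(h2_paf) / ncol(X), sum(h2_ml) / ncol(X), tolerance = 0.03)
})

test_that("assignment follows the dominant-loading rule on the printed table", {
  L <- load_loading_matrix("qs")
  asg <- assign_measures(L, threshold = 0.5)
  # loads > 0.5 on two factors but is assigned to its maximum only
  expect_equal(asg$factor[asg$measure == "SP Planar DISPL"], "QS1")
  expect_equal(asg$factor[asg$measure == "MV AP DISPL"], "QS4")
  expect_true(is.na(asg$factor[asg$measure == "SE ML"]))
  expect_equal(sum(!is.na(asg$factor)), 19)
  # nothing assigned from a zero matrix
  asg0 <- assign_measures(matrix(0, 4, 2,
                                 dimnames = list(paste0("m", 1:4), NULL)))
  expect_true(all(is.na(asg0$factor)))
})

test_that("regression factor scores are centred, orthogonal and recover the latents", {
  L <- load_loading_matrix("qs")
  spec <- synthetic_factor_spec(L, 2000, seed = 78)
  X <- simulate_feature_matrix(spec)
  latent <- attr(X, "latent_scores")
  Xs <- preprocess_features(as.matrix(X))
  fit <- fit_efa(Xs, 4)
  S <- factor_scores(Xs, fit)
  expect_lt(max(abs(colMeans(S))), 1e-10)
  expect_lt(max(abs(cor(S)[upper.tri(diag(4))])), 0.2)
  # each score column tracks one simulated latent factor
  cc <- abs(cor(S, latent))
  expect_true(all(apply(cc, 2, max) > 0.8))
})

test_that("near-noiseless structure makes scores reproduce the latents", {
  # floor -> 0 limit: uniqueness is dominated by the floor otherwise
  L <- matrix(0, 8, 2)
  L[1:4, 1] <- L[5:8, 2] <- 0.995
  rownames(L) <- paste0("m", 1:8)
  spec <- synthetic_factor_spec(L, 2000, floor = 0.005, seed = 79)
  X <- simulate_feature_matrix(spec)
  latent <- attr(X, "latent_scores")
  Xs <- preprocess_features(as.matrix(X))
  fit <- fit_efa(Xs, 2)
  S <- factor_scores(Xs, fit)
  cc <- abs(cor(S, latent))
  expect_true(all(apply(cc, 2, max) > 0.99))
})

test_that("the variance requirement is a plain threshold", {
  fake <- structure(list(cumulative_variance = 0.80), class = "efa_result")
  expect_true(check_variance(fake))
  fake$cumulative_variance <- 0.69
  expect_false(check_variance(fake))
})

test_that("degenerate factor requests are rejected", {
  X <- matrix(rnorm(100 * 3), 100, 3)
  colnames(X) <- paste0("m", 1:3)
  expect_error(fit_efa(X, 0), ">= 1")
  expect_error(fit_efa(X, 3), "too few measures")
})
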
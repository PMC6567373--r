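# Shared oracles and fixture builders. Oracles are deliberately naive
# (direct sums, dense quadrature, brute-force loops) and independent of the
# package's implementation paths.

# recording with channels sampled at given times (seconds)
make_recording <- function(t_s, ap = 0, ml = 0, v = 0, test_label = "QS",
                           gyro = NULL, meta = list()) {
  n <- length(t_s)
  acc <- cbind(ap = rep_len(ap, n), ml = rep_len(ml, n), v = rep_len(v, n))
  imu_recording(t_s * 1e9, acc, gyro = gyro, test_label = test_label,
                meta = meta)
}

# dense-quadrature oracle for the quiet-standing normalized jerk score
njs_quadrature_oracle <- function(a_fun, T, n_dense = 2e5) {
  t <- seq(0, T, length.out = n_dense)
  a <- a_fun(t)
  dt <- t[2] - t[1]
  adot <- diff(a) / dt
  integral <- sum((adot[-1]^2 + adot[-length(adot)]^2) / 2) * dt
  sp <- sum(abs(diff(a)))
  sqrt(T^5 / (2 * sp^2) * integral)
}

# dense-quadrature oracle for the gait/chair-stand variant (no path term)
njs_gait_quadrature_oracle <- function(a_fun, T, n_dense = 2e5) {
  t <- seq(0, T, length.out = n_dense)
  a <- a_fun(t)
  dt <- t[2] - t[1]
  adot <- diff(a) / dt
  integral <- sum((adot[-1]^2 + adot[-length(adot)]^2) / 2) * dt
  sqrt(T^5 / 2 * integral)
}

# brute-force unbiased autocorrelation, normalized by lag 0
acf_unbiased_oracle <- function(s, max_lag) {
  s <- s - mean(s)
  N <- length(s)
  A <- sapply(0:max_lag, function(n) sum(s[1:(N - n)] * s[(1 + n):N]) / (N - n))
  A / A[1]
}

# standardized feature matrix from a loading fixture
recovery_matrix <- function(test, seed, n = physcap::subgroup_sizes()[[test]]) {
  L <- load_loading_matrix(test)
  simulate_feature_matrix(synthetic_factor_spec(L, n, seed = seed))
}
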
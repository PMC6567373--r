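# Quiet-standing sway measures against closed-form and brute-force oracles.

test_that("spectral shape of a pure sinusoid collapses to its frequency", {
  t <- seq(0, 30, by = 0.01)
  sf <- spectral_features(band_limited_psd(sin(2 * pi * 1 * t), 100))
  bin <- 1 / 15  # 15 s Welch segments
  expect_lt(abs(sf[["CF"]] - 1), bin)
  expect_lt(abs(sf[["F50"]] - 1), bin + 1e-9)
  expect_lt(abs(sf[["F95"]] - 1), bin + 1e-9)
  expect_lt(sf[["FD"]], 0.1)
})

test_that("degenerate and flat spectra give the entropy limits", {
  # power entirely in one bin -> SE = 0
  psd1 <- structure(list(f = c(0.5, 1, 1.5), psd = c(0, 1, 0), TP = 1,
                         mu0 = 1, mu1 = 1, mu2 = 1, n_bins = 3),
                    class = "psd_estimate")
  expect_equal(spectral_features(psd1)[["SE"]], 0)
  # flat spectrum -> SE = 1; F50 at the first bin reaching half mass
  f <- seq(0.2, 2, by = 0.2)
  psdf <- structure(list(f = f, psd = rep(1, 10), TP = 10, mu0 = 10,
                         mu1 = sum(f), mu2 = sum(f^2), n_bins = 10),
                    class = "psd_estimate")
  sff <- spectral_features(psdf)
  expect_equal(sff[["SE"]], 1)
  expect_equal(sff[["F50"]], f[5])  # cumulative reaches 5/10 at bin 5
  expect_equal(sff[["F95"]], f[10])
  # zero total power is an error
  psd0 <- structure(list(f = f, psd = rep(0, 10), TP = 0, mu0 = 0,
                         mu1 = 0, mu2 = 0, n_bins = 10),
                    class = "psd_estimate")
  expect_error(spectral_features(psd0), "undefined")
})

test_that("time-domain sway measures match closed forms for a sinusoid", {
  rate <- 100
  A <- 0.3
  t <- seq(0, 10, by = 1 / rate)  # 5 full periods at 0.5 Hz
  x <- A * sin(2 * pi * 0.5 * t)
  tf <- sway_time_features(x, rate)
  expect_equal(tf[["RMS"]], A / sqrt(2), tolerance = 0.01)
  expect_equal(tf[["Range"]], 2 * A, tolerance = 0.001)
  oracle <- njs_quadrature_oracle(function(u) A * sin(2 * pi * 0.5 * u), 10)
  expect_equal(tf[["NJS"]], oracle, tolerance = 0.01)
})

test_that("constant signals yield zero dispersion and a flagged jerk score", {
  tf <- sway_time_features(rep(1.7, 500), 100)
  expect_equal(tf[["RMS"]], 0)
  expect_equal(tf[["Range"]], 0)
  expect_true(is.na(tf[["NJS"]]))
})

test_that("sway path sums absolute increments", {
  d <- displacement_features(c(0, 1, 0, 1), c(0, 0, 0, 0), T = 3)
  expect_equal(d[["SP_AP"]], 3)
  expect_equal(d[["SP_Planar"]], 3)
  expect_equal(d[["MV_AP"]], 1)
  expect_error(displacement_features(1:3, 1:4, 1), "equal length")
})

test_that("circle geometry: sway area and planar path approach pi r^2 and 2 pi r", {
  r <- 0.02
  th <- seq(0, 2 * pi, length.out = 1001)
  d <- displacement_features(r * cos(th), r * sin(th), T = 30)
  expect_lt(abs(d[["SA"]] - pi * r^2) / (pi * r^2), 0.01)
  expect_lt(abs(d[["SP_Planar"]] - 2 * pi * r) / (2 * pi * r), 0.01)
})

test_that("isotropic Gaussian cloud gives the closed-form 95% ellipse area", {
  set.seed(41)
  s <- 0.01
  n <- 1e5
  d <- displacement_features(rnorm(n, sd = s), rnorm(n, sd = s), T = 30)
  expect_lt(abs(d[["EA"]] - pi * 5.991 * s^2) / (pi * 5.991 * s^2), 0.02)
})

test_that("QS extraction yields the 23 named measures, reproducibly", {
  rec <- generate_qs_recording(0.06, 0.04, seed = 42)
  f <- extract_qs_features(rec)
  expect_named(f, qs_measure_names())
  expect_true(all(is.finite(f)))
  expect_identical(f, extract_qs_features(rec))
  expect_error(extract_qs_features(generate_walk_recording(seed = 1)),
               "expected a QS")
  expect_error(extract_qs_features(generate_qs_recording(0.05, 0.05,
                                                         duration_s = 10,
                                                         seed = 1)),
               "20 s")
})

test_that("amplitude scaling moves amplitude measures and fixes spectral ones", {
  rec <- generate_qs_recording(0.05, 0.05, seed = 43)
  rec2 <- rec
  rec2$acc <- rec$acc * 2
  f1 <- extract_qs_features(rec)
  f2 <- extract_qs_features(rec2)
  for (m in c("RMS A AP", "RMS A ML", "Range A AP", "Range A ML"))
    expect_equal(f2[[m]], 2 * f1[[m]], tolerance = 1e-9)
  for (m in c("CF AP", "F50 AP", "F95 AP", "FD AP", "SE AP", "CF ML"))
    expect_equal(f2[[m]], f1[[m]], tolerance = 1e-9)
  # linear scaling of paths/velocities, quadratic of areas
  for (m in c("SP AP DISPL", "SP ML DISPL", "SP Planar DISPL",
              "MV AP DISPL", "MV ML DISPL"))
    expect_equal(f2[[m]], 2 * f1[[m]], tolerance = 1e-6)
  for (m in c("SA DISPL", "EA DISPL"))
    expect_equal(f2[[m]], 4 * f1[[m]], tolerance = 1e-6)
})

test_that("frequency dispersion stays in [0, 1] and F50 <= F95 across inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(1500) + seed / 5 * sin(2 * pi * runif(1, 0.3, 5) *
                                        seq(0, 14.99, by = 0.01))
    sf <- spectral_features(band_limited_psd(x, 100))
    expect_gte(sf[["FD"]], 0)
    expect_lte(sf[["FD"]], 1)
    expect_lte(sf[["F50"]], sf[["F95"]])
    expect_gte(sf[["SE"]], 0)
    expect_lte(sf[["SE"]], 1)
  }
})
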
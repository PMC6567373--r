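# Walk measures: detection against planted events, hand-computed temporal
# parameters, brute-force autocorrelation and the printed PCI arithmetic.

test_that("heel strikes are recovered at the planted times", {
  w <- generate_walk_recording(gait_sim_params(cadence = 120), seed = 51)
  ev <- detect_heel_strikes(w)
  pl <- w$meta$events
  expect_equal(length(ev$times), length(pl))
  expect_lt(max(abs(ev$times - pl)), 0.03)
})

test_that("a flat recording has no detectable steps", {
  t <- seq(0, 8, by = 0.01)
  rec <- make_recording(t, ap = 0, ml = 0, v = 0, test_label = "7MW")
  expect_error(detect_heel_strikes(rec), "insufficient steps")
})

test_that("planted asymmetry is labelled on the correct leg", {
  w <- generate_walk_recording(gait_sim_params(cadence = 110,
                                               asymmetry = 1.2), seed = 52)
  ev <- detect_heel_strikes(w)
  # planted labels are per interval; detected labelling must agree
  expect_equal(ev$labels, w$meta$step_labels)
})

test_that("cadence follows the step count over the gait window", {
  # 20 steps spanning 12 s -> 100 steps/min
  ev <- step_events(seq(0, 12, length.out = 21))
  cad <- cadence_features(ev)
  expect_equal(cad[["Cadence"]], 100)
  expect_equal(cad[["SD_Cadence"]], 0)
  expect_equal(cad[["Duration"]], 12)
  # alternating 0.5/0.6 s step times: SD of per-step cadences by hand
  times <- cumsum(c(0, rep(c(0.5, 0.6), 5)))
  ev2 <- step_events(times)
  expect_equal(cadence_features(ev2)[["SD_Cadence"]],
               sd(60 / rep(c(0.5, 0.6), 5)))
})

test_that("regularity matches a brute-force autocorrelation oracle", {
  rate <- 100
  t <- seq(0, 29.99, by = 1 / rate)
  ev <- step_events(seq(1, 25, by = 0.5), rate)
  # perfectly periodic symmetric signal: both regularities ~ 1
  x <- sin(2 * pi * 2 * t)
  reg <- regularity(x, ev)
  expect_gt(reg[["StepReg"]], 0.99)
  expect_gt(reg[["StrideReg"]], 0.99)
  # asymmetric period-2 pattern: stride beats step
  x2 <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 1 * t)
  reg2 <- regularity(x2, ev)
  expect_gt(reg2[["StrideReg"]], reg2[["StepReg"]])
  # values agree with the naive oracle's windowed peaks
  A <- acf_unbiased_oracle(x2, 150)
  step_lag <- 50
  expect_equal(reg2[["StepReg"]], max(A[26:76]), tolerance = 1e-9)
  expect_equal(reg2[["StrideReg"]], max(A[51:151]), tolerance = 1e-9)
  # white noise decorrelates
  set.seed(53)
  regn <- regularity(rnorm(3000), ev)
  expect_lt(abs(regn[["StepReg"]]), 0.1)
  expect_lt(abs(regn[["StrideReg"]]), 0.1)
})

test_that("regularity is invariant to amplitude scaling and bounded", {
  rate <- 100
  t <- seq(0, 29.99, by = 1 / rate)
  ev <- step_events(seq(1, 25, by = 0.5), rate)
  x <- sin(2 * pi * 2 * t) + rnorm(length(t), sd = 0.3)
  r1 <- regularity(x, ev)
  r5 <- regularity(5 * x, ev)
  expect_equal(r1, r5, tolerance = 1e-12)
  expect_true(all(abs(r1) <= 1))
})

test_that("PCI reproduces the printed arithmetic", {
  # perfectly alternating gait: phases all 180 -> PCI = 0
  ev <- step_events(seq(0, 10, by = 0.5))
  expect_equal(phase_coordination_index(ev), 0, tolerance = 1e-10)
  # constant phase 162: PCI = 100 * 18/180 = 10
  times <- sort(c(seq(0, 9, by = 1), seq(0, 9, by = 1) + 0.45))
  ev162 <- step_events(times)
  expect_equal(phase_coordination_index(ev162), 10, tolerance = 1e-8)
  # phases alternating 170/190: PhaseCV = 5.55..., accuracy term = 5.55...
  times2 <- sort(c(0:10, (0:9) + rep(c(170, 190) / 360, 5)))
  ev2 <- step_events(times2)
  expect_equal(phase_coordination_index(ev2), 100 / 9, tolerance = 1e-8)
})

test_that("per-step jerk matches dense quadrature and its time-rescaling law", {
  rate <- 100
  t <- seq(0, 10, by = 1 / rate)
  # 2 Hz locked to 0.5 s steps: every step sees the same waveform
  x <- sin(2 * pi * 2 * t)
  ev <- step_events(seq(1, 9, by = 0.5), rate)
  njs <- gait_jerk(x, ev)
  oracle <- njs_gait_quadrature_oracle(function(u) sin(4 * pi * u), 0.5)
  expect_equal(njs, oracle, tolerance = 0.01)
  # doubling all durations with a(t/2): NJS^2 gains 2^5 from T^5 and loses
  # 2^-2 + 2^1 from the squared derivative and dt, so NJS scales by 4
  t2 <- seq(0, 20, by = 1 / rate)
  x2 <- sin(2 * pi * t2)
  ev2 <- step_events(seq(2, 18, by = 1), rate)
  njs2 <- gait_jerk(x2, ev2)
  expect_equal(njs2 / njs, 4, tolerance = 0.02)
})

test_that("walk extraction yields the 19 named measures plus gait speed", {
  w <- generate_walk_recording(gait_sim_params(cadence = 115, asymmetry = 1.1,
                                               cv = 0.02), seed = 54)
  f <- extract_gait_features(w)
  expect_named(f, gait_measure_names())
  expect_true(all(is.finite(f)))
  expect_identical(f, extract_gait_features(w))
  expect_equal(attr(f, "gait_speed"), 7 / f[["Total duration"]])
  expect_true(all(abs(f[c("Step Reg AP", "Step Reg ML", "Step Reg V",
                          "Stride Reg AP", "Stride Reg ML",
                          "Stride Reg V")]) <= 1))
})

test_that("extracted cadence tracks the planted cadence within 2%", {
  for (cad in c(95, 110, 125)) {
    w <- generate_walk_recording(gait_sim_params(cadence = cad), seed = cad)
    f <- extract_gait_features(w)
    expect_lt(abs(f[["Cadence"]] - cad) / cad, 0.02)
  }
})

test_that("PCI increases with planted step-time asymmetry", {
  pcis <- vapply(c(1, 1.1, 1.2, 1.3), function(r) {
    w <- generate_walk_recording(gait_sim_params(cadence = 110,
                                                 asymmetry = r,
                                                 duration_s = 14),
                                 seed = 55)
    extract_gait_features(w)[["PCI"]]
  }, numeric(1))
  expect_true(all(diff(pcis) > 0))
})
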
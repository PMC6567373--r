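# Synthetic IMU recordings for the three functional tests. Each generator
# plants its ground truth (target RMS, heel-strike times, phase boundaries)
# in the recording metadata so detectors can be tested against it.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  force(code)
}

# Gaussian noise band-limited by an FFT brick-wall, rescaled to an exact RMS
band_limited_noise <- function(n, rate, band, rms) {
  if (rms == 0) return(numeric(n))
  x <- stats::rnorm(n)
  f <- c(0, seq_len(n - 1)) * rate / n
  f <- pmin(f, rate - f)  # two-sided frequency magnitude
  X <- stats::fft(x)
  X[f < band[1] | f > band[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y <- y - mean(y)
  y * rms / sqrt(mean(y^2))
}

#' Simulate a quiet-standing recording
#'
#' Band-limited Gaussian sway acceleration on the AP and ML axes with a
#' requested per-axis RMS, emulating 30 s of eyes-closed stance with the
#' sensor at L5. The vertical channel carries only small wideband noise.
#' Gravity is not included: channels represent gravity-compensated body
#' acceleration.
#'
#' @param rms_ap,rms_ml target RMS acceleration in m/s^2 per axis
#'   (non-negative; `0` yields an identically zero channel).
#' @param band frequency band of the sway content, Hz.
#' @param duration_s recording length in seconds.
#' @param rate nominal sampling rate in Hz.
#' @param seed integer seed; identical seeds give identical recordings.
#' @param jitter_sd_ns timestamp jitter SD in nanoseconds (0 = exact grid).
#' @return An [imu_recording()] with `meta$target_rms`.
#' @export
generate_qs_recording <- function(rms_ap, rms_ml, band = c(0.2, 2),
                                  duration_s = 30, rate = 100, seed = NULL,
                                  jitter_sd_ns = 0) {
  if (rms_ap < 0 || rms_ml < 0) stop("RMS targets must be non-negative",
                                     call. = FALSE)
  if (duration_s <= 0) stop("duration must be positive", call. = FALSE)
  with_seed(seed, {
    n <- round(duration_s * rate) + 1
    acc <- cbind(ap = band_limited_noise(n, rate, band, rms_ap),
                 ml = band_limited_noise(n, rate, band, rms_ml),
                 v  = stats::rnorm(n, sd = 0.005))
    t_ns <- jittered_grid(n, rate, jitter_sd_ns)
    imu_recording(t_ns, acc, test_label = "QS",
                  meta = list(target_rms = c(ap = rms_ap, ml = rms_ml),
                              band = band))
  })
}

jittered_grid <- function(n, rate, jitter_sd_ns) {
  t_ns <- (0:(n - 1)) / rate * 1e9
  if (jitter_sd_ns > 0) {
    j <- stats::rnorm(n, sd = jitter_sd_ns)
    j[c(1, n)] <- 0
    t_ns <- t_ns + j
    t_ns <- sort(t_ns)  # jitter must not break monotonicity
  }
  round(t_ns)
}

#' Gait simulation parameters
#'
#' @param cadence steps per minute.
#' @param asymmetry long/short step-time ratio (>= 1; 1 = symmetric gait).
#' @param cv step-time coefficient of variation (0 = perfectly periodic).
#' @param impulse named amplitudes (m/s^2) of the heel-strike bursts on the
#'   `ap`, `ml` and `v` axes.
#' @param duration_s nominal walking time in seconds (enough steps are
#'   generated to cover it).
#' @return list of class `gait_sim_params`.
#' @export
gait_sim_params <- function(cadence = 110, asymmetry = 1, cv = 0,
                            impulse = c(ap = 1.2, ml = 0.4, v = 2),
                            duration_s = 7) {
  if (cadence <= 0) stop("cadence must be positive", call. = FALSE)
  if (asymmetry < 1) stop("asymmetry ratio must be >= 1", call. = FALSE)
  if (cv < 0) stop("step-time CV must be non-negative", call. = FALSE)
  structure(list(cadence = cadence, asymmetry = asymmetry, cv = cv,
                 impulse = impulse, duration_s = duration_s),
            class = "gait_sim_params")
}

#' Simulate a 7-meter-walk recording
#'
#' Plants heel strikes at controllable step times: a cadence-locked base
#' step time split into alternating long/short steps by the asymmetry ratio
#' (mean preserved), with optional multiplicative Gaussian step-time
#' variability. Each heel strike is a half-sine burst (80 ms, centred on the
#' strike) superimposed on a small cadence-locked sinusoid on the V and AP
#' axes; the ML axis oscillates at stride frequency. Planted strike times
#' and step labels are returned in `meta` for oracle tests.
#'
#' @param params a [gait_sim_params()] list.
#' @param rate sampling rate in Hz.
#' @param seed integer seed.
#' @return An [imu_recording()] with `meta$events` (heel-strike times, s),
#'   `meta$step_times`, `meta$step_labels` (`"long"`/`"short"` per interval)
#'   and `meta$stopwatch_s`.
#' @export
generate_walk_recording <- function(params = gait_sim_params(), rate = 100,
                                    seed = NULL) {
  stopifnot(inherits(params, "gait_sim_params"))
  with_seed(seed, {
    tau <- 60 / params$cadence
    r <- params$asymmetry
    n_steps <- max(4L, ceiling(params$duration_s / tau))
    long_first <- rep(c(TRUE, FALSE), length.out = n_steps)
    step <- ifelse(long_first, 2 * r / (1 + r), 2 / (1 + r)) * tau
    if (params$cv > 0)
      step <- pmax(0.2 * tau, step * (1 + params$cv * stats::rnorm(n_steps)))
    lead_in <- 1
    hs <- lead_in + cumsum(c(0, step))        # n_steps + 1 strikes
    total <- hs[length(hs)] + 1
    n <- round(total * rate) + 1
    t <- (0:(n - 1)) / rate
    f_step <- 1 / mean(step)
    burst <- function(amp, width = 0.08) {
      y <- numeric(n)
      for (h in hs) {
        idx <- which(t >= h - width / 2 & t <= h + width / 2)
        y[idx] <- y[idx] + amp * sin(pi * (t[idx] - h + width / 2) / width)
      }
      y
    }
    gait_window <- t >= hs[1] - 0.2 & t <= hs[length(hs)] + 0.2
    osc <- function(amp, freq) amp * sin(2 * pi * freq * t) * gait_window
    imp <- params$impulse
    acc <- cbind(
      ap = burst(imp[["ap"]]) + osc(0.15 * imp[["ap"]], f_step) +
        stats::rnorm(n, sd = 0.02),
      ml = osc(imp[["ml"]], f_step / 2) + stats::rnorm(n, sd = 0.02),
      v = burst(imp[["v"]]) + osc(0.15 * imp[["v"]], f_step) +
        stats::rnorm(n, sd = 0.02))
    imu_recording((0:(n - 1)) / rate * 1e9, acc, test_label = "7MW",
                  meta = list(events = hs, step_times = step,
                              step_labels = ifelse(long_first, "long", "short"),
                              params = params,
                              stopwatch_s = hs[length(hs)] - hs[1]))
  })
}

#' Simulate a 5-times chair-stand recording
#'
#' Alternating sit-to-stand (Sts) and stand-to-sit (stS) phases separated by
#' short pauses, starting seated. Each transition is a half-sine burst on the
#' ML angular velocity; the AP acceleration burst is positive during Sts and
#' negative during stS (forward lean polarity), which is what the segmenter
#' uses to tell the two phase kinds apart. Planted phase boundaries are
#' stored in `meta$phases`.
#'
#' @param n_cycles number of stand-up/sit-down cycles.
#' @param sts_dur,sts_dur_sd mean and SD (s) of the sit-to-stand duration.
#' @param sts2_dur,sts2_dur_sd mean and SD (s) of the stand-to-sit duration.
#' @param pause_s pause between consecutive phases, s.
#' @param amp named amplitudes: `gyro_ml` (deg/s), `acc_ap`, `acc_v` (m/s^2).
#' @param rate sampling rate in Hz.
#' @param seed integer seed.
#' @return An [imu_recording()] with gyroscope channels and
#'   `meta$phases` (data frame `kind`, `start`, `end`) plus
#'   `meta$stopwatch_s`.
#' @export
generate_cst_recording <- function(n_cycles = 5, sts_dur = 1.2,
                                   sts_dur_sd = 0, sts2_dur = 1.4,
                                   sts2_dur_sd = 0, pause_s = 0.7,
                                   amp = c(gyro_ml = 60, acc_ap = 1.5,
                                           acc_v = 2),
                                   rate = 100, seed = NULL) {
  if (n_cycles < 1) stop("need at least one cycle", call. = FALSE)
  if (sts_dur <= 0 || sts2_dur <= 0)
    stop("phase durations must be positive", call. = FALSE)
  with_seed(seed, {
    kinds <- rep(c("Sts", "stS"), n_cycles)
    dur <- ifelse(kinds == "Sts",
                  pmax(0.4, sts_dur + sts_dur_sd * stats::rnorm(2 * n_cycles)),
                  pmax(0.4, sts2_dur + sts2_dur_sd * stats::rnorm(2 * n_cycles)))
    start <- 1 + cumsum(c(0, dur[-length(dur)] + pause_s))
    end <- start + dur
    total <- end[length(end)] + 1
    n <- round(total * rate) + 1
    t <- (0:(n - 1)) / rate
    gyro_ml <- stats::rnorm(n, sd = 1)
    acc_ap <- stats::rnorm(n, sd = 0.05)
    acc_v <- stats::rnorm(n, sd = 0.05)
    for (i in seq_along(kinds)) {
      idx <- which(t >= start[i] & t <= end[i])
      u <- (t[idx] - start[i]) / dur[i]
      hs <- sin(pi * u)
      gyro_ml[idx] <- gyro_ml[idx] + amp[["gyro_ml"]] * hs
      sgn <- if (kinds[i] == "Sts") 1 else -1
      acc_ap[idx] <- acc_ap[idx] + sgn * amp[["acc_ap"]] * hs
      acc_v[idx] <- acc_v[idx] + amp[["acc_v"]] * sin(2 * pi * u) * sgn
    }
    acc <- cbind(ap = acc_ap, ml = stats::rnorm(n, sd = 0.05), v = acc_v)
    gyro <- cbind(ap = stats::rnorm(n, sd = 1), ml = gyro_ml,
                  v = stats::rnorm(n, sd = 1))
    imu_recording(t * 1e9, acc, gyro, test_label = "CST",
                  meta = list(phases = data.frame(kind = kinds, start = start,
                                                  end = end),
                              stopwatch_s = end[length(end)] - start[1]))
  })
}
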
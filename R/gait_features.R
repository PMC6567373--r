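# 7-meter-walk measures: heel-strike detection, temporal gait parameters,
# smoothness (per-step jerk), regularity (autocorrelation) and bilateral
# coordination (phase coordination index). 19 sensor-based measures plus
# gait speed.

#' Detect heel strikes in a walk recording
#'
#' Peak picking on the 10 Hz low-pass-filtered vertical acceleration:
#' candidate peaks at least 0.3 s apart, kept when their height exceeds half
#' the median candidate height (adaptive threshold). Steps are the intervals
#' between consecutive strikes; the strikes are split into the two
#' interleaved per-leg series by alternation and the series with the larger
#' mean step time is labelled "long".
#'
#' @param rec an [imu_recording()] with `test_label = "7MW"`.
#' @param rate processing rate in Hz.
#' @return An object of class `step_events`: list with `times` (s, strictly
#'   increasing heel strikes), `intervals` (s), `labels` (`"long"`/`"short"`
#'   per interval), `window` (first to last strike) and `rate`.
#' @export
detect_heel_strikes <- function(rec, rate = 100) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rec$test_label != "7MW")
    stop("expected a 7MW recording, got ", rec$test_label, call. = FALSE)
  u <- resample_uniform(rec, rate)
  lp <- signal::butter(4, 10 / (rate / 2), type = "low")
  v <- signal::filtfilt(lp, u$channels$acc_v - mean(u$channels$acc_v))
  pk <- pracma::findpeaks(v, minpeakdistance = round(0.3 * rate),
                          nups = 1, ndowns = 1)
  if (is.null(pk) || nrow(pk) < 4)
    stop("insufficient steps: fewer than 4 heel strikes detected",
         call. = FALSE)
  keep <- pk[, 1] >= 0.5 * stats::median(pk[, 1])
  pk <- pk[keep, , drop = FALSE]
  if (nrow(pk) < 4)
    stop("insufficient steps: fewer than 4 heel strikes detected",
         call. = FALSE)
  times <- sort(u$t[pk[, 2]])
  step_events(times, rate)
}

#' Assemble step events from heel-strike times
#'
#' @param times strictly increasing heel-strike times in seconds (>= 4).
#' @param rate the processing rate the events refer to, Hz.
#' @return A `step_events` object (see [detect_heel_strikes()]).
#' @export
step_events <- function(times, rate = 100) {
  if (length(times) < 4 || any(diff(times) <= 0))
    stop("need >= 4 strictly increasing heel-strike times", call. = FALSE)
  intervals <- diff(times)
  # interval i ends at strike i+1; legs alternate with strike parity
  leg <- rep_len(c(1L, 2L), length(times))
  end_leg <- leg[-1]
  mean_by_leg <- tapply(intervals, end_leg, mean)
  long_leg <- as.integer(names(which.max(mean_by_leg)))
  labels <- ifelse(end_leg == long_leg, "long", "short")
  structure(list(times = times, intervals = intervals, labels = labels,
                 leg = leg, long_leg = long_leg,
                 window = range(times), rate = rate),
            class = "step_events")
}

#' Temporal gait parameters
#'
#' Cadence over the gait phase (first to last heel strike):
#' `60 * n_steps / window length` in steps/min; the per-step cadence is
#' `60 / step time` and SD Cadence is its sample standard deviation;
#' Duration is the gait-phase window length in seconds.
#'
#' @param ev a [step_events()] object.
#' @return named numeric vector `Cadence`, `SD_Cadence`, `Duration`.
#' @export
cadence_features <- function(ev) {
  stopifnot(inherits(ev, "step_events"))
  dur <- diff(ev$window)
  n_steps <- length(ev$intervals)
  c(Cadence = 60 * n_steps / dur,
    SD_Cadence = stats::sd(60 / ev$intervals),
    Duration = dur)
}

#' Step and stride regularity from the unbiased autocorrelation
#'
#' The unbiased autocorrelation `A(n) = sum(s_i s_{i+n}) / (N - n)` of the
#' mean-removed acceleration, normalized by `A(0)`, peaks at the dominant
#' periods of the gait: the first dominant period (one step) expresses step
#' regularity, the second (one stride, i.e. two steps) stride regularity.
#' Peaks are searched within 0.5-1.5x the cadence-implied step and stride
#' lags; an empty search window gives a flagged `NA`.
#'
#' @param x uniformly sampled acceleration axis (whole recording).
#' @param ev a [step_events()] object (provides the expected lags and rate).
#' @return named numeric vector `StepReg`, `StrideReg`, both in `[-1, 1]`.
#' @export
regularity <- function(x, ev) {
  stopifnot(inherits(ev, "step_events"))
  s <- as.numeric(x) - mean(x)
  N <- length(s)
  step_lag <- mean(ev$intervals) * ev$rate
  max_lag <- min(N - 1, ceiling(3 * step_lag))
  A <- vapply(0:max_lag, function(n) {
    sum(s[1:(N - n)] * s[(1 + n):N]) / (N - n)
  }, numeric(1))
  An <- A / A[1]
  peak_in <- function(lag) {
    w <- seq.int(max(1, floor(0.5 * lag)), min(max_lag, ceiling(1.5 * lag)))
    if (length(w) == 0) return(NA_real_)
    max(An[w + 1])
  }
  c(StepReg = peak_in(step_lag), StrideReg = peak_in(2 * step_lag))
}

#' Phase coordination index
#'
#' Quantifies the accuracy and consistency of bilateral stepping phase.
#' Each stride of the long-step leg is assigned 360 degrees; the phase of
#' the intervening short-leg strike is
#' `phi_i = 360 (hs_S,i - hs_L,i) / (hs_L,i+1 - hs_L,i)`. Then
#' `PCI = PhaseCV + 100 * mean(|phi_i - 180|) / 180` with
#' `PhaseCV = 100 * sd(phi) / mean(phi)` (population SD). PCI is 0 exactly
#' when every phase is 180 degrees; it grows with both asymmetry (accuracy
#' term) and variability (consistency term).
#'
#' @param ev a [step_events()] object with at least 3 strides of the
#'   long-step leg.
#' @return PCI in percent (>= 0).
#' @export
phase_coordination_index <- function(ev) {
  stopifnot(inherits(ev, "step_events"))
  hs_L <- ev$times[ev$leg == ev$long_leg]
  hs_S <- ev$times[ev$leg != ev$long_leg]
  if (length(hs_L) < 3)
    stop("PCI needs at least 3 strides of the long-step leg", call. = FALSE)
  phi <- numeric(0)
  for (i in seq_len(length(hs_L) - 1)) {
    s <- hs_S[hs_S > hs_L[i] & hs_S < hs_L[i + 1]]
    if (length(s) == 1)
      phi <- c(phi, 360 * (s - hs_L[i]) / (hs_L[i + 1] - hs_L[i]))
  }
  if (length(phi) < 2)
    stop("PCI needs at least 2 complete strides with one opposite strike",
         call. = FALSE)
  pop_sd <- sqrt(mean((phi - mean(phi))^2))
  phase_cv <- 100 * pop_sd / mean(phi)
  phase_cv + 100 * mean(abs(phi - 180)) / 180
}

#' Per-step normalized jerk score of a gait acceleration axis
#'
#' `NJS = sqrt(T^5 / 2 * integral(adot^2 dt))` computed between each pair of
#' consecutive heel strikes with `T` = that step's duration, then averaged
#' across steps. Note the walking variant has no path-length term in the
#' denominator, unlike its quiet-standing counterpart.
#'
#' @param x uniformly sampled acceleration axis.
#' @param ev a [step_events()] object.
#' @return mean per-step NJS.
#' @export
gait_jerk <- function(x, ev) {
  stopifnot(inherits(ev, "step_events"))
  rate <- ev$rate
  per_step <- vapply(seq_len(length(ev$times) - 1), function(i) {
    i0 <- max(1, round(ev$times[i] * rate) + 1)
    i1 <- min(length(x), round(ev$times[i + 1] * rate) + 1)
    seg <- x[i0:i1]
    if (length(seg) < 3) return(NA_real_)
    T <- (length(seg) - 1) / rate
    ad <- central_diff(seg, rate)
    sqrt(T^5 / 2 *
           pracma::trapz(seq(0, T, length.out = length(seg)), ad^2))
  }, numeric(1))
  mean(per_step, na.rm = TRUE)
}

#' Names of the 19 walk measures
#' @return character vector in canonical order, matching the published
#'   loading-table row names.
#' @export
gait_measure_names <- function() {
  c("Total duration", "Cadence", "SD Cadence",
    "NJS AP", "NJS ML", "NJS V", "PCI",
    "Range A AP", "Range A ML", "Range A V",
    "RMS A AP", "RMS A ML", "RMS A V",
    "Step Reg AP", "Step Reg ML", "Step Reg V",
    "Stride Reg AP", "Stride Reg ML", "Stride Reg V")
}

#' Extract the 19 walk measures (plus gait speed) from a recording
#'
#' Detects heel strikes, then computes duration/cadence measures, per-axis
#' RMS, range, per-step jerk and step/stride regularity on the AP, ML and V
#' acceleration, and the phase coordination index. Gait speed
#' (`distance / Duration`) is attached as the `"gait_speed"` attribute; the
#' device-derived duration uses the window between first and last heel
#' strike, while any stopwatch duration in `rec$meta$stopwatch_s` is kept
#' separate for agreement analysis.
#'
#' @param rec an [imu_recording()] with `test_label = "7MW"`.
#' @param distance_m walked distance in meters.
#' @param rate processing rate in Hz.
#' @return named numeric vector of the 19 measures ([gait_measure_names()])
#'   with attribute `gait_speed` (m/s).
#' @examples
#' rec <- generate_walk_recording(gait_sim_params(cadence = 120), seed = 3)
#' f <- extract_gait_features(rec)
#' f["Cadence"]; attr(f, "gait_speed")
#' @export
extract_gait_features <- function(rec, distance_m = 7, rate = 100) {
  ev <- detect_heel_strikes(rec, rate)
  u <- resample_uniform(rec, rate)
  cad <- cadence_features(ev)
  out <- c("Total duration" = unname(cad["Duration"]),
           "Cadence" = unname(cad["Cadence"]),
           "SD Cadence" = unname(cad["SD_Cadence"]),
           "PCI" = phase_coordination_index(ev))
  in_gait <- u$t >= ev$window[1] & u$t <= ev$window[2]
  for (ax in c("ap", "ml", "v")) {
    x <- u$channels[[paste0("acc_", ax)]]
    xw <- x[in_gait]  # amplitude/regularity statistics over the gait phase
    AX <- toupper(ax)
    reg <- regularity(xw, ev)
    out[paste("NJS", AX)] <- gait_jerk(x, ev)
    out[paste("Range A", AX)] <- max(xw) - min(xw)
    out[paste("RMS A", AX)] <- sqrt(mean((xw - mean(xw))^2))
    out[paste("Step Reg", AX)] <- reg["StepReg"]
    out[paste("Stride Reg", AX)] <- reg["StrideReg"]
  }
  out <- out[gait_measure_names()]
  attr(out, "gait_speed") <- distance_m / unname(cad["Duration"])
  out
}
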
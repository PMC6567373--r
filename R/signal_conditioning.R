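# Signal conditioning: uniform resampling, band-limited Welch spectra and
# drift-suppressed displacement estimation shared by all three tests.

#' Resample a recording onto a uniform grid
#'
#' Android sensor stacks deliver samples at irregular intervals; every
#' feature extractor therefore works on a linearly interpolated version of
#' the stream at an exact rate (100 Hz by default), using the absolute
#' nanosecond timestamps as the time reference. The grid is
#' `t0 + k/rate`, `k = 0, 1, ...`, covering `[t0, t_end]`.
#'
#' @param rec an [imu_recording()].
#' @param rate target sampling rate in Hz.
#' @return An object of class `uniform_signal`: list with `rate`, `t`
#'   (seconds from first sample), `channels` (named list of numeric vectors,
#'   `acc_ap`, ..., `gyro_v` when present) and `duration` `= (N-1)/rate`.
#' @examples
#' rec <- generate_qs_recording(0.05, 0.04, seed = 1)
#' u <- resample_uniform(rec)
#' u$rate
#' @export
resample_uniform <- function(rec, rate = 100) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  t <- (rec$t_ns - rec$t_ns[1]) / 1e9
  span <- t[length(t)]
  if (span < 2 / rate)
    stop(sprintf("recording too short to resample: span %.4f s < %.4f s",
                 span, 2 / rate), call. = FALSE)
  grid <- seq(0, span, by = 1 / rate)
  interp <- function(y) stats::approx(t, y, xout = grid, rule = 2)$y
  channels <- list(acc_ap = interp(rec$acc[, "ap"]),
                   acc_ml = interp(rec$acc[, "ml"]),
                   acc_v  = interp(rec$acc[, "v"]))
  if (!is.null(rec$gyro)) {
    channels$gyro_ap <- interp(rec$gyro[, "ap"])
    channels$gyro_ml <- interp(rec$gyro[, "ml"])
    channels$gyro_v  <- interp(rec$gyro[, "v"])
  }
  structure(list(rate = rate, t = grid, channels = channels,
                 duration = (length(grid) - 1) / rate),
            class = "uniform_signal")
}

#' Band-limited Welch power spectrum
#'
#' Averaged modified periodogram (Hann window, 50% overlap, per-segment mean
#' removal) of a uniformly sampled series, returned as a one-sided power
#' spectrum restricted to frequencies at or above `low_cut`. The spectrum is
#' normalized so that the sum of the retained values approximates the
#' variance contributed by the retained band (Parseval); spectral moments
#' mu0 (= total power TP), mu1 and mu2 are plain PSD-weighted sums over the
#' retained grid, which is the convention the sway measures are defined in.
#' Postural sway has essentially no physiological content below 0.15 Hz, so
#' that band is excluded by default.
#'
#' Segments are 15 s long (or the full series when shorter), giving three
#' windows for a 30 s record and a grid fine enough to resolve the 0.15 Hz
#' cutoff.
#'
#' @param x numeric series, uniformly sampled; at least 256 samples.
#' @param rate sampling rate in Hz.
#' @param low_cut lower band edge in Hz; bins with `f < low_cut` are dropped.
#' @return An object of class `psd_estimate`: list with `f`, `psd`, `TP`,
#'   `mu0`, `mu1`, `mu2` and `n_bins`.
#' @export
band_limited_psd <- function(x, rate, low_cut = 0.15) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 256)
    stop(sprintf("series too short for spectral estimation: %d < 256 samples",
                 n), call. = FALSE)
  seg <- min(n, round(15 * rate))
  step <- max(1L, floor(seg / 2))
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, seg - 1) / (seg - 1)))
  msw <- mean(w^2)
  half <- floor(seg / 2)
  acc <- numeric(half + 1)
  for (s in starts) {
    xs <- x[s:(s + seg - 1)]
    xs <- (xs - mean(xs)) * w
    X <- stats::fft(xs)
    p <- Mod(X[1:(half + 1)])^2 / (seg^2 * msw)
    # one-sided: double interior bins (not DC, not Nyquist for even seg)
    dbl <- 2:(half + if (seg %% 2 == 0) 0 else 1)
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  psd <- acc / length(starts)
  f <- (0:half) * rate / seg
  keep <- f >= low_cut
  f <- f[keep]; psd <- psd[keep]
  tp <- sum(psd)
  structure(list(f = f, psd = psd, TP = tp, mu0 = tp,
                 mu1 = sum(f * psd), mu2 = sum(f^2 * psd),
                 n_bins = length(f)),
            class = "psd_estimate")
}

#' Estimate planar center-of-mass displacement from acceleration
#'
#' Double integration of the horizontal lumbar acceleration with drift
#' suppression: a zero-phase 4th-order Butterworth high-pass at 0.15 Hz
#' (matching the spectral floor of the sway analysis) is applied to the
#' acceleration, after trapezoidal integration to velocity, and again after
#' integration to displacement, so that integrator drift and any constant
#' sensor bias are removed at each stage. The first and last second are
#' cosine-tapered before filtering to limit end transients. Outputs are
#' zero-mean.
#'
#' @param acc_ap,acc_ml horizontal acceleration series in m/s^2, uniformly
#'   sampled.
#' @param rate sampling rate in Hz.
#' @param corner high-pass corner frequency in Hz.
#' @return list with zero-mean displacement series `ap` and `ml` (m) and the
#'   `rate`.
#' @export
estimate_displacement <- function(acc_ap, acc_ml, rate, corner = 0.15) {
  stopifnot(length(acc_ap) == length(acc_ml))
  # filtfilt runs the filter forward and backward: order-2 design, order-4
  # zero-phase response
  hp <- signal::butter(2, corner / (rate / 2), type = "high")
  one_axis <- function(a) {
    a <- taper_ends(a - mean(a), rate)
    a <- signal::filtfilt(hp, a)
    v <- pracma::cumtrapz(a)[, 1] / rate
    v <- signal::filtfilt(hp, v)
    d <- pracma::cumtrapz(v)[, 1] / rate
    d <- signal::filtfilt(hp, d)
    d - mean(d)
  }
  list(ap = one_axis(acc_ap), ml = one_axis(acc_ml), rate = rate)
}

# cosine taper over the first/last `sec` seconds
taper_ends <- function(x, rate, sec = 1) {
  n <- length(x)
  m <- min(round(sec * rate), floor(n / 2))
  if (m < 2) return(x)
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = m)))
  x[1:m] <- x[1:m] * ramp
  x[(n - m + 1):n] <- x[(n - m + 1):n] * rev(ramp)
  x
}
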
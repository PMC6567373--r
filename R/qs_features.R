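# Quiet-standing sway measures: spectral shape of the horizontal
# acceleration, its time-domain dispersion and smoothness, and geometry of
# the estimated center-of-mass displacement. 23 measures in total.

#' Spectral shape measures of postural sway
#'
#' From a band-limited power spectrum: centroidal frequency
#' `CF = sqrt(mu2/mu0)`, the frequencies below which 50% and 95% of the
#' total power lie (smallest grid frequency whose cumulative power reaches
#' the fraction), frequency dispersion `FD = sqrt(1 - mu1^2/(mu0 mu2))`
#' (0 for a pure sinusoid, grows with bandwidth, <= 1 by Cauchy-Schwarz) and
#' the spectral entropy `SE = -sum(p_i log p_i)/log N` with
#' `p_i = PSD_i/TP`, normalized to `[0, 1]` by the number of retained bins.
#'
#' @param psd a [band_limited_psd()] estimate with at least 2 retained bins.
#' @return named numeric vector `CF`, `F50`, `F95`, `FD`, `SE`.
#' @export
spectral_features <- function(psd) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (psd$n_bins < 2 || psd$TP <= 0)
    stop("spectrum undefined: needs >= 2 retained bins with positive power",
         call. = FALSE)
  g <- cumsum(psd$psd)
  f50 <- psd$f[which(g >= 0.50 * psd$TP)[1]]
  f95 <- psd$f[which(g >= 0.95 * psd$TP)[1]]
  p <- psd$psd / psd$TP
  p <- p[p > 0]
  c(CF = sqrt(psd$mu2 / psd$mu0),
    F50 = f50, F95 = f95,
    FD = sqrt(max(0, 1 - psd$mu1^2 / (psd$mu0 * psd$mu2))),
    SE = -sum(p * log(p)) / log(psd$n_bins))
}

#' Time-domain sway measures of one acceleration axis
#'
#' RMS about the mean, range, and the normalized jerk score
#' `NJS = sqrt(T^5 / (2 SP^2) * integral(adot^2 dt))`, where `SP` is the
#' one-dimensional path length of the same acceleration component
#' (`sum |delta a|`) and `adot` is obtained by central finite differences.
#' Higher NJS = less smooth sway. For a constant signal SP = 0 and NJS is
#' undefined: it is returned as `NA` (flagged missing), not an error.
#'
#' @param x uniformly sampled acceleration series (m/s^2), N >= 3.
#' @param rate sampling rate in Hz.
#' @return named numeric vector `RMS`, `Range`, `NJS`.
#' @export
sway_time_features <- function(x, rate) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("series too short: need at least 3 samples", call. = FALSE)
  T <- (n - 1) / rate
  rms <- sqrt(mean((x - mean(x))^2))
  rng <- max(x) - min(x)
  sp <- sum(abs(diff(x)))
  njs <- if (sp == 0) NA_real_ else {
    ad <- central_diff(x, rate)
    sqrt(T^5 / (2 * sp^2) * pracma::trapz(seq(0, T, length.out = n), ad^2))
  }
  c(RMS = rms, Range = rng, NJS = njs)
}

central_diff <- function(x, rate) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  d
}

#' Geometry of the planar sway trajectory
#'
#' From zero-mean AP/ML displacement estimates: per-axis sway path
#' `SP = sum |delta s|` and planar path `sum sqrt(dap^2 + dml^2)` (the total
#' length of the trajectory), mean sway velocity `MV = SP/T` per axis, the
#' sway area swept with respect to the mean point (sum of triangle areas
#' formed by consecutive points and the mean), and the 95% confidence
#' ellipse area `EA = pi * 5.991 * sqrt(det(cov))` (5.991 is the 0.95
#' quantile of a chi-square with 2 df).
#'
#' @param d_ap,d_ml equal-length displacement series in meters.
#' @param T observation time in seconds.
#' @return named numeric vector `SP_AP`, `SP_ML`, `SP_Planar`, `MV_AP`,
#'   `MV_ML`, `SA`, `EA`.
#' @export
displacement_features <- function(d_ap, d_ml, T) {
  if (length(d_ap) != length(d_ml))
    stop("displacement series must have equal length", call. = FALSE)
  sp_ap <- sum(abs(diff(d_ap)))
  sp_ml <- sum(abs(diff(d_ml)))
  sp_pl <- sum(sqrt(diff(d_ap)^2 + diff(d_ml)^2))
  m_ap <- mean(d_ap); m_ml <- mean(d_ml)
  n <- length(d_ap)
  a <- d_ap - m_ap; b <- d_ml - m_ml
  sa <- 0.5 * sum(abs(a[-1] * b[-n] - a[-n] * b[-1]))
  ea <- pi * stats::qchisq(0.95, df = 2) *
    sqrt(max(0, det(stats::cov(cbind(d_ap, d_ml)))))
  c(SP_AP = sp_ap, SP_ML = sp_ml, SP_Planar = sp_pl,
    MV_AP = sp_ap / T, MV_ML = sp_ml / T, SA = sa, EA = ea)
}

#' Names of the 23 quiet-standing measures
#' @return character vector in canonical order, matching the published
#'   loading-table row names.
#' @export
qs_measure_names <- function() {
  c("RMS A AP", "RMS A ML", "Range A AP", "Range A ML", "NJS AP", "NJS ML",
    "CF AP", "CF ML", "F50 AP", "F50 ML", "F95 AP", "F95 ML",
    "FD AP", "FD ML", "SE AP", "SE ML",
    "SP AP DISPL", "SP ML DISPL", "SP Planar DISPL",
    "MV AP DISPL", "MV ML DISPL", "SA DISPL", "EA DISPL")
}

#' Jerk-score measures of each test (log-transformed before factor analysis)
#' @param test `"qs"`, `"7mw"` or `"cst"`.
#' @return character vector of measure names.
#' @export
jerk_measure_names <- function(test = c("qs", "7mw", "cst")) {
  switch(match.arg(test),
         qs = c("NJS AP", "NJS ML"),
         `7mw` = c("NJS AP", "NJS ML", "NJS V"),
         cst = c("Sts JS AP", "Sts JS ML", "Sts JS V",
                 "stS JS AP", "stS JS ML", "stS JS V"))
}

#' Extract the 23 quiet-standing measures from a recording
#'
#' Resamples the recording to a uniform rate, then computes per horizontal
#' axis (AP, ML) the spectral measures (CF, F50, F95, FD, SE) from the
#' band-limited Welch spectrum and the time-domain measures (RMS, Range,
#' NJS) of the acceleration, plus the displacement-based measures (sway
#' path, mean velocity, sway area, ellipse area) from the drift-suppressed
#' double integral of the horizontal acceleration.
#'
#' @param rec an [imu_recording()] with `test_label = "QS"`, at least 20 s.
#' @param rate processing rate in Hz.
#' @return named numeric vector of the 23 measures ([qs_measure_names()]).
#' @examples
#' rec <- generate_qs_recording(0.06, 0.04, seed = 7)
#' extract_qs_features(rec)[c("RMS A AP", "CF AP", "SA DISPL")]
#' @export
extract_qs_features <- function(rec, rate = 100) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rec$test_label != "QS")
    stop("expected a QS recording, got ", rec$test_label, call. = FALSE)
  if (recording_duration(rec) < 20)
    stop("QS recording shorter than 20 s", call. = FALSE)
  u <- resample_uniform(rec, rate)
  T <- u$duration
  out <- numeric(0)
  spec <- list(); tf <- list()
  for (ax in c("ap", "ml")) {
    x <- u$channels[[paste0("acc_", ax)]]
    spec[[ax]] <- spectral_features(band_limited_psd(x, rate))
    tf[[ax]] <- sway_time_features(x, rate)
  }
  disp <- estimate_displacement(u$channels$acc_ap, u$channels$acc_ml, rate)
  df <- displacement_features(disp$ap, disp$ml, T)
  out <- c(
    "RMS A AP" = unname(tf$ap["RMS"]), "RMS A ML" = unname(tf$ml["RMS"]),
    "Range A AP" = unname(tf$ap["Range"]),
    "Range A ML" = unname(tf$ml["Range"]),
    "NJS AP" = unname(tf$ap["NJS"]), "NJS ML" = unname(tf$ml["NJS"]),
    "CF AP" = unname(spec$ap["CF"]), "CF ML" = unname(spec$ml["CF"]),
    "F50 AP" = unname(spec$ap["F50"]), "F50 ML" = unname(spec$ml["F50"]),
    "F95 AP" = unname(spec$ap["F95"]), "F95 ML" = unname(spec$ml["F95"]),
    "FD AP" = unname(spec$ap["FD"]), "FD ML" = unname(spec$ml["FD"]),
    "SE AP" = unname(spec$ap["SE"]), "SE ML" = unname(spec$ml["SE"]),
    "SP AP DISPL" = unname(df["SP_AP"]), "SP ML DISPL" = unname(df["SP_ML"]),
    "SP Planar DISPL" = unname(df["SP_Planar"]),
    "MV AP DISPL" = unname(df["MV_AP"]), "MV ML DISPL" = unname(df["MV_ML"]),
    "SA DISPL" = unname(df["SA"]), "EA DISPL" = unname(df["EA"])
  )
  out[qs_measure_names()]
}
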
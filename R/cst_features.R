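# Chair-stand measures: segmentation of the 5 sit-to-stand (Sts) and 5
# stand-to-sit (stS) transitions from the ML angular velocity, then per-phase
# duration, smoothness and amplitude statistics. 31 measures in total.

#' Segment a chair-stand recording into postural transitions
#'
#' Transitions appear as bursts in the low-pass-filtered (1.5 Hz) ML angular
#' velocity: contiguous regions where its magnitude exceeds 10% of the
#' maximum, with boundaries at the threshold crossings. Bursts shorter than
#' 0.2 s are discarded. The two kinds are disambiguated by the polarity of
#' the low-pass AP acceleration at burst onset (forward lean is positive
#' when rising from the chair); if polarity is ambiguous the phases are
#' labelled by alternation starting from seated (Sts first). A complete test
#' has exactly 5 phases of each kind.
#'
#' @param rec an [imu_recording()] with `test_label = "CST"` and gyroscope.
#' @param n_cycles expected number of stand-up/sit-down cycles.
#' @param rate processing rate in Hz.
#' @param min_amp minimum peak ML angular velocity (deg/s) for the recording
#'   to contain any postural transition at all; trunk pitch during a
#'   chair rise is far above this floor.
#' @return An object of class `transition_segmentation`: data frame with
#'   columns `kind` (`"Sts"`/`"stS"`), `start`, `end` (seconds).
#' @export
segment_transitions <- function(rec, n_cycles = 5, rate = 100, min_amp = 10) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rec$test_label != "CST")
    stop("expected a CST recording, got ", rec$test_label, call. = FALSE)
  if (is.null(rec$gyro))
    stop("CST segmentation requires gyroscope channels", call. = FALSE)
  u <- resample_uniform(rec, rate)
  lp <- signal::butter(2, 1.5 / (rate / 2), type = "low")
  w <- abs(signal::filtfilt(lp, u$channels$gyro_ml))
  if (max(w) < min_amp) stop("no transitions detected", call. = FALSE)
  thr <- 0.1 * max(w)
  above <- w > thr
  if (!any(above)) stop("no transitions detected", call. = FALSE)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths / rate) > 0.2
  if (!any(keep)) stop("no transitions detected", call. = FALSE)
  bursts <- data.frame(start = u$t[starts[keep]], end = u$t[ends[keep]])
  if (nrow(bursts) < 2 * n_cycles)
    stop(sprintf("incomplete test: %d transitions detected, expected %d",
                 nrow(bursts), 2 * n_cycles), call. = FALSE)
  if (nrow(bursts) > 2 * n_cycles) {
    # keep the longest bursts, restore temporal order
    len <- bursts$end - bursts$start
    bursts <- bursts[order(-len)[seq_len(2 * n_cycles)], ]
    bursts <- bursts[order(bursts$start), ]
  }
  ap <- signal::filtfilt(lp, u$channels$acc_ap - mean(u$channels$acc_ap))
  kind <- vapply(seq_len(nrow(bursts)), function(i) {
    i0 <- max(1, round(bursts$start[i] * rate) + 1)
    i1 <- min(length(ap), i0 + round(0.3 * rate))
    if (mean(ap[i0:i1]) >= 0) "Sts" else "stS"
  }, character(1))
  expect_alt <- rep_len(c("Sts", "stS"), nrow(bursts))
  if (!identical(kind, expect_alt)) kind <- expect_alt
  seg <- data.frame(kind = kind, start = bursts$start, end = bursts$end)
  class(seg) <- c("transition_segmentation", "data.frame")
  seg
}

#' Names of the 31 chair-stand measures
#' @return character vector in canonical order, matching the published
#'   loading-table row names.
#' @export
cst_measure_names <- function() {
  per_kind <- function(k)
    c(paste("Duration", k), paste("SD Duration", k),
      paste(k, "JS", c("AP", "ML", "V")),
      paste(k, "A RMS", c("AP", "ML", "V")),
      paste(k, "A Range", c("AP", "ML", "V")),
      paste(k, "G RMS", c("AP", "ML")),
      paste(k, "G Range", c("AP", "ML")))
  c("Total Duration", per_kind("Sts"), per_kind("stS"))
}

#' Extract the 31 chair-stand measures
#'
#' For each phase kind (Sts, stS), statistics are computed within each of
#' the 5 repetitions and then pooled: mean and SD of the phase duration,
#' per-axis normalized jerk score of the acceleration
#' (`sqrt(T^5/2 * integral(adot^2 dt))`, `T` = repetition duration, averaged
#' over repetitions), and acceleration RMS/Range (AP, ML, V) and gyroscope
#' RMS/Range (AP, ML) averaged over repetitions. Total Duration runs from
#' the start of the first phase to the end of the last. Acceleration samples
#' beyond +/- 2 g (sitting impacts) are winsorized at the range limit before
#' feature computation.
#'
#' @param rec an [imu_recording()] with `test_label = "CST"`.
#' @param seg a [segment_transitions()] result for the same recording (by
#'   default computed on the fly).
#' @param rate processing rate in Hz.
#' @return named numeric vector of the 31 measures ([cst_measure_names()]).
#' @examples
#' rec <- generate_cst_recording(seed = 11)
#' extract_cst_features(rec)[c("Total Duration", "Duration Sts")]
#' @export
extract_cst_features <- function(rec, seg = segment_transitions(rec, rate = rate),
                                 rate = 100) {
  stopifnot(inherits(rec, "imu_recording"),
            inherits(seg, "transition_segmentation"))
  if (max(seg$end) > recording_duration(rec) + 1e-9)
    stop("segmentation extends beyond the recording", call. = FALSE)
  u <- resample_uniform(rec, rate)
  lim <- 2 * G_MS2
  for (ch in c("acc_ap", "acc_ml", "acc_v"))
    u$channels[[ch]] <- pmin(pmax(u$channels[[ch]], -lim), lim)
  slice <- function(x, i) {
    i0 <- max(1, round(seg$start[i] * rate) + 1)
    i1 <- min(length(x), round(seg$end[i] * rate) + 1)
    x[i0:i1]
  }
  out <- c("Total Duration" = max(seg$end) - min(seg$start))
  for (k in c("Sts", "stS")) {
    idx <- which(seg$kind == k)
    durs <- seg$end[idx] - seg$start[idx]
    out[paste("Duration", k)] <- mean(durs)
    out[paste("SD Duration", k)] <- stats::sd(durs)
    for (ax in c("ap", "ml", "v")) {
      AX <- toupper(ax)
      a <- u$channels[[paste0("acc_", ax)]]
      njs <- rms <- rng <- numeric(0)
      for (i in idx) {
        s <- slice(a, i)
        T <- (length(s) - 1) / rate
        ad <- central_diff(s, rate)
        njs <- c(njs, sqrt(T^5 / 2 *
                             pracma::trapz(seq(0, T, length.out = length(s)),
                                           ad^2)))
        rms <- c(rms, sqrt(mean((s - mean(s))^2)))
        rng <- c(rng, max(s) - min(s))
      }
      out[paste(k, "JS", AX)] <- mean(njs)
      out[paste(k, "A RMS", AX)] <- mean(rms)
      out[paste(k, "A Range", AX)] <- mean(rng)
    }
    for (ax in c("ap", "ml")) {
      AX <- toupper(ax)
      g <- u$channels[[paste0("gyro_", ax)]]
      rms <- rng <- numeric(0)
      for (i in idx) {
        s <- slice(g, i)
        rms <- c(rms, sqrt(mean((s - mean(s))^2)))
        rng <- c(rng, max(s) - min(s))
      }
      out[paste(k, "G RMS", AX)] <- mean(rms)
      out[paste(k, "G Range", AX)] <- mean(rng)
    }
  }
  out[cst_measure_names()]
}
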
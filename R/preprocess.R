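#' Single-channel signal
#'
#' Light container for one angular-velocity channel (or a min-max normalized
#' version of it) together with its sampling rate.
#'
#' @param values Numeric vector, length >= 3, no missing values required at
#'   construction (QC handles those).
#' @param sample_rate_hz Positive sampling rate in Hz.
#' @param representation `"original"` (deg/s) or `"normalized"` (unitless,
#'   in \[0, 1\]).
#' @return An object of class `psm_signal`.
#' @export
psm_signal <- function(values, sample_rate_hz,
                       representation = c("original", "normalized")) {
  representation <- match.arg(representation)
  if (length(values) < 3L) stop_integrity("signal must have at least 3 samples")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop_usage("sample_rate_hz must be positive")
  }
  structure(list(values = as.numeric(values),
                 sample_rate_hz = as.numeric(sample_rate_hz),
                 representation = representation),
            class = "psm_signal")
}

#' Extract one gyroscope axis as a signal
#'
#' Analysis concentrates on the X axis, which tracks knee flexion-extension
#' during the pivot-shift maneuver; Y and Z are available for QC and
#' exploration.
#'
#' @param rec A [gyro_recording()].
#' @param axis `"X"`, `"Y"` or `"Z"`.
#' @return A [psm_signal()] with `representation = "original"`.
#' @export
select_axis <- function(rec, axis = c("X", "Y", "Z")) {
  stopifnot(inherits(rec, "gyro_recording"))
  axis <- match.arg(axis)
  values <- switch(axis, X = rec$omega_x, Y = rec$omega_y, Z = rec$omega_z)
  psm_signal(values, rec$sample_rate_hz, "original")
}

#' Quality-control rule thresholds
#'
#' Defaults: duration 1--10 s, at least 50 samples, no non-finite samples,
#' saturation when more than 5\% of samples on any axis reach +/-2000 deg/s,
#' and a minimum smoothed peak of 5 deg/s on the X axis. The amplitude floor
#' is evaluated on a moving-average smoothed trace (window
#' `smooth_window_s`); a raw-sample peak would be met by the noise floor
#' alone and would never catch a misplaced device.
#'
#' @param duration_range Length-2 numeric, admissible recording duration (s).
#' @param min_samples Minimum number of samples.
#' @param max_nan_frac Maximum tolerated fraction of non-finite samples.
#' @param saturation_limit Angular velocity treated as sensor saturation (deg/s).
#' @param saturation_frac Fraction of saturated samples above which the test fails.
#' @param amplitude_floor Minimum smoothed peak |omega_x| (deg/s).
#' @param smooth_window_s Moving-average window for the amplitude rule (s).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(duration_range = c(1, 10), min_samples = 50,
                      max_nan_frac = 0, saturation_limit = 2000,
                      saturation_frac = 0.05, amplitude_floor = 5,
                      smooth_window_s = 0.1) {
  structure(list(duration_range = duration_range, min_samples = min_samples,
                 max_nan_frac = max_nan_frac,
                 saturation_limit = saturation_limit,
                 saturation_frac = saturation_frac,
                 amplitude_floor = amplitude_floor,
                 smooth_window_s = smooth_window_s),
            class = "qc_config")
}

moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) < k) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  sm[!is.na(sm)]
}

#' Run quality control on a recording
#'
#' Mirrors the screening step that discards tests with technical failures,
#' incorrect device placement or incorrect maneuver execution. Failures are
#' report content, not errors; the report carries stable machine-readable
#' reason codes: `DURATION_OUT_OF_RANGE`, `NAN_SAMPLES`, `SATURATION`,
#' `FLATLINE`, `AMPLITUDE_FLOOR`.
#'
#' @param rec A [gyro_recording()].
#' @param rules A [qc_config()].
#' @return List of class `qc_report` with `test_id`, `passed`, `reasons`.
#' @export
run_qc <- function(rec, rules = qc_config()) {
  stopifnot(inherits(rec, "gyro_recording"))
  reasons <- character()
  n <- length(rec$t)
  duration <- rec$t[n] - rec$t[1]
  if (duration < rules$duration_range[1] || duration > rules$duration_range[2] ||
      n < rules$min_samples) {
    reasons <- c(reasons, "DURATION_OUT_OF_RANGE")
  }
  all_axes <- c(rec$omega_x, rec$omega_y, rec$omega_z)
  if (mean(!is.finite(all_axes)) > rules$max_nan_frac) {
    reasons <- c(reasons, "NAN_SAMPLES")
  }
  finite_x <- rec$omega_x[is.finite(rec$omega_x)]
  if (length(finite_x)) {
    sat <- vapply(list(rec$omega_x, rec$omega_y, rec$omega_z), function(a) {
      a <- a[is.finite(a)]
      if (!length(a)) return(0)
      mean(abs(a) >= rules$saturation_limit)
    }, numeric(1))
    if (any(sat > rules$saturation_frac)) reasons <- c(reasons, "SATURATION")
    if (stats::var(finite_x) == 0) reasons <- c(reasons, "FLATLINE")
    k <- round(rules$smooth_window_s * rec$sample_rate_hz)
    smoothed <- moving_average(finite_x, k)
    if (max(abs(smoothed)) < rules$amplitude_floor) {
      reasons <- c(reasons, "AMPLITUDE_FLOOR")
    }
  }
  structure(list(test_id = rec$test_id, passed = length(reasons) == 0L,
                 reasons = reasons),
            class = "qc_report")
}

#' Min-max normalize a signal to \[0, 1\]
#'
#' Maps values by `(x - min) / (max - min)`, so the minimum maps exactly to 0
#' and the maximum exactly to 1. Normalization is computed over the whole
#' test signal, before segmentation, so inter-segment amplitude ratios
#' survive.
#'
#' @param sig A [psm_signal()].
#' @return A [psm_signal()] with `representation = "normalized"`.
#' @export
normalize_signal <- function(sig) {
  stopifnot(inherits(sig, "psm_signal"))
  rng <- range(sig$values)
  if (!all(is.finite(rng))) stop_degenerate("signal contains non-finite values")
  if (rng[1] == rng[2]) {
    stop_degenerate("constant signal cannot be min-max normalized")
  }
  psm_signal((sig$values - rng[1]) / (rng[2] - rng[1]),
             sig$sample_rate_hz, "normalized")
}

#' Split a signal into the three contiguous segments S1, S2, S3
#'
#' The trace is divided into three sections; the final section S3 carries
#' the tibial reduction ("shift") event and most of the analysis features.
#' The default strategy is equal thirds with `|S1| = |S2| = floor(n/3)` and
#' the remainder appended to S3. An explicit-boundary strategy supports
#' event-aligned analyses: `boundaries = c(b1, b2)` puts samples `1..b1` in
#' S1, `(b1+1)..b2` in S2 and the rest in S3.
#'
#' @param sig A [psm_signal()] with at least 3 samples.
#' @param strategy `"equal_thirds"` or `"explicit"`.
#' @param boundaries Length-2 integer cut indices, required for
#'   `strategy = "explicit"`; `1 <= b1 < b2 < n`.
#' @return An object of class `segmented_signal`: list with `psm_signal`
#'   elements `S1`, `S2`, `S3`, plus `boundaries` and `representation`.
#' @export
segment_signal <- function(sig, strategy = c("equal_thirds", "explicit"),
                           boundaries = NULL) {
  stopifnot(inherits(sig, "psm_signal"))
  strategy <- match.arg(strategy)
  n <- length(sig$values)
  if (n < 3L) stop_integrity("cannot segment a signal shorter than 3 samples")
  if (strategy == "equal_thirds") {
    k <- n %/% 3L
    boundaries <- c(k, 2L * k)
  } else {
    if (is.null(boundaries) || length(boundaries) != 2L) {
      stop_usage("explicit strategy requires boundaries = c(b1, b2)")
    }
    boundaries <- as.integer(boundaries)
    if (boundaries[1] < 1L || boundaries[1] >= boundaries[2] ||
        boundaries[2] >= n) {
      stop_usage("boundaries must satisfy 1 <= b1 < b2 < n")
    }
  }
  b <- boundaries
  seg <- function(idx) psm_signal_unchecked(sig$values[idx], sig$sample_rate_hz,
                                            sig$representation)
  structure(list(S1 = seg(seq_len(b[1])),
                 S2 = seg((b[1] + 1L):b[2]),
                 S3 = seg((b[2] + 1L):n),
                 boundaries = b,
                 representation = sig$representation),
            class = "segmented_signal")
}

# Segments may legitimately be 1-2 samples long under explicit boundaries;
# bypass the >=3 constructor check while keeping the same shape.
psm_signal_unchecked <- function(values, sample_rate_hz, representation) {
  structure(list(values = as.numeric(values),
                 sample_rate_hz = sample_rate_hz,
                 representation = representation),
            class = "psm_signal")
}
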
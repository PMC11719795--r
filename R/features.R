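#' One-sided Fourier magnitude spectrum
#'
#' Returns `|X_k|` for bins `k = 0 .. floor(n/2)` at frequencies `k * fs / n`,
#' with no normalization of the DFT sum.
#'
#' @param sig A [psm_signal()] with at least 4 samples.
#' @return List of class `psm_spectrum` with `freqs_hz` and `magnitude`.
#' @export
fourier_magnitude <- function(sig) {
  stopifnot(inherits(sig, "psm_signal"))
  n <- length(sig$values)
  if (n < 4L) stop_integrity("need at least 4 samples for a spectrum")
  k <- 0:(n %/% 2L)
  mag <- Mod(stats::fft(sig$values))[k + 1L]
  structure(list(freqs_hz = k * sig$sample_rate_hz / n, magnitude = mag),
            class = "psm_spectrum")
}

#' Basic amplitude statistics of a segment
#'
#' `range = max - min`; `rx = range + mean` (the "range plus average"
#' composite used for class assignment); `std` is the population standard
#' deviation (denominator `n`).
#'
#' @param values Non-empty numeric vector.
#' @return Named list: `max`, `min`, `mean`, `range`, `std`, `rx`.
#' @export
segment_stats <- function(values) {
  if (!length(values)) stop_usage("segment_stats needs a non-empty input")
  values <- as.numeric(values)
  mx <- max(values); mn <- min(values); mu <- mean(values)
  list(max = mx, min = mn, mean = mu, range = mx - mn,
       std = sqrt(mean((values - mu)^2)), rx = (mx - mn) + mu)
}

#' Slope and ordinate of the least-squares line through a segment
#'
#' Ordinary least squares of value against elapsed time `0, dt, 2*dt, ...`;
#' the ordinate is the intercept at the segment start.
#'
#' @param values Numeric vector, length >= 2.
#' @param dt_s Sampling interval in seconds (or any positive abscissa step).
#' @return Named list: `slope` (units per second), `ordinate`.
#' @export
linreg_features <- function(values, dt_s) {
  if (length(values) < 2L) stop_usage("linear regression needs >= 2 points")
  if (!is.numeric(dt_s) || dt_s <= 0) stop_usage("dt_s must be positive")
  y <- as.numeric(values)
  x <- (seq_along(y) - 1) * dt_s
  xc <- x - mean(x)
  slope <- sum(xc * (y - mean(y))) / sum(xc^2)
  list(slope = slope, ordinate = mean(y) - slope * mean(x))
}

#' Shannon entropy of a segment's energy distribution
#'
#' The squared samples are normalized into a probability distribution
#' `p_i = x_i^2 / sum(x_j^2)` and `H = -sum(p_i log2 p_i)` is returned in
#' bits; zero-energy terms contribute 0, and an all-zero input returns 0 by
#' convention. Binning-free and deterministic.
#'
#' @param values Non-empty numeric vector.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(values) {
  if (!length(values)) stop_usage("shannon_entropy needs a non-empty input")
  e <- as.numeric(values)^2
  s <- sum(e)
  if (s == 0) return(0)
  p <- e / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Registered feature names
#'
#' The class set characterises segment 3 of the min-max normalized trace
#' (`S3n-*`) plus the slope of the regression over the Fourier magnitude of
#' normalized S3 (`S3TF-P`). The grade set works on the original (deg/s)
#' representation, except `S3TF-P` which is shared with the class set.
#'
#' @return Character vector of feature names.
#' @name feature_registry
NULL

#' @rdname feature_registry
#' @export
class_feature_names <- function() {
  c("S3n-STD", "S3n-R", "S3n-Rx", "S3n-O", "S3TF-P")
}

#' @rdname feature_registry
#' @export
grade_feature_names <- function() {
  c("S1-Max", "S3-Max", "S2-R", "S3-R", "S3-STD", "S3-We", "S3TF-P")
}

#' @rdname feature_registry
#' @export
all_feature_names <- function() {
  union(class_feature_names(), grade_feature_names())
}

# Slope of |X(f)| against frequency (Hz) over bins k >= 1 (DC excluded).
spectrum_slope <- function(spectrum) {
  mag <- spectrum$magnitude[-1]
  if (length(mag) < 2L) stop_integrity("spectrum too short for a slope")
  df <- spectrum$freqs_hz[2] - spectrum$freqs_hz[1]
  linreg_features(mag, df)$slope
}

#' Class-assignment features from normalized segment 3
#'
#' Computes the five features used to assign a test to a maneuver-execution
#' class: population standard deviation (`S3n-STD`), range (`S3n-R`), range
#' plus segment mean (`S3n-Rx`) and regression ordinate (`S3n-O`) of the
#' normalized S3 time series, plus `S3TF-P`, the regression slope of the
#' Fourier magnitude of normalized S3 over bins `k >= 1`.
#'
#' @param seg_norm A `segmented_signal` of the normalized representation.
#' @param spec_n Optional [fourier_magnitude()] spectrum of normalized S3;
#'   computed from `seg_norm$S3` when `NULL`.
#' @return Named numeric vector over [class_feature_names()].
#' @export
extract_class_features <- function(seg_norm, spec_n = NULL) {
  stopifnot(inherits(seg_norm, "segmented_signal"))
  if (seg_norm$representation != "normalized") {
    stop_usage("class features are defined on the normalized representation")
  }
  s3 <- seg_norm$S3
  if (is.null(spec_n)) spec_n <- fourier_magnitude(s3)
  st <- segment_stats(s3$values)
  lr <- linreg_features(s3$values, 1 / s3$sample_rate_hz)
  out <- c(st$std, st$range, st$rx, lr$ordinate, spectrum_slope(spec_n))
  names(out) <- class_feature_names()
  if (!all(is.finite(out))) stop_degenerate("non-finite class feature")
  out
}

#' Grade-assignment features from the original-representation segments
#'
#' Computes the seven features used to grade the injury within a maneuver
#' class: segment maxima `S1-Max` and `S3-Max`, ranges `S2-R` and `S3-R`,
#' population standard deviation `S3-STD` and energy Shannon entropy `S3-We`
#' of the original (deg/s) segments, plus the shared Fourier-slope feature
#' `S3TF-P` computed on normalized S3.
#'
#' @param seg_orig A `segmented_signal` of the original representation.
#' @param spec_n Spectrum of normalized S3 (see [extract_class_features()]);
#'   required because `S3TF-P` is defined on the normalized representation.
#' @return Named numeric vector over [grade_feature_names()].
#' @export
extract_grade_features <- function(seg_orig, spec_n) {
  stopifnot(inherits(seg_orig, "segmented_signal"))
  if (seg_orig$representation != "original") {
    stop_usage("grade features are defined on the original representation")
  }
  s1 <- segment_stats(seg_orig$S1$values)
  s2 <- segment_stats(seg_orig$S2$values)
  s3 <- segment_stats(seg_orig$S3$values)
  out <- c(s1$max, s3$max, s2$range, s3$range, s3$std,
           shannon_entropy(seg_orig$S3$values), spectrum_slope(spec_n))
  names(out) <- grade_feature_names()
  if (!all(is.finite(out))) stop_degenerate("non-finite grade feature")
  out
}

#' Full feature vector of one recording
#'
#' Convenience wrapper running the whole per-test pipeline: X-axis selection,
#' whole-signal min-max normalization, equal-thirds segmentation of both
#' representations, and both feature sets. `S3TF-P` appears once.
#'
#' @param rec A [gyro_recording()].
#' @return Named numeric vector over [all_feature_names()].
#' @export
extract_features <- function(rec) {
  sig <- select_axis(rec, "X")
  seg_o <- segment_signal(sig)
  sig_n <- normalize_signal(sig)
  seg_n <- segment_signal(sig_n)
  spec_n <- fourier_magnitude(seg_n$S3)
  cf <- extract_class_features(seg_n, spec_n)
  gf <- extract_grade_features(seg_o, spec_n)
  c(cf, gf[setdiff(names(gf), names(cf))])[all_feature_names()]
}

#' Feature table for a dataset
#'
#' Applies QC and feature extraction to every manifest row with
#' `include_flag = TRUE`. QC failures are excluded from the table and
#' returned alongside it with their reason codes, mirroring the screening
#' that discards non-standard tests before analysis.
#'
#' @param manifest Manifest data frame (see [read_manifest()]).
#' @param dir Directory signal paths are relative to.
#' @param rules A [qc_config()].
#' @param qc Set `FALSE` to skip QC screening (all rows kept).
#' @return List with `features` (data.frame: `test_id` + feature columns) and
#'   `qc_failures` (data.frame: `test_id`, `reasons`).
#' @export
feature_table <- function(manifest, dir = ".", rules = qc_config(), qc = TRUE) {
  validate_manifest(manifest)
  manifest <- manifest[manifest$include_flag, , drop = FALSE]
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    if (!file.path_is_absolute(p)) p <- file.path(dir, p)
    rec <- read_recording(p, test_id = manifest$test_id[i])
    if (qc) {
      rep <- run_qc(rec, rules)
      if (!rep$passed) {
        fails[[length(fails) + 1L]] <- data.frame(
          test_id = rec$test_id, reasons = paste(rep$reasons, collapse = ";"))
        next
      }
    }
    fv <- extract_features(rec)
    rows[[length(rows) + 1L]] <- data.frame(test_id = rec$test_id,
                                            t(fv), check.names = FALSE)
  }
  features <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = 1 + length(all_feature_names()))),
                    c("test_id", all_feature_names()))
  qc_failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(test_id = character(), reasons = character())
  list(features = features, qc_failures = qc_failures)
}

file.path_is_absolute <- function(p) {
  grepl("^(/|[A-Za-z]:[\\\\/]|\\\\\\\\)", p)
}
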
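#' Construct a gyroscope recording of one pivot-shift test
#'
#' A `gyro_recording` holds the time base and the three angular-velocity
#' channels captured by a smartphone gyroscope strapped to the tibia during
#' one pivot-shift maneuver, plus the clinical metadata needed downstream
#' (side, context, evaluator, IKDC grade and maneuver-class label when known).
#'
#' Units are fixed: seconds for `t`, degrees per second for the angular
#' velocities. No unit auto-detection is attempted because phone gyroscope
#' APIs disagree; a single convention keeps features comparable across tests.
#'
#' @param test_id Single string identifying the test.
#' @param t Numeric vector of sample times in seconds, strictly increasing,
#'   length at least 2.
#' @param omega_x,omega_y,omega_z Numeric vectors of angular velocity (deg/s)
#'   about the device X, Y and Z axes; same length as `t`.
#' @param sample_rate_hz Nominal sampling rate. If `NULL` it is derived as
#'   `1 / median(diff(t))`. A supplied rate inconsistent with the time base
#'   by more than 5\% is an integrity error.
#' @param meta Named list of clinical metadata. Recognised fields: `side`
#'   ("L"/"R"), `context` ("office", "preop", "postop", "followup"),
#'   `evaluator_id`, `ikdc_grade` (0--3 or `NA`), `class_label` (1--8 or
#'   `NA`). Missing fields default to `NA`.
#'
#' @return An object of class `gyro_recording`.
#' @export
gyro_recording <- function(test_id, t, omega_x, omega_y, omega_z,
                           sample_rate_hz = NULL, meta = list()) {
  if (!is.character(test_id) || length(test_id) != 1L || is.na(test_id)) {
    stop_usage("test_id must be a single non-missing string")
  }
  n <- length(t)
  if (n < 2L) stop_integrity("recording must have at least 2 samples")
  if (length(omega_x) != n || length(omega_y) != n || length(omega_z) != n) {
    stop_integrity("t, omega_x, omega_y, omega_z must have equal length")
  }
  t <- as.numeric(t)
  if (anyNA(t) || any(diff(t) <= 0)) {
    stop_integrity("t must be strictly increasing with no missing values")
  }
  implied <- 1 / stats::median(diff(t))
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- implied
  } else {
    if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
      stop_usage("sample_rate_hz must be a positive number")
    }
    if (abs(sample_rate_hz - implied) / sample_rate_hz > 0.05) {
      stop_integrity(sprintf(
        "sample_rate_hz (%.4g) inconsistent with median(diff(t)) (implies %.4g Hz)",
        sample_rate_hz, implied))
    }
  }
  meta_full <- list(side = NA_character_, context = NA_character_,
                    evaluator_id = NA_character_, ikdc_grade = NA_integer_,
                    class_label = NA_integer_)
  meta_full[names(meta)] <- meta
  if (!is.na(meta_full$side) && !meta_full$side %in% c("L", "R")) {
    stop_format("meta$side must be 'L' or 'R'")
  }
  if (!is.na(meta_full$context) && !meta_full$context %in% manifest_contexts()) {
    stop_format(sprintf("meta$context must be one of %s",
                        paste(manifest_contexts(), collapse = ", ")))
  }
  if (!is.na(meta_full$ikdc_grade) && !meta_full$ikdc_grade %in% 0:3) {
    stop_format("meta$ikdc_grade must be 0..3 or NA")
  }
  if (!is.na(meta_full$class_label) && !meta_full$class_label %in% 1:8) {
    stop_format("meta$class_label must be 1..8 or NA")
  }
  structure(list(test_id = test_id, sample_rate_hz = as.numeric(sample_rate_hz),
                 t = t, omega_x = as.numeric(omega_x),
                 omega_y = as.numeric(omega_y), omega_z = as.numeric(omega_z),
                 meta = meta_full),
            class = "gyro_recording")
}

#' @export
print.gyro_recording <- function(x, ...) {
  cat(sprintf("<gyro_recording> %s: %d samples @ %.4g Hz, %.3g s\n",
              x$test_id, length(x$t), x$sample_rate_hz,
              x$t[length(x$t)] - x$t[1]))
  cat(sprintf("  peak |omega_x| = %.3g deg/s; grade %s, class %s\n",
              max(abs(x$omega_x)),
              format(x$meta$ikdc_grade), format(x$meta$class_label)))
  invisible(x)
}

#' The four clinical contexts a test may be recorded in
#' @return Character vector of valid `context` values.
#' @export
manifest_contexts <- function() c("office", "preop", "postop", "followup")

#' Read a gyroscope recording from CSV
#'
#' The on-disk interchange format is a plain CSV with a mandatory header and
#' columns `t`, `omega_x`, `omega_y`, `omega_z` (names configurable via
#' `cols`): time in seconds, angular velocities in deg/s. Clinical metadata
#' travels in the dataset manifest, not in the signal file.
#'
#' @param path Path to the CSV file.
#' @param test_id Test identifier; defaults to the file name without
#'   extension.
#' @param cols Named character vector mapping the canonical column roles
#'   `t`, `omega_x`, `omega_y`, `omega_z` to the header names used in the
#'   file.
#' @param meta Metadata list passed on to [gyro_recording()].
#' @return A [gyro_recording()].
#' @export
read_recording <- function(path, test_id = NULL,
                           cols = c(t = "t", omega_x = "omega_x",
                                    omega_y = "omega_y", omega_z = "omega_z"),
                           meta = list()) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(unname(cols), names(df))
  if (length(missing)) {
    stop_format(sprintf("missing column(s) in %s: %s", path,
                        paste(missing, collapse = ", ")))
  }
  if (is.null(test_id)) test_id <- sub("\\.[^.]*$", "", basename(path))
  gyro_recording(test_id,
                 t = df[[cols[["t"]]]],
                 omega_x = df[[cols[["omega_x"]]]],
                 omega_y = df[[cols[["omega_y"]]]],
                 omega_z = df[[cols[["omega_z"]]]],
                 meta = meta)
}

#' Write a gyroscope recording to CSV
#'
#' Values are printed with 17 significant digits so that
#' [read_recording()] inverts the write bit-exactly.
#'
#' @param rec A [gyro_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gyro_recording"))
  df <- data.frame(t = sprintf("%.17g", rec$t),
                   omega_x = sprintf("%.17g", rec$omega_x),
                   omega_y = sprintf("%.17g", rec$omega_y),
                   omega_z = sprintf("%.17g", rec$omega_z))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io(sprintf("cannot write recording to %s", path))
  invisible(path)
}

manifest_columns <- function() {
  c("test_id", "path", "side", "context", "ikdc_grade", "class_label",
    "include_flag")
}

#' Read a dataset manifest
#'
#' The manifest is one CSV row per test: `test_id`, `path` (signal CSV,
#' relative to the manifest's directory unless absolute), `side` (L/R),
#' `context` (office/preop/postop/followup), `ikdc_grade` (0--3, blank if
#' unknown), `class_label` (1--8, blank if unknown), `include_flag`
#' (TRUE/FALSE).
#'
#' @param path Path to the manifest CSV.
#' @return A `data.frame` with validated columns, one row per test.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(test_id = "character"))
  missing <- setdiff(manifest_columns(), names(df))
  if (length(missing)) {
    stop_format(sprintf("manifest missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  validate_manifest(df)
  df
}

validate_manifest <- function(df) {
  if (anyDuplicated(df$test_id)) {
    stop_integrity("manifest test_id values must be unique")
  }
  bad_ctx <- setdiff(unique(df$context), manifest_contexts())
  if (length(bad_ctx)) {
    stop_format(sprintf("invalid context value(s): %s",
                        paste(bad_ctx, collapse = ", ")))
  }
  if (!all(df$side %in% c("L", "R"))) stop_format("side must be 'L' or 'R'")
  g <- df$ikdc_grade
  if (!all(is.na(g) | g %in% 0:3)) stop_format("ikdc_grade must be 0..3 or blank")
  k <- df$class_label
  if (!all(is.na(k) | k %in% 1:8)) stop_format("class_label must be 1..8 or blank")
  if (!is.logical(df$include_flag) || anyNA(df$include_flag)) {
    stop_format("include_flag must be TRUE/FALSE")
  }
  invisible(df)
}

#' Write a dataset manifest
#' @param manifest Data frame with the columns of [read_manifest()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest[, manifest_columns()], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
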
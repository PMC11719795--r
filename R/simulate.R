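#' Maneuver-class waveform registry
#'
#' Each of the eight execution classes is a fixed morphology of the X-axis
#' angular-velocity trace: a flexion lobe (Gaussian, center `t1`, width
#' `sigma1`) and a grade-scaled reduction ("shift") bump (Gaussian, center
#' `t2`, width `sigma2`, negative sign). Classes 2--7 are standard
#' executions whose bump falls in the final third of the recording; their
#' lobe timing and width differ enough that segment-3 morphology separates
#' them at every grade, including grade 0 where the bump is absent. Class 1
#' is a truncated recording (maneuver aborted before the shift) and class 8
#' a misplaced device (bump in the first third, amplitude gain 0.04), the two
#' non-standard morphologies that are excluded from injury grading.
#'
#' @return Data frame with columns `class`, `t1`, `sigma1`, `t2`, `sigma2`,
#'   `amp_gain`, `truncate_frac`. Times are fractions of `duration_s` times
#'   the default 3 s; widths in seconds.
#' @export
class_registry <- function() {
  data.frame(
    class = 1:8,
    t1     = c(0.80, 0.80, 1.10, 1.20, 1.30, 1.40, 1.50, 0.80),
    sigma1 = c(0.20, 0.20, 0.42, 0.45, 0.48, 0.55, 0.66, 0.20),
    t2     = c(2.15, 2.15, 2.30, 2.45, 2.60, 2.75, 2.90, 0.50),
    sigma2 = c(0.06, 0.06, 0.09, 0.12, 0.15, 0.18, 0.21, 0.12),
    amp_gain      = c(1, 1, 1, 1, 1, 1, 1, 0.04),
    truncate_frac = c(0.30, 1, 1, 1, 1, 1, 1, 1)
  )
}

#' Simulation configuration
#'
#' Defaults describe a 3-s pivot-shift maneuver sampled at 100 Hz with a
#' 60 deg/s flexion lobe; the reduction bump scales with injury grade as
#' `grade * grade_step` (so grades 0--3 give bump amplitudes 0, 30, 60,
#' 90 deg/s). Gaussian measurement noise (sd 3 deg/s) is added i.i.d. per
#' sample; the Y and Z channels are leak-gain copies of the deterministic X
#' waveform plus independent noise.
#'
#' @param duration_s Recording length in seconds.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param flexion_amplitude Flexion-lobe amplitude `A_f` (deg/s).
#' @param grade_step Per-grade bump amplitude increment (deg/s).
#' @param noise_sd Measurement noise standard deviation (deg/s).
#' @param leak_gain_y,leak_gain_z Cross-axis leak gains for Y and Z.
#' @param registry Class morphology registry, see [class_registry()].
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(duration_s = 3, sample_rate_hz = 100,
                              flexion_amplitude = 60, grade_step = 30,
                              noise_sd = 3, leak_gain_y = 0.3,
                              leak_gain_z = 0.2, registry = class_registry()) {
  if (duration_s <= 0 || sample_rate_hz <= 0) {
    stop_usage("duration_s and sample_rate_hz must be positive")
  }
  if (noise_sd < 0) stop_usage("noise_sd must be non-negative")
  if (!all(1:8 %in% registry$class)) stop_usage("registry must cover classes 1..8")
  if (any(registry$sigma1 <= 0) || any(registry$sigma2 <= 0) ||
      any(registry$truncate_frac <= 0)) {
    stop_usage("registry widths and truncation fractions must be positive")
  }
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 flexion_amplitude = flexion_amplitude,
                 grade_step = grade_step, noise_sd = noise_sd,
                 leak_gain_y = leak_gain_y, leak_gain_z = leak_gain_z,
                 registry = registry),
            class = "simulation_config")
}

#' Simulate one pivot-shift gyroscope recording
#'
#' The deterministic X-axis waveform is
#' `amp_gain * (A_f * exp(-(t - t1)^2 / (2 sigma1^2))
#'   - grade * grade_step * exp(-(t - t2)^2 / (2 sigma2^2)))`,
#' to which i.i.d. Gaussian noise is added; class 1 keeps only the first
#' `truncate_frac` of the duration. Deterministic given `seed`.
#'
#' @param grade Injury grade 0--3.
#' @param klass Maneuver class 1--8.
#' @param cfg A [simulation_config()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param test_id Identifier for the recording.
#' @param meta Extra metadata merged over the simulated defaults.
#' @return A [gyro_recording()] with `ikdc_grade` and `class_label` set.
#' @export
simulate_recording <- function(grade, klass, cfg = simulation_config(),
                               seed = NULL, test_id = NULL, meta = list()) {
  if (!grade %in% 0:3) stop_usage("grade must be 0..3")
  if (!klass %in% 1:8) stop_usage("klass must be 1..8")
  stopifnot(inherits(cfg, "simulation_config"))
  r <- cfg$registry[cfg$registry$class == klass, ]
  n <- floor(cfg$duration_s * cfg$sample_rate_hz * r$truncate_frac)
  t <- (seq_len(n) - 1) / cfg$sample_rate_hz
  det <- r$amp_gain * (
    cfg$flexion_amplitude * exp(-(t - r$t1)^2 / (2 * r$sigma1^2)) -
      grade * cfg$grade_step * exp(-(t - r$t2)^2 / (2 * r$sigma2^2)))
  if (is.null(test_id)) test_id <- sprintf("sim_g%d_c%d", grade, klass)
  with_seed(seed, {
    omega_x <- det + stats::rnorm(n, 0, cfg$noise_sd)
    omega_y <- cfg$leak_gain_y * det + stats::rnorm(n, 0, cfg$noise_sd)
    omega_z <- cfg$leak_gain_z * det + stats::rnorm(n, 0, cfg$noise_sd)
    gyro_recording(test_id, t, omega_x, omega_y, omega_z,
                   sample_rate_hz = cfg$sample_rate_hz,
                   meta = utils::modifyList(
                     list(side = "R", context = if (grade == 0) "postop" else "preop",
                          evaluator_id = "sim", ikdc_grade = as.integer(grade),
                          class_label = as.integer(klass)),
                     meta))
  })
}

#' Default cohort composition
#'
#' Class probabilities follow the standardized-test class distribution of
#' the multicenter cohort (counts 11, 28, 81, 79, 90, 83, 21, 6 over classes
#' 1--8). Grade probabilities combine a 0.19 share of uninjured (grade 0)
#' knees - the postoperative + follow-up fraction of the cohort - with the
#' reported 60/33/7 percent split of injured knees over grades 1--3.
#'
#' @return List with `class_probs` (length 8) and `grade_probs` (length 4).
#' @export
default_cohort_probs <- function() {
  gp <- c(0.19, 0.81 * c(0.60, 0.33, 0.07))
  list(class_probs = c(11, 28, 81, 79, 90, 83, 21, 6) / 399,
       grade_probs = gp / sum(gp))
}

#' Simulate a labeled cohort of pivot-shift tests
#'
#' Class and grade labels are drawn independently from the supplied
#' probability vectors; recordings are generated with
#' [simulate_recording()]. Context is assigned conditional on grade
#' (grade 0 -> postop/followup at 63:20; injured -> office/preop at
#' 136:180), and side L/R with the cohort's 204:233 split.
#'
#' @param n Number of tests, >= 1.
#' @param class_probs Probability vector over classes 1--8 (sums to 1).
#' @param grade_probs Probability vector over grades 0--3 (sums to 1).
#' @param cfg A [simulation_config()].
#' @param seed Integer seed governing labels, metadata and signals.
#' @return List of class `labeled_dataset`: `recordings` (list of
#'   [gyro_recording()]) and `manifest` (data frame; `path` is `NA` until
#'   written by [write_dataset()]).
#' @export
simulate_cohort <- function(n, class_probs = default_cohort_probs()$class_probs,
                            grade_probs = default_cohort_probs()$grade_probs,
                            cfg = simulation_config(), seed = 1) {
  if (n < 1) stop_usage("n must be >= 1")
  if (length(class_probs) != 8L || abs(sum(class_probs) - 1) > 1e-9 ||
      any(class_probs < 0)) {
    stop_usage("class_probs must be 8 non-negative values summing to 1")
  }
  if (length(grade_probs) != 4L || abs(sum(grade_probs) - 1) > 1e-9 ||
      any(grade_probs < 0)) {
    stop_usage("grade_probs must be 4 non-negative values summing to 1")
  }
  with_seed(seed, {
    klass <- sample(1:8, n, replace = TRUE, prob = class_probs)
    grade <- sample(0:3, n, replace = TRUE, prob = grade_probs)
    side <- sample(c("L", "R"), n, replace = TRUE, prob = c(204, 233))
    context <- ifelse(grade == 0,
                      sample(c("postop", "followup"), n, TRUE, c(63, 20)),
                      sample(c("office", "preop"), n, TRUE, c(136, 180)))
    rec_seeds <- sample.int(.Machine$integer.max - 1L, n)
    recordings <- vector("list", n)
    ids <- sprintf("test_%04d", seq_len(n))
    for (i in seq_len(n)) {
      recordings[[i]] <- simulate_recording(
        grade[i], klass[i], cfg, seed = rec_seeds[i], test_id = ids[i],
        meta = list(side = side[i], context = context[i]))
    }
    manifest <- data.frame(test_id = ids,
                           path = paste0(ids, ".csv"),
                           side = side, context = context,
                           ikdc_grade = as.integer(grade),
                           class_label = as.integer(klass),
                           include_flag = TRUE)
    structure(list(recordings = recordings, manifest = manifest),
              class = "labeled_dataset")
  })
}

#' Write a simulated dataset to disk
#'
#' Writes one signal CSV per recording, the manifest CSV, and a JSON sidecar
#' of the true simulation parameters.
#'
#' @param dataset A `labeled_dataset` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param cfg The [simulation_config()] used, stored in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, cfg = simulation_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in dataset$recordings) {
    write_recording(rec, file.path(dir, paste0(rec$test_id, ".csv")))
  }
  write_manifest(dataset$manifest, file.path(dir, "manifest.csv"))
  sidecar <- cfg
  sidecar$registry <- NULL
  jsonlite::write_json(
    list(config = unclass(sidecar), registry = cfg$registry,
         n = length(dataset$recordings)),
    file.path(dir, "simulation_params.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
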
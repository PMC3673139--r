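# Synthetic-session simulator.
#
# Emulates the capture design the classifier is meant for: nine-second
# tri-axial logs at a smartphone's native rate, the annotated activity centred
# at 4.5 s, 30 logs per activity and sport. The signal model is deliberately
# simple -- a sum of sinusoids at the stride frequency and its first
# harmonics for locomotion, Gaussian-enveloped damped oscillation bursts for
# ball-interaction events, a constant 1 g gravity component rotated by a
# per-subject orientation perturbation, white Gaussian sensor noise, and
# 8-bit quantization over the device range. It reproduces the qualitative
# structure real sessions show (energy ordering stationary < walk < jog <
# sprint; game activities separable or confusable depending on how distinct
# their burst signatures are) without claiming biomechanical realism.

.device_profiles <- list(
  nexus_one = list(name = "nexus_one", sampling_rate = 16, resolution_bits = 8L,
                   range_g = 4, noise_sd = 0.03),
  htc_desire = list(name = "htc_desire", sampling_rate = 25, resolution_bits = 8L,
                    range_g = 4, noise_sd = 0.03)
)

#' Device capture profile
#'
#' The two built-in profiles mirror the handsets the original dataset was
#' captured with: `"nexus_one"` samples at 16 Hz, `"htc_desire"` at 25 Hz,
#' both tri-axial at 8-bit resolution. `range_g` is the full scale in g and
#' `noise_sd` the sensor noise standard deviation in g (about one least
#' significant bit).
#'
#' @param name profile name, or any string when overriding fields for a
#'   custom device.
#' @param sampling_rate,resolution_bits,range_g,noise_sd optional overrides.
#' @return a `device_profile` list.
#' @export
device_profile <- function(name = c("nexus_one", "htc_desire"),
                           sampling_rate = NULL, resolution_bits = NULL,
                           range_g = NULL, noise_sd = NULL) {
  base <- if (is.character(name) && length(name) == 1L &&
              name %in% names(.device_profiles)) {
    .device_profiles[[name]]
  } else {
    list(name = as.character(name)[1L], sampling_rate = 25,
         resolution_bits = 8L, range_g = 4, noise_sd = 0.03)
  }
  for (field in c("sampling_rate", "resolution_bits", "range_g", "noise_sd")) {
    val <- get(field)
    if (!is.null(val)) base[[field]] <- val
  }
  if (base$sampling_rate <= 0 || base$resolution_bits < 1L) {
    stop("invalid device profile", call. = FALSE)
  }
  structure(base, class = "device_profile")
}

# Locomotion models. Speed bands (m/s): A1 0, A2 1 +/- 1, A3 3.5 +/- 1.5,
# A4 5+. stride_hz is the dominant step frequency, amp_g the overall gait
# amplitude, harmonics the relative weights of stride_hz, 2x, 3x, and
# axis_w the (x forward, y lateral, z vertical) weighting.
.locomotion_models <- list(
  A1 = list(stride_hz = 0.25, amp_g = 0.02, harmonics = 1,
            axis_w = c(x = 0.5, y = 0.5, z = 1)),
  A2 = list(stride_hz = 1.8, amp_g = 0.25, harmonics = c(1, 0.35, 0.12),
            axis_w = c(x = 0.6, y = 0.35, z = 1)),
  A3 = list(stride_hz = 2.6, amp_g = 0.70, harmonics = c(1, 0.50, 0.22),
            axis_w = c(x = 0.7, y = 0.40, z = 1)),
  A4 = list(stride_hz = 3.3, amp_g = 1.40, harmonics = c(1, 0.65, 0.35),
            axis_w = c(x = 0.8, y = 0.45, z = 1))
)

# Game activities ride on walking-level locomotion plus bursts.
.game_base <- list(stride_hz = 1.6, amp_g = 0.18,
                   harmonics = c(1, 0.3), axis_w = c(x = 0.6, y = 0.4, z = 1))

# Burst signatures: offsets_s are burst centres relative to the activity
# centre, freq_hz the oscillation frequency, sd_s the Gaussian envelope
# width, peak_g the envelope peak. Under the high-separability preset the
# three game activities occupy distinct frequency/duration niches; under the
# low-separability preset their signatures are pulled together so that only
# the inertial activities remain easy.
.burst_models <- list(
  high = list(
    A5 = list(offsets_s = 0, freq_hz = 7.2, sd_s = 0.12, peak_g = 1.6),
    A6 = list(offsets_s = 0, freq_hz = 1.2, sd_s = 0.45, peak_g = 1.5),
    A7 = list(offsets_s = c(-1.5, -0.5, 0.5, 1.5), freq_hz = 3.5,
              sd_s = 0.12, peak_g = 1.0)),
  low = list(
    A5 = list(offsets_s = 0, freq_hz = 5.0, sd_s = 0.20, peak_g = 1.10),
    A6 = list(offsets_s = 0, freq_hz = 4.6, sd_s = 0.22, peak_g = 1.00),
    A7 = list(offsets_s = 0, freq_hz = 4.8, sd_s = 0.21, peak_g = 1.05))
)

#' Sport preset for the simulator
#'
#' The sports share the locomotion models and differ in where the game
#' activities load: soccer ball interactions are lower-body movements
#' (forward/vertical axes), hockey ones are upper-arm movements (lateral
#' axis). `separability` selects how distinct the three game-activity burst
#' signatures are: `"high"` gives each a clear frequency/duration niche,
#' `"low"` pulls them together so A5--A7 become mutually confusable while
#' A1--A4 stay easy.
#'
#' @param sport `"soccer"` or `"hockey"`.
#' @param separability `"high"` or `"low"`.
#' @return a `sport_preset` list (versioned via `version`).
#' @export
sport_preset <- function(sport = c("soccer", "hockey"),
                         separability = c("high", "low")) {
  sport <- match.arg(sport)
  separability <- match.arg(separability)
  burst_axis_w <- if (sport == "soccer") {
    c(x = 0.8, y = 0.3, z = 1.0)
  } else {
    c(x = 0.4, y = 1.0, z = 0.5)
  }
  structure(list(sport = sport, separability = separability,
                 burst_axis_w = burst_axis_w,
                 bursts = .burst_models[[separability]],
                 version = "1"),
            class = "sport_preset")
}

#' Draw a subject profile
#'
#' Captures inter-subject variability: an overall amplitude scale (weight,
#' strength), a stride-frequency jitter, and a small random orientation
#' perturbation of the phone on the upper back.
#'
#' @param seed integer seed.
#' @return a `subject_profile` with `amp_scale`, `freq_jitter` and a 3x3
#'   orientation rotation matrix.
#' @export
subject_profile <- function(seed = 1L) {
  set.seed(seed)
  angles <- stats::rnorm(3L, 0, 3 * pi / 180)
  rx <- matrix(c(1, 0, 0,
                 0, cos(angles[1L]), -sin(angles[1L]),
                 0, sin(angles[1L]), cos(angles[1L])), 3L, byrow = TRUE)
  ry <- matrix(c(cos(angles[2L]), 0, sin(angles[2L]),
                 0, 1, 0,
                 -sin(angles[2L]), 0, cos(angles[2L])), 3L, byrow = TRUE)
  rz <- matrix(c(cos(angles[3L]), -sin(angles[3L]), 0,
                 sin(angles[3L]), cos(angles[3L]), 0,
                 0, 0, 1), 3L, byrow = TRUE)
  structure(list(amp_scale = exp(stats::rnorm(1L, 0, 0.15)),
                 freq_jitter = stats::runif(1L, 0.9, 1.1),
                 rotation = rz %*% ry %*% rx),
            class = "subject_profile")
}

.quantize <- function(v, device) {
  step <- 2 * device$range_g / 2^device$resolution_bits
  pmin(pmax(round(v / step) * step, -device$range_g), device$range_g)
}

#' Simulate one nine-second activity log
#'
#' @param label activity, `"A1"`..`"A7"`.
#' @param device a [device_profile()] (or profile name).
#' @param subject a [subject_profile()]; drawn from `seed` when `NULL`.
#' @param preset a [sport_preset()]; only the game activities A5--A7 read it,
#'   so logs for A1--A4 are identical across sports at equal seeds.
#' @param seed integer seed; equal seeds give identical logs.
#' @return an `activity_log` centred at 4.5 s.
#' @export
simulate_log <- function(label, device = device_profile("htc_desire"),
                         subject = NULL, preset = sport_preset("soccer"),
                         seed = 1L) {
  label <- as.character(label)
  if (!label %in% .activity_labels) {
    stop("`label` must be one of A1..A7", call. = FALSE)
  }
  if (is.character(device)) device <- device_profile(device)
  if (is.null(subject)) subject <- subject_profile(seed + 7919L)
  set.seed(seed)
  rate <- device$sampling_rate
  n <- as.integer(9 * rate)
  t <- (0:(n - 1L)) / rate
  is_game <- label %in% c("A5", "A6", "A7")
  loco <- if (is_game) .game_base else .locomotion_models[[label]]

  # Fixed-size draws first so the consumed stream does not depend on the
  # preset: phases for up to 3 harmonics x 3 axes, the noise matrix, then
  # the context-event candidates.
  phases <- matrix(stats::runif(9L, 0, 2 * pi), nrow = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  noise <- matrix(stats::rnorm(3L * n, 0, device$noise_sd), ncol = 3L)
  ctx <- matrix(stats::runif(12L), nrow = 2L)

  f0 <- loco$stride_hz * subject$freq_jitter
  amp <- loco$amp_g * subject$amp_scale
  sig <- vapply(c("x", "y", "z"), function(ax) {
    s <- numeric(n)
    for (h in seq_along(loco$harmonics)) {
      s <- s + loco$harmonics[h] * sin(2 * pi * f0 * h * t + phases[h, ax])
    }
    amp * loco$axis_w[[ax]] * s
  }, numeric(n))

  # Context events: logs are cut from continuous play, so movement by the
  # same player shortly before or after the annotated activity shows up
  # away from the centre (here at least 3 s out). Windows of up to about
  # 5 s therefore see only the annotated activity, while longer windows
  # mix in neighbouring events -- which is what makes them harder.
  for (ci in 1:2) {
    if (ctx[ci, 1L] < 0.35) {
      side <- if (ctx[ci, 2L] < 0.5) -1 else 1
      centre <- 4.5 + side * (3.0 + 1.2 * ctx[ci, 3L])
      freq <- 2 + 4 * ctx[ci, 4L]
      peak <- (0.4 + 0.5 * ctx[ci, 6L]) * subject$amp_scale
      env <- peak * exp(-(t - centre)^2 / (2 * 0.15^2))
      osc <- env * sin(2 * pi * freq * (t - centre) + 2 * pi * ctx[ci, 5L])
      sig <- sig + outer(osc, c(x = 0.7, y = 0.7, z = 1))
    }
  }

  if (is_game) {
    b <- preset$bursts[[label]]
    for (off in b$offsets_s) {
      centre <- 4.5 + off
      phase <- stats::runif(1L, 0, 2 * pi)
      env <- b$peak_g * subject$amp_scale *
        exp(-(t - centre)^2 / (2 * b$sd_s^2))
      osc <- env * sin(2 * pi * b$freq_hz * (t - centre) + phase)
      sig <- sig + outer(osc, preset$burst_axis_w)
    }
  }

  # Rotate body-frame signal + gravity into the (perturbed) sensor frame,
  # add sensor noise and quantize to the 8-bit device grid.
  gravity <- c(0, 0, 1)
  sensed <- t(subject$rotation %*% (t(sig) + gravity)) + noise
  sensed <- .quantize(sensed, device)

  rec <- accel_recording(t, sensed[, 1L], sensed[, 2L], sensed[, 3L],
                         sampling_rate = rate, device_id = device$name)
  activity_log(rec, label, activity_center = 4.5)
}

#' Simulate a labelled per-sport dataset
#'
#' Generates `n_per_activity` logs for each of the seven activities (the
#' standard design is 30, i.e. 210 logs), drawing each log's subject from a
#' seeded pool and alternating the device profiles in `devices`.
#'
#' @param sport,separability forwarded to [sport_preset()]; alternatively
#'   pass a ready `preset`.
#' @param n_per_activity logs per activity, at least 2.
#' @param devices device profile names cycled over the logs of each activity.
#' @param n_subjects size of the subject pool.
#' @param seed master seed; subjects, per-log seeds and device assignment all
#'   derive from it, so equal seeds give identical datasets and two sports at
#'   the same seed differ only in their game-activity signatures.
#' @param preset optional explicit [sport_preset()].
#' @return list of `activity_log` objects (length `7 * n_per_activity`) with
#'   attribute `preset`.
#' @export
simulate_dataset <- function(sport = "soccer", separability = "high",
                             n_per_activity = 30L,
                             devices = c("nexus_one", "htc_desire"),
                             n_subjects = 12L, seed = 1L, preset = NULL) {
  if (is.null(preset)) {
    preset <- sport_preset(sport, separability)
  }
  stopifnot(inherits(preset, "sport_preset"))
  if (n_per_activity < 2L) {
    stop("`n_per_activity` must be at least 2", call. = FALSE)
  }
  set.seed(seed)
  subject_seeds <- sample.int(2^31 - 1L, n_subjects)
  subjects <- lapply(subject_seeds, subject_profile)
  total <- 7L * n_per_activity
  log_seeds <- sample.int(2^31 - 1L, total)
  subject_idx <- sample.int(n_subjects, total, replace = TRUE)
  device_idx <- rep_len(seq_along(devices), total)
  labels <- rep(.activity_labels, each = n_per_activity)
  logs <- lapply(seq_len(total), function(i) {
    simulate_log(labels[i],
                 device = device_profile(devices[device_idx[i]]),
                 subject = subjects[[subject_idx[i]]],
                 preset = preset, seed = log_seeds[i])
  })
  attr(logs, "preset") <- preset
  logs
}
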
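#' Canonical activity classes
#'
#' The ten activity classes recognized by the workflow, in the fixed order
#' used for confusion matrices and reports: two stair activities, walking,
#' running, sitting, four directed falls, and lying. The extra
#' `"transition"` label marks stretches between activities; it is present in
#' raw recordings but removed during segmentation and never classified.
#'
#' @return character vector of the 10 class labels, named by protocol code
#'   (`A1`--`A10`).
#' @export
#' @examples
#' activity_classes()
activity_classes <- function() {
  c(A1 = "stairs_up", A2 = "stairs_down", A3 = "walk", A4 = "run",
    A5 = "sit", A6 = "fall_right", A7 = "fall_left", A8 = "fall_front",
    A9 = "fall_back", A10 = "lying")
}

#' Label used for inter-activity stretches
#' @return the string `"transition"`.
#' @export
transition_label <- function() "transition"

normalize3 <- function(v) v / sqrt(sum(v^2))

#' Construct an activity signal model
#'
#' Describes one activity class as a simple band-limited signal: a static
#' gravity orientation plus, for dynamic activities, a fundamental sinusoid
#' and one harmonic per axis, with additive white noise. Falls are modelled
#' as a brief half-sine transient on a direction-coding axis followed by a
#' lying orientation.
#'
#' @param label activity class label.
#' @param base_freq dominant oscillation frequency in Hz (0 for static
#'   activities).
#' @param amplitude length-3 per-axis oscillation amplitude in g.
#' @param gravity_dir length-3 orientation of the static gravity component;
#'   normalized to unit Euclidean length.
#' @param duration nominal activity duration in seconds.
#' @param noise_sd additive white-noise standard deviation in g.
#' @param drift slow vertical drift amplitude in g (stair activities).
#' @param fall_sign length-2 sign pattern on (x, y) coding fall direction,
#'   or `NULL` for non-fall activities.
#' @param fall_peak peak transient amplitude in g (falls only).
#' @return an object of class `activity_model`.
#' @export
activity_model <- function(label, base_freq = 0, amplitude = c(0, 0, 0),
                           gravity_dir = c(0, 0, 1), duration = 10,
                           noise_sd = 0.03, drift = 0, fall_sign = NULL,
                           fall_peak = 0) {
  if (base_freq < 0) stop("base_freq must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  if (length(amplitude) != 3) stop("amplitude must have length 3")
  if (!is.null(fall_sign) && duration > 2) {
    stop("fall activities must have duration <= 2 s")
  }
  structure(
    list(label = label, base_freq = base_freq, amplitude = amplitude,
         gravity_dir = normalize3(gravity_dir), duration = duration,
         noise_sd = noise_sd, drift = drift, fall_sign = fall_sign,
         fall_peak = fall_peak),
    class = "activity_model")
}

#' Default activity models
#'
#' The default signal models for the ten protocol activities plus the
#' transitional stretches. Dynamic activities (stairs, walk, run) are
#' periodic with distinct fundamental frequencies; stairs differ from
#' walking by their amplitude ratios and a slow vertical drift term (up vs.
#' down in sign); running has a higher frequency and amplitude. Static
#' activities (sit, lying) are gravity-oriented constants. Falls are 2-s
#' events: a 1-s half-sine spike whose sign pattern on the (x, y) axes
#' encodes the direction (right/left/front/back), followed by a lying
#' orientation. Durations encode the protocol's class imbalance: walking
#' dominates (protocol walk plus ambulation between activity stations) and
#' falls are rare because the events are short.
#'
#' @return named list of [activity_model()] objects keyed by class label,
#'   including a `"transition"` model.
#' @export
#' @examples
#' names(default_activity_models())
default_activity_models <- function() {
  models <- list(
    activity_model("stairs_up", base_freq = 1.5,
                   amplitude = c(0.25, 0.08, 0.40), duration = 15,
                   noise_sd = 0.03, drift = 0.15),
    activity_model("stairs_down", base_freq = 1.0,
                   amplitude = c(0.08, 0.25, 0.35), duration = 15,
                   noise_sd = 0.03, drift = -0.15),
    activity_model("walk", base_freq = 2.5,
                   amplitude = c(0.10, 0.15, 0.30), duration = 40,
                   noise_sd = 0.03),
    activity_model("run", base_freq = 3.5,
                   amplitude = c(0.25, 0.35, 0.90), duration = 30,
                   noise_sd = 0.05),
    activity_model("sit", gravity_dir = c(0.20, 0.10, 0.97), duration = 30,
                   noise_sd = 0.02),
    activity_model("fall_right", duration = 2, noise_sd = 0.05,
                   fall_sign = c(1, 0), fall_peak = 2.0,
                   gravity_dir = c(0.97, 0.05, 0.20)),
    activity_model("fall_left", duration = 2, noise_sd = 0.05,
                   fall_sign = c(-1, 0), fall_peak = 2.0,
                   gravity_dir = c(-0.97, 0.05, 0.20)),
    activity_model("fall_front", duration = 2, noise_sd = 0.05,
                   fall_sign = c(0, 1), fall_peak = 2.0,
                   gravity_dir = c(0.05, 0.97, 0.20)),
    activity_model("fall_back", duration = 2, noise_sd = 0.05,
                   fall_sign = c(0, -1), fall_peak = 2.0,
                   gravity_dir = c(0.05, -0.97, 0.20)),
    activity_model("lying", gravity_dir = c(0.05, 0.97, -0.20),
                   duration = 10, noise_sd = 0.02),
    activity_model("transition", base_freq = 0.8,
                   amplitude = c(0.05, 0.05, 0.08), duration = 2,
                   noise_sd = 0.05)
  )
  names(models) <- vapply(models, `[[`, character(1), "label")
  models
}

#' Draw a subject profile
#'
#' Inter-subject variability is modelled by a per-axis multiplicative gain,
#' a multiplicative jitter on every activity's fundamental frequency, and a
#' small fixed rotation of the device frame (placement/orientation
#' differences). All draws come from `seed`, so an identical
#' (subject_id, seed) pair always yields the identical profile.
#'
#' @param subject_id integer subject identifier (>= 1).
#' @param seed integer seed for the profile draw.
#' @param gain_sd standard deviation of log-gain per axis.
#' @param freq_jitter_sd standard deviation of the frequency jitter around 1.
#' @param orientation_sd standard deviation of the rotation angles (radians).
#' @return an object of class `subject_profile` with fields `subject_id`,
#'   `gain`, `freq_jitter`, `orientation` (3x3 rotation matrix) and `seed`.
#' @export
#' @examples
#' subject_profile(1, seed = 42)
subject_profile <- function(subject_id, seed, gain_sd = 0.05,
                            freq_jitter_sd = 0.04, orientation_sd = 0.06) {
  stopifnot_scalar_count(subject_id, "subject_id")
  with_seed(seed, {
    gain <- exp(rnorm(3, 0, gain_sd))
    freq_jitter <- exp(rnorm(1, 0, freq_jitter_sd))
    angles <- rnorm(3, 0, orientation_sd)
    structure(
      list(subject_id = as.integer(subject_id), gain = gain,
           freq_jitter = freq_jitter,
           orientation = rotation_matrix(angles[1], angles[2], angles[3]),
           seed = as.integer(seed)),
      class = "subject_profile")
  })
}
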
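# Physical stimulus mappings: disparity offset, angular size, audio pitch.
#
# The analysis pipeline works in normalized depth units (reference = 0,
# full range +/- 1); these mappings connect normalized depths to the
# physical cue values a display would render, and are used for round-trip
# checks and for documenting the stimulus geometry.

#' Horizontal image offset producing a binocular disparity for a target depth
#'
#' For a screen at distance `D0` and a target at distance `D`, the half-image
#' horizontal displacement is `ioD * (D - D0) / (2 * D)`, where `ioD` is the
#' observer's interocular distance. The offset is zero at the screen plane and
#' carries the sign of `D - D0`.
#'
#' @param D Target distance in cm (positive).
#' @param params A [disparity_params()] object (or any list with `ioD`, `D0`).
#' @return Offset in cm (same sign as `D - D0`).
#' @examples
#' disparity_offset(276, disparity_params(ioD = 6))  # 1.5 cm
#' @export
disparity_offset <- function(D, params = disparity_params()) {
  if (any(!is.finite(D)) || any(D <= 0)) {
    stop("target distance `D` must be positive", call. = FALSE)
  }
  params$ioD * (D - params$D0) / (2 * D)
}

#' Disparity-geometry parameters
#'
#' @param ioD Interocular distance in cm.
#' @param D0 Screen distance in cm (study value 138).
#' @param noisy Whether the uncertainty-added disparity variant (dot-level
#'   jitter) is in force. Carried as a flag; the observer model represents the
#'   added uncertainty as an inflated sensory noise.
#' @export
disparity_params <- function(ioD = 6.3, D0 = 138, noisy = FALSE) {
  stopifnot_scalar_pos(ioD, "ioD")
  stopifnot_scalar_pos(D0, "D0")
  structure(list(ioD = ioD, D0 = D0, noisy = isTRUE(noisy)),
            class = "disparity_params")
}

#' Angular size of a square/dot of physical width S0 at distance D
#'
#' `stimSize = 2 * atan(S0 / (2 * D))`, in radians. Strictly decreasing in
#' distance, which is what makes retinal size a depth cue.
#'
#' @param D Target distance in cm (positive).
#' @param params A [size_params()] object.
#' @return Angular size in radians.
#' @export
angular_size <- function(D, params = size_params()) {
  if (any(!is.finite(D)) || any(D <= 0)) {
    stop("target distance `D` must be positive", call. = FALSE)
  }
  2 * atan(params$S0 / (2 * D))
}

#' Size-cue parameters
#'
#' @param S0 Width of the square (and dot diameter) at screen level, in cm.
#'   The default subtends 6 degrees at a 138 cm screen.
#' @export
size_params <- function(S0 = 2 * 138 * tan(3 * pi / 180)) {
  stopifnot_scalar_pos(S0, "S0")
  structure(list(S0 = S0), class = "size_params")
}

#' Physical width that subtends a given visual angle at a given distance
#'
#' Inverse of [angular_size()]; convenient for constructing stimuli that are,
#' e.g., 6 degrees wide at screen level.
#'
#' @param angle_deg Desired angular size in degrees.
#' @param D Distance in cm.
#' @export
size_for_angle <- function(angle_deg, D = 138) {
  2 * D * tan(angle_deg * pi / 360)
}

#' Audio pitch for a signed depth from the screen plane
#'
#' Depth maps to pitch exponentially: `f = base_freq *
#' 2^(direction * cents_per_cm * delta_cm / 1200)`. At screen depth the tone
#' is `base_freq`; each cm changes the pitch by `cents_per_cm` cents, and the
#' mapping direction is counterbalanced across observers.
#'
#' @param delta_cm Signed depth from the screen plane in cm.
#' @param map An [audio_mapping()] object.
#' @return Frequency in Hz.
#' @export
pitch_for_depth <- function(delta_cm, map = audio_mapping()) {
  map$base_freq * 2^(map$direction * map$cents_per_cm * delta_cm / 1200)
}

#' Audio depth-to-pitch mapping parameters
#'
#' @param base_freq Frequency at screen depth, Hz (study value 600).
#' @param cents_per_cm Pitch change per cm of depth, in cents (study value 1.5).
#' @param direction `+1` or `-1`; which way pitch moves with depth.
#' @export
audio_mapping <- function(base_freq = 600, cents_per_cm = 1.5, direction = 1) {
  stopifnot_scalar_pos(base_freq, "base_freq")
  if (!direction %in% c(-1, 1)) {
    stop("`direction` must be +1 or -1", call. = FALSE)
  }
  structure(list(base_freq = base_freq, cents_per_cm = cents_per_cm,
                 direction = direction),
            class = "audio_mapping")
}
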
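## Propulsive efficiency surrogates and the axon-regeneration metric.

#' Strouhal number
#'
#' St = 2 f A / U, where f is the tail-beat frequency (Hz), U the swimming
#' speed (BL/s) and A the maximum amplitude. Amplitudes in this package are
#' recorded peak to peak; by default A is taken as half the peak-to-peak
#' value, so St = f * amp_pp / U. The literal peak-to-peak reading
#' (St = 2 f amp_pp / U) is available via `amplitude = "pp"`: for healthy
#' anguilliform swimmers the half-peak-to-peak convention places St inside
#' the 0.25-0.35 band where flapping propulsion is most efficient, while
#' the peak-to-peak reading roughly doubles it out of that band, which is
#' why half-peak-to-peak is the default.
#'
#' St is dimensionless (Hz x BL / (BL/s)) and invariant under a common
#' rescaling of f and U.
#'
#' @param frequency_hz tail-beat frequency, > 0.
#' @param amp_pp_bl maximum peak-to-peak amplitude in BL, >= 0.
#' @param speed_bl_s swimming speed in BL/s, > 0.
#' @param amplitude "half_pp" (default) or "pp".
#' @return Strouhal number.
#' @export
strouhal <- function(frequency_hz, amp_pp_bl, speed_bl_s,
                     amplitude = c("half_pp", "pp")) {
  amplitude <- match.arg(amplitude)
  if (any(frequency_hz <= 0)) stop("frequency_hz must be > 0")
  if (any(speed_bl_s <= 0)) stop("speed_bl_s must be > 0")
  if (any(amp_pp_bl < 0)) stop("amp_pp_bl must be >= 0")
  A <- if (amplitude == "half_pp") amp_pp_bl / 2 else amp_pp_bl
  2 * frequency_hz * A / speed_bl_s
}

#' Stride length
#'
#' Distance traveled per body wave (per tail-beat cycle): U / f, in body
#' lengths per cycle.
#'
#' @param speed_bl_s swimming speed in BL/s.
#' @param frequency_hz tail-beat frequency in Hz, > 0.
#' @return stride length in BL per cycle.
#' @export
stride_length <- function(speed_bl_s, frequency_hz) {
  if (any(frequency_hz <= 0)) stop("frequency_hz must be > 0")
  speed_bl_s / frequency_hz
}

#' Classify a Strouhal number against the optimal propulsion band
#'
#' Flapping propulsion is most efficient for St in [0.25, 0.35]; both
#' endpoints are inclusive.
#'
#' @param st Strouhal number(s), > 0.
#' @param band optimal range (default c(0.25, 0.35)).
#' @return factor with levels "below", "optimal", "above".
#' @export
classify_strouhal <- function(st, band = c(0.25, 0.35)) {
  if (any(st <= 0)) stop("st must be > 0")
  out <- ifelse(st < band[1], "below",
                ifelse(st > band[2], "above", "optimal"))
  factor(out, levels = c("below", "optimal", "above"))
}

#' Percent axon regeneration
#'
#' 100 x (number of labeled axons counted distal to the transection site) /
#' (number counted proximal to it).
#'
#' @param n_distal,n_proximal non-negative integer axon counts (distal:
#'   1.0 mm beyond the lesion; proximal: 1.0-1.5 mm before it).
#' @return percent regeneration.
#' @export
percent_regeneration <- function(n_distal, n_proximal) {
  if (any(n_distal < 0) || any(n_proximal < 0) ||
      any(n_distal != round(n_distal)) || any(n_proximal != round(n_proximal)))
    stop("axon counts must be non-negative integers")
  if (any(n_proximal == 0))
    stop("percent regeneration undefined: proximal axon count is zero")
  100 * n_distal / n_proximal
}

#' Append performance indices to a kinematics table
#'
#' Adds strouhal, stride_length_bl and in_optimal_range columns computed
#' from the table's frequency_hz, amp_pp_bl and speed_bl_s columns.
#'
#' @param kin data.frame with columns frequency_hz, amp_pp_bl, speed_bl_s.
#' @param amplitude amplitude convention passed to [strouhal()].
#' @return the table with the three columns appended.
#' @export
performance_indices <- function(kin, amplitude = c("half_pp", "pp")) {
  amplitude <- match.arg(amplitude)
  stopifnot(all(c("frequency_hz", "amp_pp_bl", "speed_bl_s") %in% names(kin)))
  kin$strouhal <- strouhal(kin$frequency_hz, kin$amp_pp_bl, kin$speed_bl_s,
                           amplitude = amplitude)
  kin$stride_length_bl <- stride_length(kin$speed_bl_s, kin$frequency_hz)
  kin$in_optimal_range <- classify_strouhal(kin$strouhal) == "optimal"
  kin
}
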
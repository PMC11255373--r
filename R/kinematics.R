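## Eleven per-trajectory flight parameters computed from Kalman-smoothed
## states plus a manually counted wingbeat total. Velocities and
## accelerations come from the Kalman state, never finite differences; the
## first and last `burn_in` frames are excluded from all summaries (filter
## edge effects).

#' @keywords internal
included_frames <- function(states, burn_in = 5L) {
  n <- length(states$frame_index)
  idx <- seq_len(n)
  idx[idx > burn_in & idx <= n - burn_in]
}

speed_of <- function(states, idx) sqrt(rowSums(states$velocity[idx, , drop = FALSE]^2))

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Covered distance of a flight path
#'
#' Sum of Euclidean distances between consecutive smoothed positions over
#' the included (post burn-in) frames.
#'
#' @param states A `smoothed_states` object.
#' @param burn_in Frames dropped at each end (default 5).
#' @return Distance in metres.
#' @export
covered_distance <- function(states, burn_in = 5L) {
  idx <- included_frames(states, burn_in)
  if (length(idx) < 2L)
    stop("covered_distance: undefined for fewer than 2 included frames")
  p <- states$position[idx, , drop = FALSE]
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Mean flight velocity (speed)
#'
#' Mean per-frame speed |v| from the Kalman velocity state.
#'
#' @inheritParams covered_distance
#' @return m/s.
#' @export
mean_velocity <- function(states, burn_in = 5L) {
  idx <- included_frames(states, burn_in)
  mean(speed_of(states, idx))
}

#' Mean flight acceleration magnitude
#'
#' Mean per-frame |a| from the Kalman acceleration state.
#'
#' @inheritParams covered_distance
#' @return m/s^2.
#' @export
mean_acceleration <- function(states, burn_in = 5L) {
  idx <- included_frames(states, burn_in)
  mean(sqrt(rowSums(states$acceleration[idx, , drop = FALSE]^2)))
}

#' Mean flight height
#'
#' Mean z coordinate (metres above the ground plane) over included frames.
#'
#' @inheritParams covered_distance
#' @return m.
#' @export
flight_height <- function(states, burn_in = 5L) {
  idx <- included_frames(states, burn_in)
  mean(states$position[idx, 3])
}

#' Advance ratio
#'
#' Mean velocity divided by wingbeat frequency: the distance advanced per
#' wingbeat (m/wingbeat), a simplified flapping-efficiency measure. A
#' missing or zero frequency propagates a missing value (flagged for later
#' imputation in the statistical layer).
#'
#' @param mean_velocity m/s.
#' @param wingbeat_frequency Hz.
#' @return m per wingbeat, or `NA` when the frequency is missing/zero.
#' @export
advance_ratio <- function(mean_velocity, wingbeat_frequency) {
  if (is.na(wingbeat_frequency) || wingbeat_frequency <= 0) return(NA_real_)
  mean_velocity / wingbeat_frequency
}

## frames where speed exceeds eps, within the included range
moving_frames <- function(states, burn_in, eps = 1e-6) {
  idx <- included_frames(states, burn_in)
  idx[speed_of(states, idx) > eps]
}

#' Turning acceleration
#'
#' Mean magnitude of the acceleration component perpendicular to the
#' velocity, |v x a| / |v| — the centripetal part of acceleration strictly
#' attributable to changes in flight direction.
#'
#' @inheritParams covered_distance
#' @param eps Minimum speed (m/s) for a frame to be included.
#' @return m/s^2.
#' @export
turning_acceleration <- function(states, burn_in = 5L, eps = 1e-6) {
  idx <- moving_frames(states, burn_in, eps)
  if (length(idx) == 0L)
    stop("turning_acceleration: undefined - no frames with speed > ", eps)
  v <- states$velocity[idx, , drop = FALSE]
  a <- states$acceleration[idx, , drop = FALSE]
  mean(sqrt(rowSums(cross_rows(v, a)^2)) / sqrt(rowSums(v^2)))
}

#' Turning rate
#'
#' Mean angular change of direction between subsequent velocity vectors,
#' divided by the frame interval. The angle between consecutive velocities
#' is computed with the numerically stable two-argument arctangent of the
#' cross- and dot-product magnitudes.
#'
#' @inheritParams turning_acceleration
#' @param degrees Return degrees/s instead of rad/s.
#' @return rad/s (or degrees/s).
#' @export
turning_rate <- function(states, burn_in = 5L, eps = 1e-6, degrees = FALSE) {
  idx <- moving_frames(states, burn_in, eps)
  if (length(idx) < 2L)
    stop("turning_rate: undefined - need >= 2 moving frames")
  v1 <- states$velocity[idx[-length(idx)], , drop = FALSE]
  v2 <- states$velocity[idx[-1], , drop = FALSE]
  ang <- atan2(sqrt(rowSums(cross_rows(v1, v2)^2)), rowSums(v1 * v2))
  out <- mean(ang) / states$dt
  if (degrees) out * 180 / pi else out
}

#' Sinuosity of a flight path
#'
#' Straight start-to-end distance divided by covered distance; 1 for a
#' perfectly straight path, approaching 0 for closed or convoluted paths.
#' (This is the reciprocal of the conventional sinuosity index; the
#' convention here keeps the quantity in \[0, 1\].)
#'
#' @inheritParams covered_distance
#' @return Dimensionless in \[0, 1\].
#' @export
sinuosity <- function(states, burn_in = 5L) {
  d <- covered_distance(states, burn_in)
  if (d <= 0) stop("sinuosity: undefined - zero covered distance")
  idx <- included_frames(states, burn_in)
  straight <- sqrt(sum((states$position[idx[length(idx)], ] -
                          states$position[idx[1], ])^2))
  min(1, max(0, straight / d))
}

#' Mean flight curvature
#'
#' Frame-averaged differential-geometric curvature of the path,
#' kappa = |v x a| / |v|^3 — how sharply the butterfly turns, in 1/m.
#'
#' @inheritParams turning_acceleration
#' @return 1/m.
#' @export
flight_curvature <- function(states, burn_in = 5L, eps = 1e-6) {
  idx <- moving_frames(states, burn_in, eps)
  if (length(idx) == 0L)
    stop("flight_curvature: undefined - no frames with speed > ", eps)
  v <- states$velocity[idx, , drop = FALSE]
  a <- states$acceleration[idx, , drop = FALSE]
  mean(sqrt(rowSums(cross_rows(v, a)^2)) / sqrt(rowSums(v^2))^3)
}

#' Mean ascent angle
#'
#' Mean angle between the velocity vector and the horizontal plane,
#' arcsin(v_z / |v|) in degrees; sign preserved (descent negative). Set
#' `absolute = TRUE` to average |angle| instead.
#'
#' @inheritParams turning_acceleration
#' @param absolute Average the absolute angle.
#' @return Degrees in \[-90, 90\].
#' @export
ascent_angle <- function(states, burn_in = 5L, eps = 1e-6, absolute = FALSE) {
  idx <- moving_frames(states, burn_in, eps)
  if (length(idx) == 0L)
    stop("ascent_angle: undefined - no frames with speed > ", eps)
  sp <- speed_of(states, idx)
  ang <- asin(pmin(1, pmax(-1, states$velocity[idx, 3] / sp))) * 180 / pi
  if (absolute) mean(abs(ang)) else mean(ang)
}

#' Wingbeat record for one trajectory
#'
#' The manually counted total number of wingbeats over a trajectory and its
#' duration. Counts may be missing (wingbeats too hard to score).
#'
#' @param trajectory_id Identifier.
#' @param n_wingbeats Non-negative integer count, or `NA`.
#' @param duration_s Trajectory duration in seconds (> 0).
#' @return An object of class `wingbeat_record`.
#' @export
wingbeat_record <- function(trajectory_id, n_wingbeats, duration_s) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (!is.na(n_wingbeats) && n_wingbeats < 0)
    stop("n_wingbeats must be non-negative")
  structure(list(trajectory_id = trajectory_id,
                 n_wingbeats = n_wingbeats, duration_s = duration_s),
            class = "wingbeat_record")
}

#' Wingbeat frequency
#'
#' Average number of wingbeats per second; a missing count gives a missing
#' frequency (later imputed in the statistical layer).
#'
#' @param rec A [wingbeat_record()].
#' @return Hz, or `NA`.
#' @export
wingbeat_frequency <- function(rec) {
  if (is.na(rec$n_wingbeats)) return(NA_real_)
  rec$n_wingbeats / rec$duration_s
}

#' Summarise a trajectory into the eleven flight parameters
#'
#' Assembles the full flight summary: wingbeat frequency, covered distance,
#' flight height, mean velocity, mean acceleration, advance ratio, turning
#' acceleration, turning rate, sinuosity, flight curvature and ascent
#' angle, plus bookkeeping fields.
#'
#' @param states A `smoothed_states` object.
#' @param rec A [wingbeat_record()] (`NULL` = no count; frequency and
#'   advance ratio come out missing).
#' @param trajectory_id Identifier stored in the summary.
#' @param burn_in Frames dropped at each end.
#' @return A one-row data frame of class `flight_summary`.
#' @export
summarize_flight <- function(states, rec = NULL, trajectory_id = "traj",
                             burn_in = 5L) {
  idx <- included_frames(states, burn_in)
  if (length(idx) < 2L)
    stop("summarize_flight: fewer than 2 usable frames after burn-in")
  f <- if (is.null(rec)) NA_real_ else wingbeat_frequency(rec)
  v <- mean_velocity(states, burn_in)
  out <- data.frame(
    trajectory_id = trajectory_id,
    wingbeat_frequency = f,
    covered_distance = covered_distance(states, burn_in),
    flight_height = flight_height(states, burn_in),
    mean_velocity = v,
    mean_acceleration = mean_acceleration(states, burn_in),
    advance_ratio = advance_ratio(v, f),
    turning_acceleration = turning_acceleration(states, burn_in),
    turning_rate = turning_rate(states, burn_in),
    turning_rate_deg = turning_rate(states, burn_in, degrees = TRUE),
    sinuosity = sinuosity(states, burn_in),
    flight_curvature = flight_curvature(states, burn_in),
    ascent_angle = ascent_angle(states, burn_in),
    n_frames_used = length(idx),
    stringsAsFactors = FALSE)
  class(out) <- c("flight_summary", "data.frame")
  out
}
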
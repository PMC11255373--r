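## Synthetic-data generators: every input the pipeline consumes can be
## produced here with known ground truth - 3D flight paths, stereo pixel
## tracks, calibration-wand sweeps, wing landmark sets, and full cohorts
## with the statistical structure of the seasonal-form study (group means
## and dispersions of morphology and flight parameters). All generators are
## pure functions of their configuration and seed.

#' Synthetic recording scene
#'
#' The stereo recording geometry emulated by the renderer: a 6 x 2.5 x
#' 2.5 m tunnel cage, two cameras on 0.8 m tripods at perpendicular viewing
#' angles outside the cage, 120 frames per second at 2560 x 1440 px. These
#' defaults are the study conditions; pixel noise, frame dropout and radial
#' distortion are configurable.
#'
#' @param cage Cage extents (length, width, height) in metres.
#' @param fps Frames per second.
#' @param resolution Pixels (width, height).
#' @param cam_height Tripod height (m).
#' @param focal_px Pinhole focal length (px) of both cameras.
#' @param pixel_noise_sd Gaussian pixel noise SD (px) added when rendering.
#' @param dropout Per-frame i.i.d. probability that a camera misses the
#'   point (not digitised).
#' @param k1 Radial distortion coefficient of both lenses (0 = none).
#' @return An object of class `scene_config` carrying both the pinhole
#'   cameras (for rendering, with depth information) and their exact
#'   11-coefficient DLT equivalents (for calibration and triangulation).
#' @export
scene_config <- function(cage = c(6, 2.5, 2.5), fps = 120,
                         resolution = c(2560, 1440), cam_height = 0.8,
                         focal_px = 1200, pixel_noise_sd = 0, dropout = 0,
                         k1 = 0) {
  stopifnot(fps > 0, all(cage > 0), dropout >= 0, dropout < 1)
  centre <- c(cage[1] / 2, cage[2] / 2, cage[3] / 2)
  pin1 <- make_pinhole(eye = c(cage[1] / 2, -3.2, cam_height), target = centre,
                       focal = focal_px, image_width = resolution[1],
                       image_height = resolution[2], id = "cam1")
  pin2 <- make_pinhole(eye = c(-3.2, cage[2] / 2, cam_height), target = centre,
                       focal = focal_px, image_width = resolution[1],
                       image_height = resolution[2], id = "cam2")
  structure(list(cage = cage, fps = fps, resolution = resolution,
                 cam_height = cam_height, focal_px = focal_px,
                 pixel_noise_sd = pixel_noise_sd, dropout = dropout, k1 = k1,
                 pinholes = list(pin1, pin2),
                 cameras = list(pinhole_to_camera(pin1, k1 = k1),
                                pinhole_to_camera(pin2, k1 = k1))),
            class = "scene_config")
}

#' Flight path profile
#'
#' Parametric description of a ground-truth flight path. Kinds: `straight`,
#' `circle`, `semicircle`, `helix` (radius + vertical pitch), `flutter`
#' (straight flight with a vertical wingbeat sinusoid) and `crw`
#' (correlated random walk). Analytic kinds carry closed-form kinematic
#' ground truth; `flutter` and `crw` carry ground truth integrated
#' numerically at generation time.
#'
#' @param kind Profile kind.
#' @param speed Mean speed (m/s).
#' @param radius Circle/helix radius (m).
#' @param pitch Helix pitch (m per radian of turn).
#' @param flutter_amplitude,flutter_frequency Vertical sinusoid amplitude
#'   (m) and frequency (Hz) of the `flutter` kind.
#' @param crw_turn_sd Per-step turning-angle SD (rad) of the `crw` kind
#'   (concentration = 1/sd^2); `crw_speed_sd` the step-speed SD (m/s).
#' @param crw_speed_sd Step-speed SD for `crw`.
#' @param duration Seconds (>= 20 frames).
#' @param dt Seconds per frame.
#' @param start Path start/centre reference (m), inside the cage.
#' @param seed RNG seed (stochastic kinds are pure functions of it).
#' @return An object of class `path_profile`.
#' @export
path_profile <- function(kind = c("straight", "circle", "semicircle", "helix",
                                  "flutter", "crw"),
                         speed = 1.5, radius = 0.5, pitch = 0.1,
                         flutter_amplitude = 0.02, flutter_frequency = 11,
                         crw_turn_sd = 0.25, crw_speed_sd = 0.3,
                         duration = 3, dt = 1 / 120,
                         start = c(2.0, 1.25, 1.2), seed = 1L) {
  kind <- match.arg(kind)
  if (duration / dt < 20)
    stop("path_profile: need >= 20 frames (duration/dt)")
  structure(list(kind = kind, speed = speed, radius = radius, pitch = pitch,
                 flutter_amplitude = flutter_amplitude,
                 flutter_frequency = flutter_frequency,
                 crw_turn_sd = crw_turn_sd, crw_speed_sd = crw_speed_sd,
                 duration = duration, dt = dt, start = start,
                 seed = as.integer(seed)),
            class = "path_profile")
}

## kinematic summaries of a discrete path given analytic v(t), a(t)
numeric_truth <- function(pos, vel, acc, dt) {
  sp <- sqrt(rowSums(vel^2))
  cr <- cross_rows(vel, acc)
  crn <- sqrt(rowSums(cr^2))
  d <- sum(sqrt(rowSums(diff(pos)^2)))
  list(covered_distance = d,
       flight_height = mean(pos[, 3]),
       mean_velocity = mean(sp),
       mean_acceleration = mean(sqrt(rowSums(acc^2))),
       turning_acceleration = mean(crn / sp),
       turning_rate = {
         v1 <- vel[-nrow(vel), , drop = FALSE]
         v2 <- vel[-1, , drop = FALSE]
         mean(atan2(sqrt(rowSums(cross_rows(v1, v2)^2)),
                    rowSums(v1 * v2))) / dt
       },
       sinuosity = min(1, sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2)) / d),
       flight_curvature = mean(crn / sp^3),
       ascent_angle = mean(asin(pmin(1, pmax(-1, vel[, 3] / sp)))) * 180 / pi)
}

#' Generate a ground-truth flight path
#'
#' Realises a [path_profile()] as a noiseless [trajectory3d()] together
#' with its kinematic ground truth. Frames that leave the cage volume are
#' truncated (flagged invalid) with a warning.
#'
#' @param profile A [path_profile()].
#' @param cage Cage extents used for bounds truncation.
#' @return A list: `traj` ([trajectory3d()]), `truth` (named list of the
#'   kinematic parameters), `profile`.
#' @export
generate_flight_path <- function(profile, cage = c(6, 2.5, 2.5)) {
  stopifnot(inherits(profile, "path_profile"))
  dt <- profile$dt
  tt <- seq(0, profile$duration, by = dt)
  n <- length(tt)
  p0 <- profile$start
  v <- profile$speed
  truth <- NULL
  if (profile$kind == "straight") {
    dir <- unit(c(1, 0.15, 0))
    pos <- outer(tt, dir * v) + rep(p0, each = n)
    truth <- list(covered_distance = v * profile$duration,
                  flight_height = p0[3], mean_velocity = v,
                  mean_acceleration = 0, turning_acceleration = 0,
                  turning_rate = 0, sinuosity = 1, flight_curvature = 0,
                  ascent_angle = 0)
  } else if (profile$kind %in% c("circle", "semicircle")) {
    r <- profile$radius
    om <- v / r
    arc <- if (profile$kind == "semicircle") pi else om * profile$duration
    if (profile$kind == "semicircle") tt <- seq(0, pi / om, by = dt)
    th <- om * tt
    pos <- cbind(p0[1] + r * cos(th) - r, p0[2] + r * sin(th), p0[3])
    span <- max(th)
    truth <- list(covered_distance = r * span, flight_height = p0[3],
                  mean_velocity = v, mean_acceleration = v^2 / r,
                  turning_acceleration = v^2 / r, turning_rate = om,
                  sinuosity = min(1, 2 * r * abs(sin(span / 2)) / (r * span)),
                  flight_curvature = 1 / r, ascent_angle = 0)
  } else if (profile$kind == "helix") {
    a <- profile$radius; b <- profile$pitch
    om <- v / sqrt(a^2 + b^2)
    th <- om * tt
    pos <- cbind(p0[1] + a * cos(th) - a, p0[2] + a * sin(th),
                 p0[3] + b * th)
    span <- max(th)
    truth <- list(covered_distance = sqrt(a^2 + b^2) * span,
                  flight_height = p0[3] + b * span / 2,
                  mean_velocity = v,
                  mean_acceleration = om^2 * a,
                  turning_acceleration = om^2 * a,
                  turning_rate = om * a / sqrt(a^2 + b^2),
                  sinuosity = min(1, sqrt((2 * a * sin(span / 2))^2 +
                                            (b * span)^2) /
                                    (sqrt(a^2 + b^2) * span)),
                  flight_curvature = a / (a^2 + b^2),
                  ascent_angle = asin(b / sqrt(a^2 + b^2)) * 180 / pi)
  } else if (profile$kind == "flutter") {
    A <- profile$flutter_amplitude
    omw <- 2 * pi * profile$flutter_frequency
    dir <- unit(c(1, 0.15, 0))
    pos <- outer(tt, dir * v) + rep(p0, each = n)
    pos[, 3] <- pos[, 3] + A * sin(omw * tt)
    vel <- outer(rep(1, n), dir * v)
    vel[, 3] <- vel[, 3] + A * omw * cos(omw * tt)
    acc <- matrix(0, n, 3)
    acc[, 3] <- -A * omw^2 * sin(omw * tt)
    truth <- numeric_truth(pos, vel, acc, dt)
  } else {  # crw
    withr_seed <- profile$seed
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(withr_seed)
    heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                        stats::rnorm(n - 2, 0, profile$crw_turn_sd)))
    step_sp <- pmax(0.05, stats::rnorm(n - 1, v, profile$crw_speed_sd))
    dirs <- cbind(cos(heading), sin(heading), stats::rnorm(n - 1, 0, 0.15))
    dirs <- dirs / sqrt(rowSums(dirs^2))
    steps <- dirs * step_sp
    pos <- rbind(p0, rep(p0, each = n - 1) + apply(steps * dt, 2, cumsum))
    vel <- rbind(steps, steps[n - 1, ])
    acc <- rbind(diff(vel) / dt, 0)
    truth <- numeric_truth(pos, vel, acc, dt)
  }
  inside <- pos[, 1] >= 0 & pos[, 1] <= cage[1] &
    pos[, 2] >= 0 & pos[, 2] <= cage[2] &
    pos[, 3] >= 0 & pos[, 3] <= cage[3]
  if (!all(inside))
    warning("generate_flight_path: ", sum(!inside),
            " frames outside the cage truncated")
  traj <- trajectory3d(seq_along(tt) - 1L, pos, valid = inside, dt = dt)
  list(traj = traj, truth = truth, profile = profile)
}

## save/restore global RNG state so generators are pure functions of seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Render a 3D trajectory into two pixel tracks
#'
#' Projects each valid frame through both scene cameras, applies forward
#' lens distortion (if configured), adds i.i.d. Gaussian pixel noise, drops
#' frames at the configured dropout probability, and flags points outside
#' the sensor or behind a camera as invalid.
#'
#' @param traj A [trajectory3d()].
#' @param scene A [scene_config()].
#' @param seed RNG seed for noise and dropout.
#' @return A list of two [pixel_track()]s.
#' @export
render_pixel_tracks <- function(traj, scene, seed = 1L) {
  stopifnot(inherits(traj, "trajectory3d"), inherits(scene, "scene_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- length(traj$frame_index)
  out <- vector("list", 2)
  for (ci in 1:2) {
    pin <- scene$pinholes[[ci]]
    cam <- scene$cameras[[ci]]
    xy <- matrix(NA_real_, n, 2)
    ok <- traj$valid
    pr <- P_project(pinhole_P(pin), traj$xyz[ok, , drop = FALSE])
    uv <- pr$uv
    if (scene$k1 != 0)
      uv <- distort_points(uv, scene$k1, image_centre(cam), radius_scale(cam))
    if (scene$pixel_noise_sd > 0)
      uv <- uv + matrix(stats::rnorm(length(uv), 0, scene$pixel_noise_sd),
                        ncol = 2)
    vis <- pr$depth > 0 &
      uv[, 1] >= 0 & uv[, 1] < scene$resolution[1] &
      uv[, 2] >= 0 & uv[, 2] < scene$resolution[2]
    if (scene$dropout > 0)
      vis <- vis & (stats::runif(sum(ok)) >= scene$dropout)
    xy[which(ok)[vis], ] <- uv[vis, , drop = FALSE]
    valid <- rep(FALSE, n); valid[which(ok)[vis]] <- TRUE
    if (!any(valid))
      stop("render_pixel_tracks: subject never visible to camera ", pin$id)
    out[[ci]] <- pixel_track(traj$frame_index, xy, valid, camera_id = pin$id)
  }
  out
}

#' Generate a calibration-wand sweep
#'
#' Random rigid poses of a two-point wand spanning the cage volume,
#' projected through both scene cameras with the scene's pixel noise. The
#' endpoint separation before projection is exactly `wand_length`.
#'
#' @param scene A [scene_config()].
#' @param wand_length Metres (default 0.24, the study wand).
#' @param n_poses Number of poses (>= 30).
#' @param seed RNG seed.
#' @param margin Clearance kept from the cage walls (m).
#' @return A [wand_observation()].
#' @export
generate_wand_sweep <- function(scene, wand_length = 0.24, n_poses = 200L,
                                seed = 1L, margin = 0.4) {
  stopifnot(inherits(scene, "scene_config"))
  if (n_poses < 30L)
    stop("generate_wand_sweep: insufficient data - need >= 30 poses")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lo <- rep(margin, 3); hi <- scene$cage - margin
  ctr <- cbind(stats::runif(n_poses, lo[1], hi[1]),
               stats::runif(n_poses, lo[2], hi[2]),
               stats::runif(n_poses, lo[3], hi[3]))
  z <- stats::rnorm(n_poses * 3)
  dirm <- matrix(z, n_poses, 3)
  dirm <- dirm / sqrt(rowSums(dirm^2))
  A <- ctr + dirm * wand_length / 2
  B <- ctr - dirm * wand_length / 2
  shoot <- function(pts, ci) {
    pin <- scene$pinholes[[ci]]
    pr <- P_project(pinhole_P(pin), pts)
    uv <- pr$uv
    if (scene$k1 != 0)
      uv <- distort_points(uv, scene$k1, image_centre(scene$cameras[[ci]]),
                           radius_scale(scene$cameras[[ci]]))
    if (scene$pixel_noise_sd > 0)
      uv <- uv + matrix(stats::rnorm(length(uv), 0, scene$pixel_noise_sd),
                        ncol = 2)
    bad <- pr$depth <= 0 | uv[, 1] < 0 | uv[, 1] >= scene$resolution[1] |
      uv[, 2] < 0 | uv[, 2] >= scene$resolution[2]
    uv[bad, ] <- NA_real_
    uv
  }
  wand_observation(seq_len(n_poses) - 1L,
                   cam1_a = shoot(A, 1), cam1_b = shoot(B, 1),
                   cam2_a = shoot(A, 2), cam2_b = shoot(B, 2),
                   wand_length = wand_length,
                   image_width = scene$resolution[1],
                   image_height = scene$resolution[2])
}

#' Render a known-vertical reference segment
#'
#' Projects a vertical plumb segment at the cage centre through both
#' cameras, for use as `vertical_ref` in [wand_calibrate()].
#'
#' @param scene A [scene_config()].
#' @param length Segment length (m).
#' @param base_height Height of the segment's lower end above the ground
#'   (m); carried along so calibration can anchor z = 0 to the ground.
#' @return A list with `cam1_top`, `cam1_bottom`, `cam2_top`,
#'   `cam2_bottom` and `bottom_height`.
#' @export
render_vertical_ref <- function(scene, length = 1, base_height = 0.5) {
  base <- c(scene$cage[1] / 2, scene$cage[2] / 2, base_height)
  top <- base + c(0, 0, length)
  sh <- function(p, ci) P_project(pinhole_P(scene$pinholes[[ci]]),
                                  matrix(p, 1))$uv
  list(cam1_top = sh(top, 1), cam1_bottom = sh(base, 1),
       cam2_top = sh(top, 2), cam2_bottom = sh(base, 2),
       bottom_height = base_height)
}
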
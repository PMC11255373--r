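## Stereo geometry: DLT camera model, point (un)distortion, calibration
## (known-points and wand-based) and two-view triangulation.
##
## Conventions: world coordinates in metres, z vertical up, ground z = 0;
## pixels x rightward, y downward; frames 0-based.

#' Direct linear transformation camera model
#'
#' Constructs the 11-coefficient DLT camera used throughout the package. The
#' forward map from a world point \eqn{(x, y, z)} (metres) to a pixel
#' \eqn{(u, v)} is
#' \deqn{u = \frac{L_1 x + L_2 y + L_3 z + L_4}{L_9 x + L_{10} y + L_{11} z + 1}, \quad
#'       v = \frac{L_5 x + L_6 y + L_7 z + L_8}{L_9 x + L_{10} y + L_{11} z + 1}.}
#' An optional one-parameter radial (Brown) distortion about the geometric
#' image centre, with radius normalised by the image half-diagonal, models
#' wide-lens barrel distortion at the point level.
#'
#' @param dlt Numeric vector of the 11 DLT coefficients `L1..L11`.
#' @param k1 Radial distortion coefficient (dimensionless; 0 = none).
#' @param image_width,image_height Sensor size in pixels.
#' @param id Camera label.
#' @param rms Root-mean-square reprojection residual (px) of the calibration
#'   set used to fit the model, if known.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(dlt, k1 = 0, image_width = 2560, image_height = 1440,
                         id = "cam", rms = NA_real_) {
  dlt <- as.numeric(dlt)
  if (length(dlt) != 11L || any(!is.finite(dlt)))
    stop("`dlt` must be 11 finite coefficients")
  P <- rbind(dlt[1:4], dlt[5:8], c(dlt[9:11], 1))
  if (qr(P)$rank < 3L)
    stop("degenerate DLT: the 3x4 projection matrix has rank < 3")
  structure(list(dlt = dlt, k1 = k1,
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 id = id, rms = rms),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model '%s'> %dx%d px, k1 = %g, fit RMS = %s px\n",
              x$id, x$image_width, x$image_height, x$k1,
              ifelse(is.na(x$rms), "NA", format(x$rms, digits = 4))))
  cat("  L1..L11:", paste(format(x$dlt, digits = 6), collapse = " "), "\n")
  invisible(x)
}

dlt_matrix <- function(cam) {
  matrix(c(cam$dlt[1:4], cam$dlt[5:8], cam$dlt[9:11], 1),
         nrow = 3, byrow = TRUE)
}

image_centre <- function(cam) c(cam$image_width, cam$image_height) / 2

## radius normalisation scale: half the image diagonal
radius_scale <- function(cam) sqrt(sum(image_centre(cam)^2))

#' Project world points through a DLT camera
#'
#' Applies the DLT forward map and, when the camera carries a nonzero radial
#' coefficient, forward lens distortion. Points on the camera's principal
#' plane (projective denominator near zero) are rejected.
#'
#' @param xyz World point(s), a length-3 vector or an n x 3 matrix (metres).
#' @param cam A [camera_model()].
#' @param distort Apply forward radial distortion when `cam$k1 != 0`.
#' @return An n x 2 matrix of pixel coordinates (u, v).
#' @export
project <- function(xyz, cam, distort = TRUE) {
  xyz <- rbind3(xyz)
  w <- xyz %*% cam$dlt[9:11] + 1
  if (any(abs(w) < 1e-12))
    stop("degenerate projection: point on the camera's principal plane")
  u <- (xyz %*% cam$dlt[1:3] + cam$dlt[4]) / w
  v <- (xyz %*% cam$dlt[5:7] + cam$dlt[8]) / w
  uv <- cbind(u, v)
  if (distort && cam$k1 != 0)
    uv <- distort_points(uv, cam$k1, image_centre(cam), radius_scale(cam))
  dimnames(uv) <- list(NULL, c("u", "v"))
  uv
}

## coerce a 3-vector or n x 3 matrix to n x 3
rbind3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  stopifnot(ncol(x) == 3)
  x
}

#' Apply forward radial distortion to pixel coordinates
#'
#' One-parameter Brown model: an undistorted pixel at radial distance r from
#' the image centre (r normalised by `scale`, by default the half-diagonal)
#' maps to `centre + (p - centre) * (1 + k1 * r^2)`.
#'
#' @param uv n x 2 pixel coordinates (undistorted).
#' @param k1 Radial coefficient; negative = barrel.
#' @param centre Image centre (length 2, px).
#' @param scale Radius normalisation (px).
#' @return n x 2 distorted pixel coordinates.
#' @export
distort_points <- function(uv, k1, centre, scale) {
  uv <- matrix(uv, ncol = 2)
  d <- sweep(uv, 2, centre)
  r2 <- rowSums(d^2) / scale^2
  sweep(d * (1 + k1 * r2), 2, centre, `+`)
}

#' Undistort pixel coordinates
#'
#' Inverts the one-parameter radial model by fixed-point iteration on the
#' undistorted radius, to better than 1e-8 px. The map must be invertible
#' over the image for the supplied `k1` (it is for the mild coefficients of
#' action-camera lenses); non-convergence raises an error.
#'
#' @inheritParams distort_points
#' @param uv n x 2 observed (distorted) pixel coordinates.
#' @param max_iter Iteration cap.
#' @return n x 2 undistorted pixel coordinates.
#' @export
undistort_points <- function(uv, k1, centre, scale, max_iter = 100L) {
  uv <- matrix(uv, ncol = 2)
  if (k1 == 0) return(uv)
  d_obs <- sweep(uv, 2, centre)
  d <- d_obs
  for (i in seq_len(max_iter)) {
    r2 <- rowSums(d^2) / scale^2
    d_new <- d_obs / (1 + k1 * r2)
    if (max(abs(d_new - d)) < 1e-8) {
      return(sweep(d_new, 2, centre, `+`))
    }
    d <- d_new
  }
  stop("undistort_points: fixed-point iteration did not converge; ",
       "radial model not invertible at k1 = ", k1)
}

#' Undistort the pixel coordinates of a 2D track
#'
#' Convenience wrapper applying [undistort_points()] to the valid frames of a
#' [pixel_track()] using the distortion parameters of its camera.
#'
#' @param track A `pixel_track`.
#' @param cam The [camera_model()] the track was observed by.
#' @return The track with undistorted coordinates.
#' @export
undistort_track <- function(track, cam) {
  if (cam$k1 == 0) return(track)
  ok <- track$valid
  track$xy[ok, ] <- undistort_points(track$xy[ok, , drop = FALSE], cam$k1,
                                     image_centre(cam), radius_scale(cam))
  track
}

#' Per-camera 2D pixel track
#'
#' Pixel coordinates of one tracked point (the butterfly thorax, or a wand
#' endpoint) in one camera, with a validity mask: frames where the point was
#' not digitised carry `valid = FALSE` and undefined coordinates.
#'
#' @param frame_index Strictly increasing 0-based integer frame numbers.
#' @param xy n x 2 matrix of pixel coordinates (x right, y down).
#' @param valid Logical mask, `FALSE` where not digitised.
#' @param camera_id Camera label.
#' @return An object of class `pixel_track`.
#' @export
pixel_track <- function(frame_index, xy, valid = NULL, camera_id = "cam") {
  frame_index <- as.integer(frame_index)
  if (is.unsorted(frame_index, strictly = TRUE))
    stop("frame_index must be strictly increasing")
  xy <- matrix(as.numeric(xy), ncol = 2)
  if (nrow(xy) != length(frame_index))
    stop("xy and frame_index lengths differ")
  if (is.null(valid)) valid <- apply(is.finite(xy), 1, all)
  structure(list(camera_id = camera_id, frame_index = frame_index,
                 xy = xy, valid = as.logical(valid)),
            class = "pixel_track")
}

#' Calibrate a DLT camera from known 3D-2D correspondences
#'
#' Solves the linear DLT system in least squares for the 11 coefficients.
#' Requires at least 6 correspondences whose world points are not coplanar
#' (a coplanar set leaves the projective model underdetermined).
#'
#' @param world n x 3 world points (metres), n >= 6, non-coplanar.
#' @param pixels n x 2 pixel observations (undistorted).
#' @param image_width,image_height,id,k1 Passed to [camera_model()].
#' @return A [camera_model()] with its RMS reprojection residual stored.
#' @export
dlt_calibrate <- function(world, pixels, image_width = 2560,
                          image_height = 1440, id = "cam", k1 = 0) {
  world <- rbind3(world)
  pixels <- matrix(pixels, ncol = 2)
  n <- nrow(world)
  if (n < 6L)
    stop("dlt_calibrate: need at least 6 correspondences, got ", n)
  sv <- svd(scale(world, scale = FALSE))$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("dlt_calibrate: singular system - world points are coplanar ",
         "(third principal extent ", format(sv[3], digits = 3), " m)")
  u <- pixels[, 1]; v <- pixels[, 2]
  zero <- matrix(0, n, 4)
  A <- rbind(cbind(world, 1, zero, -u * world),
             cbind(zero, world, 1, -v * world))
  b <- c(u, v)
  L <- qr.coef(qr(A), b)
  cam <- camera_model(L, k1 = k1, image_width = image_width,
                      image_height = image_height, id = id)
  ## geometric (reprojection) residual, per pixel coordinate
  cam$rms <- sqrt(mean((project(world, cam, distort = FALSE) - pixels)^2))
  cam
}

#' Triangulate paired 2D tracks into a 3D trajectory
#'
#' Per-frame homogeneous linear least squares on the stacked two-camera DLT
#' equations. A frame is valid only where both cameras digitised the point
#' and the two viewing rays are well conditioned; other frames carry
#' `valid = FALSE` and are left for the smoother to estimate.
#'
#' @param track1,track2 `pixel_track`s sharing a frame clock (undistorted).
#' @param cam1,cam2 The corresponding [camera_model()]s.
#' @param dt Seconds per frame (default 1/120).
#' @param max_condition Frames whose 4x3 triangulation system has a singular
#'   value ratio above this are flagged invalid (near-parallel rays).
#' @return A [trajectory3d()].
#' @export
triangulate <- function(track1, track2, cam1, cam2, dt = 1 / 120,
                        max_condition = 1e6) {
  if (!identical(track1$frame_index, track2$frame_index))
    stop("triangulate: tracks do not share a frame clock")
  n <- length(track1$frame_index)
  xyz <- matrix(NA_real_, n, 3)
  valid <- track1$valid & track2$valid
  for (i in which(valid)) {
    p <- triangulate_point(track1$xy[i, ], track2$xy[i, ], cam1, cam2,
                           max_condition = max_condition)
    if (is.null(p)) valid[i] <- FALSE else xyz[i, ] <- p
  }
  trajectory3d(track1$frame_index, xyz, valid = valid, dt = dt)
}

## single-point two-camera DLT inversion; NULL when ill-conditioned
triangulate_point <- function(uv1, uv2, cam1, cam2, max_condition = 1e6) {
  A <- rbind(dlt_rows(uv1, cam1), dlt_rows(uv2, cam2))
  s <- svd(A[, 1:3])
  if (s$d[3] < 1e-14 || s$d[1] / s$d[3] > max_condition) return(NULL)
  drop(qr.solve(A[, 1:3], -A[, 4]))
}

dlt_rows <- function(uv, cam) {
  L <- cam$dlt
  rbind(c(uv[1] * L[9] - L[1], uv[1] * L[10] - L[2], uv[1] * L[11] - L[3],
          uv[1] - L[4]),
        c(uv[2] * L[9] - L[5], uv[2] * L[10] - L[6], uv[2] * L[11] - L[7],
          uv[2] - L[8]))
}

#' Time-stamped 3D trajectory
#'
#' Raw (pre-smoothing) 3D positions with a validity mask. World frame:
#' metres, z vertical up, ground plane at z = 0.
#'
#' @param frame_index Strictly increasing 0-based frame numbers.
#' @param xyz n x 3 positions (metres); rows with `valid = FALSE` may be NA.
#' @param valid Logical mask.
#' @param dt Seconds per frame.
#' @return An object of class `trajectory3d`.
#' @export
trajectory3d <- function(frame_index, xyz, valid = NULL, dt = 1 / 120) {
  stopifnot(dt > 0)
  frame_index <- as.integer(frame_index)
  if (is.unsorted(frame_index, strictly = TRUE))
    stop("frame_index must be strictly increasing")
  xyz <- rbind3(xyz)
  if (is.null(valid)) valid <- apply(is.finite(xyz), 1, all)
  valid <- as.logical(valid)
  if (any(valid & !apply(is.finite(xyz), 1, all)))
    stop("valid frames must have finite coordinates")
  structure(list(dt = dt, frame_index = frame_index, xyz = xyz,
                 valid = valid),
            class = "trajectory3d")
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("<trajectory3d> %d frames (%d valid), dt = %.5f s\n",
              length(x$frame_index), sum(x$valid), x$dt))
  invisible(x)
}
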
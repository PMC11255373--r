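## Wand-based stereo calibration: joint estimation of both cameras and the
## 3D wand endpoints from tracked images of a rigid two-point wand of known
## length, by nonlinear least squares on reprojection error.

#' Calibration-wand observation set
#'
#' Per-frame pixel coordinates of the two wand endpoints (A, B) in each of
#' two cameras, plus the known rigid endpoint separation that fixes metric
#' scale. At least 30 frames with both endpoints visible in both cameras are
#' required for calibration.
#'
#' @param frame_index Integer frame numbers.
#' @param cam1_a,cam1_b,cam2_a,cam2_b n x 2 pixel coordinate matrices of
#'   endpoints A and B in cameras 1 and 2 (NA = not digitised).
#' @param wand_length Endpoint separation in metres (> 0); the study wand
#'   was 0.24 m.
#' @param image_width,image_height Sensor size in pixels.
#' @return An object of class `wand_observation`.
#' @export
wand_observation <- function(frame_index, cam1_a, cam1_b, cam2_a, cam2_b,
                             wand_length = 0.24, image_width = 2560,
                             image_height = 1440) {
  if (wand_length <= 0) stop("wand_length must be > 0")
  m <- function(x) matrix(as.numeric(x), ncol = 2)
  obs <- list(frame_index = as.integer(frame_index),
              cam1_a = m(cam1_a), cam1_b = m(cam1_b),
              cam2_a = m(cam2_a), cam2_b = m(cam2_b),
              wand_length = wand_length,
              image_width = image_width, image_height = image_height)
  obs$usable <- apply(
    cbind(obs$cam1_a, obs$cam1_b, obs$cam2_a, obs$cam2_b), 1,
    function(r) all(is.finite(r)))
  class(obs) <- "wand_observation"
  obs
}

## stack usable endpoint observations as two matched pixel lists
wand_points <- function(obs) {
  ok <- obs$usable
  list(uv1 = rbind(obs$cam1_a[ok, , drop = FALSE],
                   obs$cam1_b[ok, , drop = FALSE]),
       uv2 = rbind(obs$cam2_a[ok, , drop = FALSE],
                   obs$cam2_b[ok, , drop = FALSE]),
       n_pose = sum(ok))
}

## normalized 8-point essential matrix; x2' E x1 = 0
estimate_essential <- function(x1, x2) {
  A <- cbind(x2[, 1] * x1[, 1], x2[, 1] * x1[, 2], x2[, 1],
             x2[, 2] * x1[, 1], x2[, 2] * x1[, 2], x2[, 2],
             x1[, 1], x1[, 2], 1)
  e <- svd(A)$v[, 9]
  E <- matrix(e, 3, 3, byrow = TRUE)
  s <- svd(E)
  s$u %*% diag(c(1, 1, 0)) %*% t(s$v)
}

## decompose E into the 4 (R, t) candidates and pick by cheirality
decompose_essential <- function(E, x1, x2) {
  s <- svd(E)
  U <- s$u; V <- s$v
  if (det(U) < 0) U <- -U
  if (det(V) < 0) V <- -V
  W <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  cands <- list(list(R = U %*% W %*% t(V), t = U[, 3]),
                list(R = U %*% W %*% t(V), t = -U[, 3]),
                list(R = U %*% t(W) %*% t(V), t = U[, 3]),
                list(R = U %*% t(W) %*% t(V), t = -U[, 3]))
  P1 <- cbind(diag(3), 0)
  best <- NULL; best_n <- -1L
  idx <- seq_len(min(nrow(x1), 50L))
  for (cand in cands) {
    P2 <- cbind(cand$R, cand$t)
    X <- tri_linear_many(P1, P2, x1[idx, 1:2, drop = FALSE],
                         x2[idx, 1:2, drop = FALSE])
    d1 <- X[, 3]
    d2 <- (X %*% cand$R[3, ]) + cand$t[3]
    n_front <- sum(d1 > 0 & d2 > 0)
    if (n_front > best_n) { best_n <- n_front; best <- cand }
  }
  best
}

## pinhole pair from the 7-parameter vector
## theta = (log f1, log f2, rotvec2 (3), azimuth, polar) ; |t2| = 1
theta_to_pins <- function(theta, w, h) {
  cen <- c(w, h) / 2
  t2 <- c(cos(theta[7]) * cos(theta[6]), cos(theta[7]) * sin(theta[6]),
          sin(theta[7]))
  list(f1 = exp(theta[1]), f2 = exp(theta[2]),
       R2 = rotvec_to_matrix(theta[3:5]), t2 = t2, centre = cen)
}

pins_to_P <- function(pp) {
  K1 <- matrix(c(pp$f1, 0, 0, 0, pp$f1, 0, pp$centre[1], pp$centre[2], 1),
               3, 3)
  K2 <- matrix(c(pp$f2, 0, 0, 0, pp$f2, 0, pp$centre[1], pp$centre[2], 1),
               3, 3)
  list(P1 = K1 %*% cbind(diag(3), 0), P2 = K2 %*% cbind(pp$R2, pp$t2))
}

#' Wand-based calibration of a two-camera rig
#'
#' Jointly estimates both cameras and the 3D wand endpoint positions by
#' nonlinear least squares on pixel reprojection error. Because two fully
#' projective 11-coefficient cameras are not identifiable from reprojection
#' error alone, the optimisation runs over a constrained pinhole
#' parameterisation (one focal length per camera, principal point at the
#' image centre, relative pose), initialised from a normalized 8-point
#' essential-matrix estimate, then alternates linear triangulation of the
#' endpoints with Levenberg-Marquardt refinement of the camera parameters.
#' The gauge is fixed by: metric scale such that the mean reconstructed
#' wand length equals `obs$wand_length`; z axis aligned to `vertical_ref`
#' when given (otherwise to camera 1's image "up"); y axis along the
#' horizontal component of camera 1's viewing direction; world origin at
#' the centroid of the reconstructed wand cloud, except that z = 0 is
#' anchored to the ground plane when the vertical reference carries its
#' known `bottom_height`. Inputs are assumed undistorted; the fitted
#' cameras carry k1 = 0.
#'
#' @param obs A [wand_observation()] with >= 30 usable frames.
#' @param vertical_ref Optional known-vertical segment: a list with n x 2
#'   pixel matrices `cam1_top`, `cam1_bottom`, `cam2_top`, `cam2_bottom`
#'   (top above bottom in the world).
#' @param max_outer Outer triangulate/refine alternations.
#' @return A list of class `wand_calibration`: `cameras` (two
#'   [camera_model()]s), `wand_lengths` (per-frame reconstructed lengths,
#'   m), `mean_length`, `sd_length`, `rms_px` (reprojection RMS), and
#'   `endpoints` (reconstructed A/B positions in the final world frame).
#' @export
wand_calibrate <- function(obs, vertical_ref = NULL, max_outer = 12L) {
  pts <- wand_points(obs)
  if (pts$n_pose < 30L)
    stop("wand_calibrate: insufficient data - ", pts$n_pose,
         " usable frames (need >= 30)")
  w <- obs$image_width; h <- obs$image_height
  cen <- c(w, h) / 2

  uv_obs <- rbind(pts$uv1, pts$uv2)
  n <- pts$n_pose
  ## variable-projection residual: the wand endpoints are re-triangulated
  ## linearly at every camera evaluation, so the LM runs over the 7 camera
  ## parameters only while minimising the joint objective. Reprojection
  ## error alone leaves a projective ambiguity when the optical axes are
  ## coplanar (a common rig degeneracy), so the wand's rigidity - zero
  ## variation of the reconstructed endpoint separation - enters the
  ## objective as additional residuals (relative variation, weighted to be
  ## commensurate with pixels: 1% length scatter ~ rigidity_weight px).
  rigidity_weight <- 100
  resid_fn <- function(th) {
    pp <- theta_to_pins(th, w, h)
    Ps <- pins_to_P(pp)
    X <- tri_linear_many(Ps$P1, Ps$P2, pts$uv1, pts$uv2)
    pr1 <- P_project(Ps$P1, X)$uv
    pr2 <- P_project(Ps$P2, X)$uv
    len <- sqrt(rowSums((X[seq_len(n), , drop = FALSE] -
                           X[n + seq_len(n), , drop = FALSE])^2))
    r <- c(as.numeric(rbind(pr1, pr2) - uv_obs),
           rigidity_weight * (len - mean(len)) / mean(len))
    r[!is.finite(r)] <- 1e4
    r
  }
  n_px_resid <- 2L * nrow(uv_obs)
  refine <- function(theta, maxiter) {
    fit <- minpack.lm::nls.lm(par = theta, fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = maxiter, ptol = 1e-14,
                                ftol = 1e-14))
    list(theta = fit$par, rms = sqrt(mean(fit$fvec^2)),
         rms_px = sqrt(mean(fit$fvec[seq_len(n_px_resid)]^2)))
  }

  ## multi-start over focal guesses: the essential-matrix initialisation
  ## depends on the assumed focal length, which is unknown a priori
  best <- NULL
  for (f0 in c(0.45, 0.7, 1.0, 1.5) * (w + h) / 2) {
    norm1 <- cbind(sweep(pts$uv1, 2, cen) / f0, 1)
    norm2 <- cbind(sweep(pts$uv2, 2, cen) / f0, 1)
    E <- estimate_essential(norm1, norm2)
    rt <- decompose_essential(E, norm1, norm2)
    theta0 <- c(log(f0), log(f0), matrix_to_rotvec(rt$R),
                atan2(rt$t[2], rt$t[1]), asin(min(1, max(-1, rt$t[3]))))
    cand <- refine(theta0, 40L)
    if (is.null(best) || cand$rms < best$rms) best <- cand
  }
  for (i in seq_len(max_outer)) {
    prev <- best$rms
    best <- refine(best$theta, 100L)
    if (abs(prev - best$rms) < 1e-12) break
  }
  theta <- best$theta
  Ps <- pins_to_P(theta_to_pins(theta, w, h))
  X <- tri_linear_many(Ps$P1, Ps$P2, pts$uv1, pts$uv2)
  rms_px <- best$rms_px
  if (!is.finite(rms_px) || rms_px > 50)
    stop("wand_calibrate: optimisation failed to converge ",
         "(final RMS ", format(rms_px, digits = 3), " px)")

  ## metric scale from the known wand length
  n <- pts$n_pose
  A <- X[seq_len(n), , drop = FALSE]
  B <- X[n + seq_len(n), , drop = FALSE]
  len <- sqrt(rowSums((A - B)^2))
  s <- obs$wand_length / mean(len)

  pp <- theta_to_pins(theta, w, h)
  pin1 <- list(focal = pp$f1, centre = cen, R = diag(3), t = c(0, 0, 0),
               image_width = w, image_height = h, id = "cam1")
  pin2 <- list(focal = pp$f2, centre = cen, R = pp$R2, t = s * pp$t2,
               image_width = w, image_height = h, id = "cam2")
  X <- X * s

  ## vertical direction in the current (camera-1) frame
  if (!is.null(vertical_ref)) {
    top <- tri_linear_many(Ps$P1, Ps$P2, matrix(vertical_ref$cam1_top, ncol = 2),
                           matrix(vertical_ref$cam2_top, ncol = 2)) * s
    bot <- tri_linear_many(Ps$P1, Ps$P2,
                           matrix(vertical_ref$cam1_bottom, ncol = 2),
                           matrix(vertical_ref$cam2_bottom, ncol = 2)) * s
    up_dir <- unit(colMeans(rbind3(top)) - colMeans(rbind3(bot)))
  } else {
    up_dir <- c(0, -1, 0)  # camera 1 image "up"
  }
  ## world rotation taking up_dir -> +z and camera-1 forward into the y-z
  ## half-space with positive y
  fwd1 <- c(0, 0, 1)
  yw <- fwd1 - sum(fwd1 * up_dir) * up_dir
  if (sqrt(sum(yw^2)) < 1e-8) yw <- c(0, 1, 0) - sum(c(0, 1, 0) * up_dir) * up_dir
  yw <- unit(yw)
  xw <- cross3(yw, up_dir)
  S <- rbind(xw, yw, up_dir)   # world_new = S %*% world_old
  dimnames(S) <- NULL

  origin_old <- colMeans(X)    # wand-cloud centroid becomes the new origin
  ## when the vertical reference carries its true height above the ground,
  ## anchor z = 0 to the ground plane
  if (!is.null(vertical_ref) && !is.null(vertical_ref$bottom_height)) {
    bot_new_z <- drop(S %*% (colMeans(rbind3(bot)) - origin_old))[3]
    dz <- vertical_ref$bottom_height - bot_new_z
    origin_old <- origin_old - drop(t(S) %*% c(0, 0, dz))
  }
  to_new <- function(p) drop(S %*% (p - origin_old))
  Xn <- t(apply(X, 1, to_new))

  ## re-express cameras in the new world frame: x_cam = R_old x_old + t_old,
  ## x_old = S' x_new + origin_old
  reframe <- function(pin, id) {
    Rn <- pin$R %*% t(S)
    tn <- drop(pin$R %*% origin_old) + pin$t
    eye <- drop(-t(Rn) %*% tn)
    list(focal = pin$focal, centre = pin$centre, R = Rn, t = tn, eye = eye,
         image_width = w, image_height = h, id = id)
  }
  pin1 <- reframe(pin1, "cam1")
  pin2 <- reframe(pin2, "cam2")
  cams <- list(pinhole_to_camera(pin1, rms = rms_px),
               pinhole_to_camera(pin2, rms = rms_px))

  An <- Xn[seq_len(n), , drop = FALSE]
  Bn <- Xn[n + seq_len(n), , drop = FALSE]
  len <- sqrt(rowSums((An - Bn)^2))
  structure(list(cameras = cams, wand_lengths = len,
                 mean_length = mean(len), sd_length = stats::sd(len),
                 rms_px = rms_px,
                 endpoints = list(a = An, b = Bn)),
            class = "wand_calibration")
}

#' @export
print.wand_calibration <- function(x, ...) {
  cat(sprintf(paste0("<wand_calibration> %d poses; wand length %.4f m ",
                     "(SD %.2e m); reprojection RMS %.3f px\n"),
              length(x$wand_lengths), x$mean_length, x$sd_length, x$rms_px))
  invisible(x)
}
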
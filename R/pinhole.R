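## Internal pinhole-camera machinery. Wand calibration optimises a
## constrained pinhole parameterisation (focal length per camera, principal
## point at the image centre, relative pose); these helpers build pinhole
## cameras, project through them, and convert them exactly to 11-coefficient
## DLT form.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) v / sqrt(sum(v^2))

## Rodrigues rotation vector -> matrix
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

matrix_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(axis^2)) < 1e-12) {
    ## theta ~ pi: take axis from R + I
    M <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(M), 0))
    axis[which.max(abs(axis))] <- axis[which.max(abs(axis))] *
      sign(M[which.max(abs(axis)), which.max(abs(axis))])
    return(unit(axis) * th)
  }
  unit(axis) * th
}

## camera looking from `eye` toward `target`, world-up `up`
## axes: x_cam = right, y_cam = down (pixel y), z_cam = forward
make_pinhole <- function(eye, target, focal, image_width = 2560,
                         image_height = 1440, up = c(0, 0, 1), id = "cam") {
  fwd <- unit(target - eye)
  right <- unit(cross3(fwd, up))
  down <- cross3(fwd, right)
  R <- rbind(right, down, fwd)
  dimnames(R) <- NULL
  list(focal = focal, centre = c(image_width, image_height) / 2,
       R = R, t = drop(-R %*% eye), eye = eye,
       image_width = image_width, image_height = image_height, id = id)
}

pinhole_P <- function(pin) {
  K <- matrix(c(pin$focal, 0, 0,
                0, pin$focal, 0,
                pin$centre[1], pin$centre[2], 1), 3, 3)
  K %*% cbind(pin$R, pin$t)
}

## project through a 3x4 matrix; returns list(uv, depth)
P_project <- function(P, xyz) {
  xyz <- rbind3(xyz)
  h <- cbind(xyz, 1) %*% t(P)
  list(uv = h[, 1:2, drop = FALSE] / h[, 3], depth = h[, 3])
}

## exact conversion pinhole -> 11-coefficient DLT camera_model;
## requires the world origin off the camera's principal plane (P[3,4] != 0)
pinhole_to_camera <- function(pin, k1 = 0, rms = NA_real_) {
  P <- pinhole_P(pin)
  if (abs(P[3, 4]) < 1e-9)
    stop("pinhole_to_camera: world origin lies on the principal plane; ",
         "shift the world frame before conversion")
  P <- P / P[3, 4]
  camera_model(c(P[1, ], P[2, ], P[3, 1:3]), k1 = k1,
               image_width = pin$image_width, image_height = pin$image_height,
               id = pin$id, rms = rms)
}

## linear two-view triangulation from 3x4 matrices (inhomogeneous LS)
tri_linear <- function(P1, P2, uv1, uv2) {
  A <- rbind(uv1[1] * P1[3, ] - P1[1, ],
             uv1[2] * P1[3, ] - P1[2, ],
             uv2[1] * P2[3, ] - P2[1, ],
             uv2[2] * P2[3, ] - P2[2, ])
  drop(qr.solve(A[, 1:3], -A[, 4]))
}

## vectorised linear triangulation of many points (normal equations of the
## stacked 4 x 3 system, solved per point by Cramer's rule)
tri_linear_many <- function(P1, P2, uv1, uv2) {
  n <- nrow(uv1)
  rowset <- list(outer(uv1[, 1], P1[3, ]) - rep_row(P1[1, ], n),
                 outer(uv1[, 2], P1[3, ]) - rep_row(P1[2, ], n),
                 outer(uv2[, 1], P2[3, ]) - rep_row(P2[1, ], n),
                 outer(uv2[, 2], P2[3, ]) - rep_row(P2[2, ], n))
  a11 <- a12 <- a13 <- a22 <- a23 <- a33 <- b1 <- b2 <- b3 <- numeric(n)
  for (R in rowset) {
    a11 <- a11 + R[, 1]^2;      a12 <- a12 + R[, 1] * R[, 2]
    a13 <- a13 + R[, 1] * R[, 3]; a22 <- a22 + R[, 2]^2
    a23 <- a23 + R[, 2] * R[, 3]; a33 <- a33 + R[, 3]^2
    b1 <- b1 - R[, 1] * R[, 4]; b2 <- b2 - R[, 2] * R[, 4]
    b3 <- b3 - R[, 3] * R[, 4]
  }
  c11 <- a22 * a33 - a23^2
  c12 <- a13 * a23 - a12 * a33
  c13 <- a12 * a23 - a13 * a22
  det <- a11 * c11 + a12 * c12 + a13 * c13
  cbind((b1 * c11 + b2 * c12 + b3 * c13) / det,
        (b1 * c12 + b2 * (a11 * a33 - a13^2) +
           b3 * (a12 * a13 - a11 * a23)) / det,
        (b1 * c13 + b2 * (a12 * a13 - a11 * a23) +
           b3 * (a11 * a22 - a12^2)) / det)
}

rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)
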
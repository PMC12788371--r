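#' 33-keypoint pose topology
#'
#' 1-based indices of the anatomical landmarks used by the kinematic chain,
#' following the common 33-landmark full-body pose layout (nose + face = 1-11,
#' shoulders 12/13, elbows 14/15, wrists 16/17, hands 18-23, hips 24/25,
#' knees 26/27, ankles 28/29, heels 30/31, foot tips 32/33; left before
#' right).
#'
#' @export
pose_landmarks <- list(
  nose = 1L,
  shoulder = c(left = 12L, right = 13L),
  elbow = c(left = 14L, right = 15L),
  wrist = c(left = 16L, right = 17L),
  hip = c(left = 24L, right = 25L),
  knee = c(left = 26L, right = 27L),
  ankle = c(left = 28L, right = 29L),
  heel = c(left = 30L, right = 31L),
  foot_index = c(left = 32L, right = 33L)
)

#' Pinhole camera with intrinsic and extrinsic calibration
#'
#' @param intrinsics 3 x 3 upper-triangular matrix with positive focal terms.
#' @param rotation 3 x 3 world-to-camera rotation (orthonormal).
#' @param translation length-3 world-to-camera translation.
#' @return `camera_model` with the derived 3 x 4 projection matrix.
#' @export
camera_model <- function(intrinsics, rotation, translation) {
  K <- as.matrix(intrinsics); R <- as.matrix(rotation)
  t <- as.numeric(translation)
  if (!all(dim(K) == c(3L, 3L)) || any(abs(K[lower.tri(K)]) > 1e-12))
    abort_invalid("intrinsics must be 3x3 upper-triangular")
  if (K[1, 1] <= 0 || K[2, 2] <= 0)
    abort_invalid("focal terms must be positive")
  if (!all(dim(R) == c(3L, 3L)) || max(abs(crossprod(R) - diag(3))) > 1e-9)
    abort_invalid("rotation must be orthonormal (R'R = I within 1e-9)")
  if (length(t) != 3L) abort_invalid("translation must be length 3")
  cam <- list(intrinsics = K, rotation = R, translation = t,
              projection = K %*% cbind(R, t))
  class(cam) <- "camera_model"
  cam
}

#' Projection matrix of a calibrated camera
#' @param camera a [camera_model()].
#' @return 3 x 4 matrix `P = K [R | t]`.
#' @export
projection_matrix <- function(camera) {
  stopifnot(inherits(camera, "camera_model"))
  camera$projection
}

#' Project world points through a camera
#'
#' @param camera a [camera_model()].
#' @param points `N x 3` world coordinates (meters).
#' @return list with `px` (`N x 2` pixels) and `valid` (`FALSE` where the
#'   point lies behind the camera; such points are not projected).
#' @export
project_points <- function(camera, points) {
  X <- cbind(as.matrix(points), 1)
  h <- X %*% t(projection_matrix(camera))
  valid <- h[, 3] > 1e-12
  px <- cbind(h[, 1] / h[, 3], h[, 2] / h[, 3])
  px[!valid, ] <- NA_real_
  list(px = px, valid = valid)
}

#' DLT triangulation of one point from two views
#'
#' Builds the homogeneous linear system from both projection rays and solves
#' it by the smallest right singular vector. Exact (residual ~1e-9) on
#' noiseless projections; with pixel noise it returns the least-squares point
#' and the RMS reprojection residual.
#'
#' A point observed invalidly (NA) in either view, or seen along (near-)
#' parallel rays, is flagged `valid = FALSE` and not triangulated.
#'
#' @param pt_a,pt_b pixel coordinates (length 2) in each view.
#' @param P_a,P_b 3 x 4 projection matrices.
#' @return list with `point` (length-3), `residual_px` (RMS reprojection
#'   residual), `valid`.
#' @export
triangulate_dlt <- function(pt_a, pt_b, P_a, P_b) {
  bad <- list(point = rep(NA_real_, 3), residual_px = NA_real_, valid = FALSE)
  if (anyNA(pt_a) || anyNA(pt_b)) return(bad)
  A <- rbind(pt_a[1] * P_a[3, ] - P_a[1, ],
             pt_a[2] * P_a[3, ] - P_a[2, ],
             pt_b[1] * P_b[3, ] - P_b[1, ],
             pt_b[2] * P_b[3, ] - P_b[2, ])
  sv <- svd(A)
  Xh <- sv$v[, 4]
  if (abs(Xh[4]) < 1e-12) return(bad)  # point at infinity: degenerate rays
  X <- Xh[1:3] / Xh[4]
  # reprojection residual
  rp <- function(P, pt) {
    h <- P %*% c(X, 1)
    if (abs(h[3]) < 1e-15) return(Inf)
    sum((h[1:2] / h[3] - pt)^2)
  }
  res <- sqrt((rp(P_a, pt_a) + rp(P_b, pt_b)) / 2)
  if (!is.finite(res)) return(bad)
  list(point = X, residual_px = res, valid = TRUE)
}

#' Batched DLT triangulation of keypoint tracks
#'
#' Vectorised least-squares triangulation of `T x K` keypoints from two
#' synchronized views (inhomogeneous normal-equation form of the DLT system,
#' solved per point by Cramer's rule). Agrees with [triangulate_dlt()] to
#' numerical precision away from degeneracies; keypoints invalid in either
#' view propagate as invalid.
#'
#' @param kp_a,kp_b arrays `T x K x 2` of pixel coordinates (NA = invalid).
#' @param P_a,P_b 3 x 4 projection matrices.
#' @return list with `points` (`T x K x 3`), `valid` (`T x K`).
#' @export
triangulate_tracks <- function(kp_a, kp_b, P_a, P_b) {
  d <- dim(kp_a)
  Tn <- d[1]; K <- d[2]
  ua <- as.vector(kp_a[, , 1]); va <- as.vector(kp_a[, , 2])
  ub <- as.vector(kp_b[, , 1]); vb <- as.vector(kp_b[, , 2])
  valid <- !(is.na(ua) | is.na(va) | is.na(ub) | is.na(vb))
  rows <- list(list(ua, P_a[3, ], P_a[1, ]),
               list(va, P_a[3, ], P_a[2, ]),
               list(ub, P_b[3, ], P_b[1, ]),
               list(vb, P_b[3, ], P_b[2, ]))
  n <- length(ua)
  S11 <- S12 <- S13 <- S22 <- S23 <- S33 <- numeric(n)
  b1 <- b2 <- b3 <- numeric(n)
  for (r in rows) {
    u <- r[[1]]; p3 <- r[[2]]; pk <- r[[3]]
    r1 <- u * p3[1] - pk[1]; r2 <- u * p3[2] - pk[2]
    r3 <- u * p3[3] - pk[3]; r4 <- u * p3[4] - pk[4]
    S11 <- S11 + r1 * r1; S12 <- S12 + r1 * r2; S13 <- S13 + r1 * r3
    S22 <- S22 + r2 * r2; S23 <- S23 + r2 * r3; S33 <- S33 + r3 * r3
    b1 <- b1 - r1 * r4; b2 <- b2 - r2 * r4; b3 <- b3 - r3 * r4
  }
  det <- S11 * (S22 * S33 - S23 * S23) - S12 * (S12 * S33 - S23 * S13) +
    S13 * (S12 * S23 - S22 * S13)
  valid <- valid & is.finite(det) & abs(det) > 1e-18
  det[!valid] <- 1
  x <- (b1 * (S22 * S33 - S23 * S23) - S12 * (b2 * S33 - S23 * b3) +
          S13 * (b2 * S23 - S22 * b3)) / det
  y <- (S11 * (b2 * S33 - b3 * S23) - b1 * (S12 * S33 - S23 * S13) +
          S13 * (S12 * b3 - b2 * S13)) / det
  z <- (S11 * (S22 * b3 - S23 * b2) - S12 * (S12 * b3 - b2 * S13) +
          b1 * (S12 * S23 - S22 * S13)) / det
  x[!valid] <- NA_real_; y[!valid] <- NA_real_; z[!valid] <- NA_real_
  pts <- array(c(x, y, z), dim = c(Tn, K, 3L))
  list(points = pts, valid = matrix(valid, Tn, K))
}

#' Zero-phase low-pass filtering of a 3D keypoint track
#'
#' Fourth-order zero-phase Butterworth (default cutoff 2 Hz) applied to each
#' coordinate of each keypoint. Invalid-sample gaps are linearly
#' interpolated first (gap length capped); a track whose gaps exceed the cap
#' is flagged via the `flagged` attribute.
#'
#' @param track `T x K x 3` array (NA = invalid sample).
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz.
#' @param order filter order.
#' @param max_gap longest invalid run that may be bridged, frames.
#' @return filtered `T x K x 3` array.
#' @export
lowpass_track <- function(track, fs = 30, cutoff = 2, order = 4L, max_gap = 10L) {
  d <- dim(track)
  out <- track
  flagged <- FALSE
  for (k in seq_len(d[2])) for (j in 1:3) {
    x <- track[, k, j]
    if (anyNA(x)) {
      filled <- fill_gaps_linear(x, max_gap = max_gap)
      if (isTRUE(attr(filled, "flagged"))) flagged <- TRUE
      x <- filled
    }
    out[, k, j] <- butter_lowpass_zerophase(x, fs = fs, cutoff = cutoff, order = order)
  }
  attr(out, "flagged") <- flagged
  out
}

# linear interpolation over NA runs; leading/trailing NAs take the nearest
# value; runs longer than max_gap are still bridged but flagged
fill_gaps_linear <- function(x, max_gap = 10L) {
  n <- length(x)
  ok <- which(!is.na(x))
  if (length(ok) < 2L) abort_invalid("track has < 2 valid samples")
  runs <- rle(is.na(x))
  flagged <- any(runs$lengths[runs$values] > max_gap)
  y <- stats::approx(ok, x[ok], xout = seq_len(n), rule = 2)$y
  attr(y, "flagged") <- flagged
  y
}

#' Joint angle at a vertex by the vector dot product
#'
#' Angle at `b` between the limb vectors `(a - b)` and `(c - b)`, via the
#' arccosine of the normalized dot product (clamped into `[-1, 1]` against
#' floating-point domain errors). Returned in degrees, in `[0, 180]`.
#'
#' @param a,b,c 3D points (or `N x 3` matrices for vectorised evaluation).
#' @return angle(s) in degrees; `NA` where a limb vector has zero length.
#' @export
joint_angle <- function(a, b, c) {
  as_pts <- function(x) {
    if (is.matrix(x) && ncol(x) == 3L && nrow(x) > 1L) return(unname(x))
    matrix(as.numeric(x), 1L, 3L)
  }
  scalar <- !(is.matrix(a) && ncol(a) == 3L && nrow(a) > 1L)
  a <- as_pts(a); b <- as_pts(b); c <- as_pts(c)
  u <- a - b; v <- c - b
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  cosang <- rowSums(u * v) / (nu * nv)
  cosang[nu == 0 | nv == 0] <- NA_real_
  ang <- unname(acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
  if (scalar) ang[1] else ang
}

#' Lower-limb joint angles from a 3D keypoint track
#'
#' Hip: angle at the hip between hip->shoulder and hip->knee. Knee: angle at
#' the knee between knee->hip and knee->ankle. Ankle: angle at the ankle
#' between ankle->knee and ankle->foot tip. These vertex conventions are a
#' declared choice of the package (the field names the joints, not the
#' triplets); they are configurable through `topology`.
#'
#' @param track `T x 33 x 3` keypoint array.
#' @param topology landmark index list, defaults to [pose_landmarks].
#' @return `T x 6` matrix, columns `hip_left, hip_right, knee_left,
#'   knee_right, ankle_left, ankle_right`, degrees.
#' @export
extract_joint_angles <- function(track, topology = pose_landmarks) {
  sides <- c("left", "right")
  cols <- list()
  pt <- function(name, side) track[, topology[[name]][[side]], , drop = FALSE][, 1, ]
  for (s in sides)
    cols[[paste0("hip_", s)]] <-
      joint_angle(pt("shoulder", s), pt("hip", s), pt("knee", s))
  for (s in sides)
    cols[[paste0("knee_", s)]] <-
      joint_angle(pt("hip", s), pt("knee", s), pt("ankle", s))
  for (s in sides)
    cols[[paste0("ankle_", s)]] <-
      joint_angle(pt("knee", s), pt("ankle", s), pt("foot_index", s))
  out <- do.call(cbind, cols[c("hip_left", "hip_right", "knee_left",
                               "knee_right", "ankle_left", "ankle_right")])
  out
}

#' Angular velocity and acceleration by central differences
#'
#' First and second temporal derivatives of each joint-angle column: central
#' differences at interior samples, one-sided at the ends; the acceleration
#' is the derivative of the velocity. Exact for linear (velocity) and
#' quadratic (acceleration) angle trajectories.
#'
#' @param angles `T x J` matrix of joint angles, degrees.
#' @param fs sampling rate, Hz.
#' @return list with `angle`, `velocity` (deg/s), `acceleration` (deg/s^2),
#'   and `features`: the `T x (3*J)` matrix ordered
#'   `<joint>_angle, <joint>_velocity, <joint>_acceleration` per joint
#'   column.
#' @export
angular_features <- function(angles, fs) {
  angles <- as.matrix(angles)
  if (nrow(angles) < 3L) abort_invalid("need >= 3 frames for derivatives")
  assert_scalar_number(fs, "fs", positive = TRUE)
  vel <- central_diff(angles, fs)
  acc <- central_diff(vel, fs)
  J <- ncol(angles)
  nm <- colnames(angles) %||% paste0("joint", seq_len(J))
  feats <- matrix(0, nrow(angles), 3L * J)
  fn <- character(3L * J)
  for (j in seq_len(J)) {
    feats[, 3L * j - 2L] <- angles[, j]
    feats[, 3L * j - 1L] <- vel[, j]
    feats[, 3L * j] <- acc[, j]
    fn[(3L * j - 2L):(3L * j)] <- paste0(nm[j], c("_angle", "_velocity", "_acceleration"))
  }
  colnames(feats) <- fn
  list(angle = angles, velocity = vel, acceleration = acc, features = feats)
}

central_diff <- function(x, fs) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- x * 0
  if (n >= 3L)
    d[2:(n - 1L), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2L), , drop = FALSE]) * fs / 2
  d[1L, ] <- (x[2L, ] - x[1L, ]) * fs
  d[n, ] <- (x[n, ] - x[n - 1L, ]) * fs
  d
}
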
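test_that("projection matrices follow P = K [R | t]", {
  K <- diag(3)
  cam <- camera_model(K, diag(3), c(0, 0, 0))
  P <- projection_matrix(cam)
  # point on the optical axis lands at the principal point (0, 0)
  px <- project_points(cam, rbind(c(0, 0, 1)))$px
  expect_equal(as.numeric(px), c(0, 0))
  # hand-built projection of a known point
  cams <- test_camera_pair()
  X <- c(0.4, -0.2, 3)
  h <- cams$cam_b$intrinsics %*%
    (cams$cam_b$rotation %*% X + cams$cam_b$translation)
  expect_equal(as.numeric(project_points(cams$cam_b, rbind(X))$px),
               as.numeric(h[1:2] / h[3]), tolerance = 1e-12)
  # projective scale invariance of the homogeneous projection
  Ps <- 3.7 * projection_matrix(cams$cam_a)
  hh <- Ps %*% c(X, 1)
  expect_equal(as.numeric(hh[1:2] / hh[3]),
               as.numeric(project_points(cams$cam_a, rbind(X))$px),
               tolerance = 1e-9)
  expect_error(camera_model(K, matrix(runif(9), 3, 3), rep(0, 3)), "orthonormal")
  expect_error(camera_model(matrix(1, 3, 3), diag(3), rep(0, 3)), "triangular")
})

test_that("DLT triangulation is exact on noiseless projections", {
  cams <- test_camera_pair()
  P_a <- projection_matrix(cams$cam_a); P_b <- projection_matrix(cams$cam_b)
  set.seed(1)
  for (i in 1:25) {
    X <- c(runif(1, -0.5, 0.5), runif(1, -0.5, 0.5), runif(1, 1.5, 3.5))
    pa <- project_points(cams$cam_a, rbind(X))$px[1, ]
    pb <- project_points(cams$cam_b, rbind(X))$px[1, ]
    tri <- triangulate_dlt(pa, pb, P_a, P_b)
    expect_true(tri$valid)
    expect_lt(max(abs(tri$point - X)), 1e-6)
    expect_lt(tri$residual_px, 1e-6)
  }
})

test_that("pixel noise yields positive residuals and millimetre-level error", {
  cams <- test_camera_pair()
  P_a <- projection_matrix(cams$cam_a); P_b <- projection_matrix(cams$cam_b)
  set.seed(2)
  errs <- replicate(50, {
    X <- c(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3), runif(1, 1.8, 2.2))
    pa <- project_points(cams$cam_a, rbind(X))$px[1, ] + rnorm(2, 0, 0.5)
    pb <- project_points(cams$cam_b, rbind(X))$px[1, ] + rnorm(2, 0, 0.5)
    tri <- triangulate_dlt(pa, pb, P_a, P_b)
    expect_gt(tri$residual_px, 0)
    sqrt(sum((tri$point - X)^2))
  })
  # 0.5 px noise at ~2 m with f = 1000 px: a few mm
  expect_lt(stats::median(errs), 0.01)
})

test_that("keypoints invalid in either view are not triangulated", {
  cams <- test_camera_pair()
  P_a <- projection_matrix(cams$cam_a); P_b <- projection_matrix(cams$cam_b)
  expect_false(triangulate_dlt(c(NA, 1), c(2, 3), P_a, P_b)$valid)
  kpa <- array(rnorm(2 * 2 * 2, 300, 10), c(2, 2, 2))
  kpb <- kpa + 5
  kpa[2, 1, 1] <- NA
  tri <- triangulate_tracks(kpa, kpb, P_a, P_b)
  expect_false(tri$valid[2, 1])
  expect_true(all(is.na(tri$points[2, 1, ])))
})

test_that("batched triangulation agrees with the single-point SVD solver", {
  cams <- test_camera_pair()
  P_a <- projection_matrix(cams$cam_a); P_b <- projection_matrix(cams$cam_b)
  set.seed(3)
  Tn <- 4; K <- 5
  X <- array(c(runif(Tn * K, -0.5, 0.5), runif(Tn * K, -0.5, 0.5),
               runif(Tn * K, 1.5, 3)), c(Tn * K, 3))
  pa <- project_points(cams$cam_a, X)$px + rnorm(2 * Tn * K, 0, 0.3)
  pb <- project_points(cams$cam_b, X)$px + rnorm(2 * Tn * K, 0, 0.3)
  kpa <- array(pa, c(Tn, K, 2)); kpb <- array(pb, c(Tn, K, 2))
  tri <- triangulate_tracks(kpa, kpb, P_a, P_b)
  # with pixel noise the homogeneous (SVD) and inhomogeneous (normal
  # equation) solutions minimise slightly different algebraic errors;
  # they agree to well under a millimetre at this noise level
  for (t in 1:Tn) for (k in 1:K) {
    ref <- triangulate_dlt(kpa[t, k, ], kpb[t, k, ], P_a, P_b)
    expect_lt(max(abs(tri$points[t, k, ] - ref$point)), 1e-3)
  }
  # and exactly (to solver precision) on noiseless projections
  pa0 <- project_points(cams$cam_a, X)$px; pb0 <- project_points(cams$cam_b, X)$px
  tri0 <- triangulate_tracks(array(pa0, c(Tn, K, 2)), array(pb0, c(Tn, K, 2)), P_a, P_b)
  for (t in 1:Tn) for (k in 1:K) {
    ref <- triangulate_dlt(pa0[(k - 1) * Tn + t, ], pb0[(k - 1) * Tn + t, ], P_a, P_b)
    expect_lt(max(abs(tri0$points[t, k, ] - ref$point)), 1e-8)
  }
})

test_that("track low-pass filtering is zero-phase with unit DC gain", {
  Tn <- 120
  tr <- array(5, c(Tn, 2, 3))
  out <- lowpass_track(tr, fs = 30, cutoff = 2)
  expect_lt(max(abs(out - 5)), 1e-9)
  # gaps are bridged before filtering
  tr[50:53, 1, 1] <- NA
  out <- lowpass_track(tr, fs = 30, cutoff = 2)
  expect_false(anyNA(out))
  expect_false(attr(out, "flagged"))
  tr[40:60, 2, 2] <- NA
  out <- lowpass_track(tr, fs = 30, cutoff = 2, max_gap = 10)
  expect_true(attr(out, "flagged"))
})

test_that("joint angles implement the clamped dot-product formula", {
  expect_equal(joint_angle(c(0, 0, 1), c(0, 0, 0), c(0, 0, -1)), 180)
  expect_equal(joint_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  set.seed(4)
  for (i in 1:50) {
    a <- rnorm(3); b <- rnorm(3); cc <- rnorm(3)
    u <- a - b; v <- cc - b
    ref <- acos(min(max(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1)) * 180 / pi
    expect_equal(joint_angle(a, b, cc), ref, tolerance = 1e-9)
    # invariance under global rotation + translation
    th <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3, 3)
    tr <- rnorm(3)
    expect_equal(joint_angle(Rz %*% a + tr, Rz %*% b + tr, Rz %*% cc + tr),
                 ref, tolerance = 1e-9)
  }
  expect_true(is.na(joint_angle(c(1, 1, 1), c(1, 1, 1), c(0, 0, 1))))
})

test_that("angular derivatives are exact for polynomial trajectories", {
  fs <- 14
  t <- seq(0, 3, by = 1 / fs)
  lin <- cbind(a = 5 + 3 * t)
  af <- angular_features(lin, fs)
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(af$velocity[interior, 1] - 3)), 1e-9)
  expect_lt(max(abs(af$acceleration[3:(length(t) - 2), 1])), 1e-9)
  quad <- cbind(a = 0.5 * 4 * t^2)
  af <- angular_features(quad, fs)
  deep <- 3:(length(t) - 2)   # acceleration needs central velocities on both sides
  expect_lt(max(abs(af$acceleration[deep, 1] - 4)), 1e-6)
  # sine: peak |velocity| ~ 2*pi*f*A within the discretization bound
  A <- 20; f0 <- 1
  sine <- cbind(a = A * sin(2 * pi * f0 * t))
  af <- angular_features(sine, fs)
  expect_equal(max(abs(af$velocity[, 1])), A * 2 * pi * f0, tolerance = 0.05)
  expect_error(angular_features(lin[1:2, , drop = FALSE], fs), "3 frames")
})

test_that("the 18-feature contract is ordered deterministically", {
  set.seed(5)
  ang <- matrix(runif(10 * 6, 0, 180), 10, 6,
                dimnames = list(NULL, c("hip_left", "hip_right", "knee_left",
                                        "knee_right", "ankle_left", "ankle_right")))
  af <- angular_features(ang, 14)
  expect_equal(ncol(af$features), 18L)
  expect_equal(colnames(af$features)[1:3],
               c("hip_left_angle", "hip_left_velocity", "hip_left_acceleration"))
  expect_equal(colnames(af$features)[16:18],
               c("ankle_right_angle", "ankle_right_velocity", "ankle_right_acceleration"))
  # angle columns pass through untouched
  expect_equal(af$features[, seq(1, 16, by = 3)], ang, ignore_attr = TRUE)
})

test_that("joint angle extraction uses the declared keypoint triplets", {
  Tn <- 3
  pts <- array(0, c(Tn, 33, 3))
  lm <- pose_landmarks
  # straight right leg along z: hip above knee above ankle
  pts[, lm$hip["right"], ] <- matrix(rep(c(0, 0, 1.0), each = Tn), Tn)
  pts[, lm$knee["right"], ] <- matrix(rep(c(0, 0, 0.5), each = Tn), Tn)
  pts[, lm$ankle["right"], ] <- matrix(rep(c(0, 0, 0.05), each = Tn), Tn)
  pts[, lm$foot_index["right"], ] <- matrix(rep(c(0, 0.2, 0.05), each = Tn), Tn)
  pts[, lm$shoulder["right"], ] <- matrix(rep(c(0, 0, 1.5), each = Tn), Tn)
  ang <- extract_joint_angles(pts)
  expect_equal(as.numeric(ang[1, "knee_right"]), 180)
  expect_equal(as.numeric(ang[1, "ankle_right"]), 90)
  expect_equal(as.numeric(ang[1, "hip_right"]), 180)
})
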
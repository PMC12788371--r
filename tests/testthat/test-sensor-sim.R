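test_that("cohort generation matches the stated sampling distributions", {
  coh <- make_cohort(23, seed = 7)
  expect_equal(nrow(coh), 23L)
  expect_true(all(coh$height > 0 & coh$weight > 0 & coh$foot_length > 0))
  expect_true(all(coh$foot_length < coh$height))
  expect_true(all(coh$waist_hip_ratio > 0.4 & coh$waist_hip_ratio < 1.5))
  # mean height over repeated seeds near 171.6
  means <- sapply(1:6, function(s) mean(make_cohort(23, seed = s)$height))
  expect_lt(abs(mean(means) - 171.6), 5)
  # determinism
  expect_identical(make_cohort(1, seed = 0), make_cohort(1, seed = 0))
  # law of large numbers on the height SD
  big <- make_cohort(1000, seed = 1)
  expect_lt(abs(sd(big$height) - 7.8) / 7.8, 0.10)
  expect_error(make_cohort(0), "n_subjects")
})

test_that("protocol specifications encode the study design", {
  expect_false(protocol_spec("one_leg")$is_dynamic)
  expect_false(protocol_spec("tandem")$is_dynamic)
  expect_true(protocol_spec("squat")$is_dynamic)
  expect_true(protocol_spec("walk_in_place")$is_dynamic)
  sq <- protocol_spec("squat")
  expect_equal(sq$duration_s, 90)
  expect_equal(sq$analysis_window_s, 80)
  expect_equal(sq$sway_params$period, 3)
  expect_error(protocol_spec("squat", duration_s = 10, analysis_window_s = 20),
               "analysis_window")
  expect_error(noise_model(gamma = -1), "gamma")
  expect_error(noise_model(sp_noise_rate = 2), "rates")
})

test_that("degenerate sway pins the one-leg CoP at the support foot center", {
  coh <- make_cohort(1, seed = 3)
  pr <- protocol_spec("one_leg", duration_s = 6, analysis_window_s = 4,
                      sway_params = list(sd_ml = 0, sd_ap = 0))
  tr <- simulate_trial(coh[1, ], pr, noise_model(), seed = 2)
  expect_lt(diff(range(tr$truth_cop$ml_mm)), 1e-9)
  expect_lt(diff(range(tr$truth_cop$ap_mm)), 1e-9)
  expect_equal(tr$truth_cop$ml_mm[1], 300)  # mat center
})

test_that("squat truth CoP has its dominant AP spectral peak at 1/3 Hz", {
  tr <- cached("squat_trial", function()
    sim_test_trial("squat", duration = 24, window = 18, seed = 8))
  ap <- tr$truth_cop$ap_mm
  ap <- ap - mean(ap)
  n <- length(ap)
  sp <- abs(fft(ap))^2
  freqs <- (seq_len(n) - 1) * 1000 / n
  keep <- freqs > 0.05 & freqs < 10
  expect_equal(freqs[keep][which.max(sp[keep])], 1 / 3, tolerance = 0.02)
})

test_that("walking with symmetric load alternation averages to the stance midpoint", {
  coh <- make_cohort(1, seed = 4)
  pr <- protocol_spec("walk_in_place", duration_s = 10, analysis_window_s = 8,
                      sway_params = list(sd_ml = 0, sd_ap = 0))
  tr <- simulate_trial(coh[1, ], pr, noise_model(), seed = 3)
  # integer number of cadence cycles: time-average ML sits at the midpoint
  sel <- tr$truth_cop$timestamp < 10
  expect_equal(mean(tr$truth_cop$ml_mm[sel]), 300, tolerance = 0.5)
  # and the ML range spans a substantial part of the stance width
  expect_gt(diff(range(tr$truth_cop$ml_mm)), 50)
})

test_that("dynamic protocols produce larger CoP ranges than static ones", {
  rng <- function(p) {
    tr <- cached(paste0("sep_", p), function()
      sim_test_trial(p, duration = 12, window = 8, seed = 21))
    max(diff(range(tr$truth_cop$ml_mm)), diff(range(tr$truth_cop$ap_mm)))
  }
  expect_gt(rng("squat"), max(rng("one_leg"), rng("tandem")))
  expect_gt(rng("walk_in_place"), max(rng("one_leg"), rng("tandem")))
})

test_that("ideal rendering conserves load and tracks the analytic centroid", {
  tr <- cached("ideal_tandem", function()
    sim_test_trial("tandem", duration = 16, window = 10, seed = 5))
  ps <- stitch_stream(tr$raw_tactile)
  # conservation: total rendered pressure proportional to instantaneous load
  loads <- approx(tr$truth_cop$timestamp, tr$total_load, ps$timestamps, rule = 2)$y
  ratio <- rowSums(ps$frames) / loads
  expect_lt((max(ratio) - min(ratio)) / mean(ratio), 0.01)
  # centroid consistency across the full trial
  w <- wma_cop_sequence(ps)
  tml <- approx(tr$truth_cop$timestamp, tr$truth_cop$ml_mm, w$timestamp, rule = 2)$y
  tap <- approx(tr$truth_cop$timestamp, tr$truth_cop$ap_mm, w$timestamp, rule = 2)$y
  expect_lt(max(abs(w$ml_mm - tml)), 600 / 64)
  expect_lt(max(abs(w$ap_mm - tap)), 800 / 64)
})

test_that("gamma compression biases the centroid toward the lighter foot", {
  coh <- make_cohort(1, seed = 4)
  pr <- protocol_spec("walk_in_place", duration_s = 6, analysis_window_s = 4,
                      sway_params = list(sd_ml = 0, sd_ap = 0))
  tr <- simulate_trial(coh[1, ], pr, noise_model(), seed = 9)
  ideal <- stitch_stream(tr$raw_tactile)
  gam <- stitch_stream(render_pressure_sequence(tr, noise_model(gamma = 0.7),
                                                tr$geometry, seed = tr$seed))
  wi <- wma_cop_sequence(ideal); wg <- wma_cop_sequence(gam)
  # frames where the right foot carries more load: truth ML right of center;
  # gamma < 1 flattens the pressure contrast, pulling the centroid back
  # toward the lighter (left) foot, i.e. toward the midline
  off <- wi$ml_mm - 300
  pull <- wg$ml_mm - wi$ml_mm
  loaded <- abs(off) > 20
  expect_true(all(sign(pull[loaded]) == -sign(off[loaded])))
})

test_that("salt-and-pepper noise flips cells at the configured rate", {
  tr <- cached("ideal_tandem", function()
    sim_test_trial("tandem", duration = 16, window = 10, seed = 5))
  noisy <- render_pressure_sequence(tr, noise_model(sp_noise_rate = 0.01),
                                    tr$geometry, seed = tr$seed)
  clean <- render_pressure_sequence(tr, noise_model(), tr$geometry, seed = tr$seed)
  frac <- mean(do.call(cbind, noisy$modules) != do.call(cbind, clean$modules))
  expect_lt(frac, 0.02)   # at most ~2x the nominal 1% rate
  expect_gt(frac, 0.005)
})

test_that("identical inputs and seed reproduce the trial bit for bit", {
  coh <- make_cohort(1, seed = 6)
  pr <- protocol_spec("one_leg", duration_s = 6, analysis_window_s = 4)
  n <- default_sensor_defects(3)
  t1 <- simulate_trial(coh[1, ], pr, n, seed = 42)
  t2 <- simulate_trial(coh[1, ], pr, n, seed = 42)
  expect_identical(t1$truth_cop, t2$truth_cop)
  expect_identical(t1$raw_tactile$modules, t2$raw_tactile$modules)
  expect_identical(t1$keypoints_2d$cam_a$px, t2$keypoints_2d$cam_a$px)
})

test_that("skeleton projection emits 33 keypoints per frame per view", {
  tr <- cached("ideal_tandem", function()
    sim_test_trial("tandem", duration = 16, window = 10, seed = 5))
  kp <- tr$keypoints_2d
  expect_equal(dim(kp$cam_a$px)[2:3], c(33L, 2L))
  expect_equal(dim(kp$cam_b$px)[2:3], c(33L, 2L))
  expect_true(all(kp$cam_a$valid))
  # noiseless projections triangulate back to the 3D skeleton
  rig <- default_stereo_rig()
  tri <- triangulate_tracks(kp$cam_a$px, kp$cam_b$px,
                            projection_matrix(rig$cam_a),
                            projection_matrix(rig$cam_b))
  expect_lt(max(abs(tri$points - tr$skeleton$points), na.rm = TRUE), 1e-6)
})

test_that("squat skeleton knee angle oscillates at the squat period", {
  tr <- cached("squat_trial", function()
    sim_test_trial("squat", duration = 24, window = 18, seed = 8))
  knee <- tr$truth_kinematics[, "knee_left"]
  knee <- knee - mean(knee)
  n <- length(knee)
  sp <- abs(fft(knee))^2
  freqs <- (seq_len(n) - 1) * 30 / n
  keep <- freqs > 0.05 & freqs < 5
  expect_equal(freqs[keep][which.max(sp[keep])], 1 / 3, tolerance = 0.02)
  # knee flexes well away from straight during the squat
  expect_lt(min(tr$truth_kinematics[, "knee_left"]), 140)
})

test_that("the default schedule is 4 tasks x 2 repetitions", {
  sched <- protocol_schedule()
  expect_equal(nrow(sched), 8L)
  expect_equal(sort(unique(sched$protocol_id)),
               sort(c("one_leg", "tandem", "squat", "walk_in_place")))
  expect_true(all(table(sched$protocol_id) == 2))
})
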
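# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# one simulated trial (short, quiet warnings about edge clipping)
sim_test_trial <- function(protocol = "tandem", duration = 20, window = 10,
                           noise = noise_model(), seed = 5, subject_seed = 7,
                           kp_noise_px = 0) {
  coh <- make_cohort(1, seed = subject_seed)
  pr <- protocol_spec(protocol, duration_s = duration, analysis_window_s = window)
  suppressWarnings(simulate_trial(coh[1, ], pr, noise, seed = seed,
                                  kp_noise_px = kp_noise_px))
}

# a small set of synchronized records for model tests: 2 subjects x 4 protocols
model_test_records <- function() {
  cached("model_records", function() {
    coh <- make_cohort(2, seed = 7)
    noise <- default_sensor_defects(1)
    recs <- list(); k <- 0
    for (s in 1:2) for (p in c("one_leg", "tandem", "squat", "walk_in_place")) {
      k <- k + 1
      pr <- protocol_spec(p, duration_s = 16, analysis_window_s = 10)
      tr <- suppressWarnings(simulate_trial(coh[s, ], pr, noise, seed = 100 + k))
      recs[[k]] <- assemble_trial(tr)
    }
    recs
  })
}

# a fake lightweight trial record with arbitrary T (tactile bytes all zero)
fake_record <- function(T, subject_id = "S01", protocol_id = 1L) {
  build_trial_record(
    tactile_gray8 = matrix(0L, T, 64 * 64),
    tactile_wma_cop = matrix(stats::rnorm(T * 2, 300, 10), T, 2),
    truth_cop = matrix(stats::rnorm(T * 2, 300, 10), T, 2),
    angular_features = matrix(stats::rnorm(T * 18), T, 18),
    timestamps = seq(0, by = 1 / 14, length.out = T),
    subject = list(subject_id = subject_id, gender = "M", weight = 70,
                   lean_mass = 55, upper_limb_length = 75,
                   lower_limb_length = 82, waist_hip_ratio = 0.88),
    settings = list(protocol_id = protocol_id, sensor_width_mm = 600,
                    sensor_length_mm = 800))
}

# two offset test cameras in general position
test_camera_pair <- function() {
  K <- matrix(c(1000, 0, 0, 0, 1000, 0, 640, 360, 1), 3, 3)
  R1 <- diag(3)
  th <- 0.25
  R2 <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  list(cam_a = camera_model(K, R1, c(0.2, 0, 0)),
       cam_b = camera_model(K, R2, c(-0.3, 0.05, 0.1)))
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
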
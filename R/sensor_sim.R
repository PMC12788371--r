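#' Generate a synthetic study cohort
#'
#' Draws subject profiles from normal distributions matched to a young
#' healthy-adult cohort (age 22.7 +/- 1.6 y, height 171.6 +/- 7.8 cm, weight
#' 73.4 +/- 13.5 kg, ~15:8 male:female), truncated to positive values.
#' Segment lengths, foot dimensions, lean mass and waist-hip ratio are
#' derived from height/weight/gender with standard anthropometric ratios
#' plus individual variation.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed; the cohort is a pure function of it.
#' @return data.frame with one row per subject: `subject_id`, `gender`,
#'   `age`, `height` (cm), `weight` (kg), `lean_mass` (kg),
#'   `upper_limb_length` (cm), `lower_limb_length` (cm), `waist_hip_ratio`,
#'   `foot_length` (cm), `foot_width` (cm), `dominant_foot`.
#' @export
make_cohort <- function(n_subjects, seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    abort_invalid("n_subjects must be >= 1")
  n <- as.integer(n_subjects)
  with_seed(seed, {
    rtnorm <- function(n, mean, sd, lo = 1e-6, hi = Inf) {
      x <- stats::rnorm(n, mean, sd)
      bad <- which(x <= lo | x >= hi)
      while (length(bad)) {
        x[bad] <- stats::rnorm(length(bad), mean, sd)
        bad <- bad[x[bad] <= lo | x[bad] >= hi]
      }
      x
    }
    gender <- ifelse(stats::runif(n) < 15 / 23, "M", "F")
    height <- rtnorm(n, 171.6, 7.8, lo = 120)
    weight <- rtnorm(n, 73.4, 13.5, lo = 35)
    age <- rtnorm(n, 22.7, 1.6, lo = 18)
    lean_frac <- ifelse(gender == "M", 0.84, 0.74) * rtnorm(n, 1, 0.04)
    whr <- ifelse(gender == "M", rtnorm(n, 0.88, 0.04), rtnorm(n, 0.77, 0.04))
    whr <- pmin(pmax(whr, 0.45), 1.45)
    foot_len <- 0.152 * height * rtnorm(n, 1, 0.03)
    data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      gender = gender,
      age = age,
      height = height,
      weight = weight,
      lean_mass = lean_frac * weight,
      upper_limb_length = 0.44 * height * rtnorm(n, 1, 0.02),
      lower_limb_length = 0.48 * height * rtnorm(n, 1, 0.02),
      waist_hip_ratio = whr,
      foot_length = foot_len,
      foot_width = 0.37 * foot_len * rtnorm(n, 1, 0.05),
      dominant_foot = ifelse(stats::runif(n) < 0.85, "R", "L"),
      stringsAsFactors = FALSE)
  })
}

#' Balance-protocol specification
#'
#' Four protocols: static one-leg and tandem stance, dynamic squat (one
#' repetition per 3 s) and walking-in-place (default cadence 1 Hz). Trials
#' last 90 s; analysis uses the middle 80 s. Sway trajectory parameters
#' default to clinically plausible magnitudes (the source protocols specify
#' none): static sway is 1 Hz low-passed Gaussian noise with protocol-
#' specific SD, the squat adds a deterministic AP oscillation at 1/3 Hz and
#' walking-in-place alternates foot loading at the cadence.
#'
#' @param protocol_id one of `"one_leg"`, `"tandem"`, `"squat"`,
#'   `"walk_in_place"`.
#' @param duration_s trial length, seconds.
#' @param analysis_window_s analysed middle window, seconds.
#' @param sway_params optional overrides of the per-protocol defaults
#'   (amplitudes mm, frequencies Hz, cadence Hz).
#' @return `protocol_spec` object; `is_dynamic` is `TRUE` for squat and
#'   walking-in-place.
#' @export
protocol_spec <- function(protocol_id = c("one_leg", "tandem", "squat", "walk_in_place"),
                          duration_s = 90, analysis_window_s = 80,
                          sway_params = list()) {
  protocol_id <- match.arg(protocol_id)
  assert_scalar_number(duration_s, "duration_s", positive = TRUE)
  assert_scalar_number(analysis_window_s, "analysis_window_s", positive = TRUE)
  if (analysis_window_s > duration_s)
    abort_invalid("analysis_window_s must not exceed duration_s")
  defaults <- switch(protocol_id,
    one_leg = list(sd_ml = 8, sd_ap = 10, lp_cutoff = 1),
    tandem = list(sd_ml = 12, sd_ap = 6, lp_cutoff = 1),
    squat = list(sd_ml = 4, sd_ap = 4, lp_cutoff = 1, ap_amp = 100, period = 3,
                 load_mod = 0.15, depth_frac = 0.15),
    walk_in_place = list(sd_ml = 5, sd_ap = 5, lp_cutoff = 1, cadence = 1,
                         share_amp = 0.45, load_mod = 0.1, lift_frac = 0.06))
  sp <- utils::modifyList(defaults, sway_params)
  structure(list(protocol_id = protocol_id,
                 is_dynamic = protocol_id %in% c("squat", "walk_in_place"),
                 duration_s = duration_s,
                 analysis_window_s = analysis_window_s,
                 sway_params = sp),
            class = "protocol_spec")
}

#' Sensor defect model
#'
#' Describes how the ideal pressure field is corrupted on its way through
#' the piezoresistive modules, applied in this order: response nonlinearity
#' (`measured = sat * (true/sat)^gamma`), per-module gain and baseline
#' offset (plus slow drift), salt-and-pepper cell noise, and whole-frame
#' drops. `noise_model()` with no arguments is the ideal linear sensor.
#'
#' @param module_baseline per-module offsets, kPa (length 4, recycled).
#' @param module_gain per-module multipliers (length 4, recycled).
#' @param gamma nonlinearity exponent (> 0; 1 = linear).
#' @param sp_noise_rate probability per cell per frame of a salt/pepper hit.
#' @param drop_rate probability a tactile frame is dropped.
#' @param drift_rate baseline units (kPa) per minute.
#' @export
noise_model <- function(module_baseline = rep(0, 4), module_gain = rep(1, 4),
                        gamma = 1, sp_noise_rate = 0, drop_rate = 0,
                        drift_rate = 0) {
  assert_scalar_number(gamma, "gamma", positive = TRUE)
  for (r in list(sp_noise_rate = sp_noise_rate, drop_rate = drop_rate)) {
    if (r < 0 || r > 1) abort_invalid("rates must lie in [0, 1]")
  }
  structure(list(module_baseline = rep_len(as.numeric(module_baseline), 4L),
                 module_gain = rep_len(as.numeric(module_gain), 4L),
                 gamma = gamma, sp_noise_rate = sp_noise_rate,
                 drop_rate = drop_rate, drift_rate = drift_rate),
            class = "noise_model")
}

#' The default noisy sensor used for model benchmarking
#'
#' Nonlinear response (`gamma = 0.7`) with +/-20% module gain spread, small
#' per-module baselines, sparse salt-and-pepper hits and occasional frame
#' drops.
#'
#' @param seed seed used to draw the module gains/baselines.
#' @export
default_sensor_defects <- function(seed = 1L) {
  with_seed(derive_seed(seed, "sensor-defects"), {
    noise_model(module_baseline = stats::runif(4, 0.1, 0.4),
                module_gain = stats::runif(4, 0.8, 1.2),
                gamma = 0.7, sp_noise_rate = 0.002, drop_rate = 0.02,
                drift_rate = 0.01)
  })
}

#' Default stereo camera rig for the synthetic capture volume
#'
#' Two pinhole cameras ~2.2 m in front of the mat, 0.6 m apart, 1.2 m high,
#' both aimed at a point 1 m above the mat center. Intrinsics emulate a
#' 1080p RGB camera.
#'
#' @return list with `cam_a` and `cam_b` ([camera_model()] objects).
#' @export
default_stereo_rig <- function() {
  K <- matrix(c(1400, 0, 0, 0, 1400, 0, 960, 540, 1), 3, 3)
  look_at <- function(C, target) {
    z <- target - C; z <- z / sqrt(sum(z^2))
    up <- c(0, 0, 1)
    x <- c(z[2] * up[3] - z[3] * up[2], z[3] * up[1] - z[1] * up[3],
           z[1] * up[2] - z[2] * up[1])
    x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    R <- rbind(x, y, z)
    camera_model(K, R, -R %*% C)
  }
  target <- c(0, 0, 1.0)
  list(cam_a = look_at(c(-0.3, 2.2, 1.2), target),
       cam_b = look_at(c(0.3, 2.2, 1.2), target))
}

# --- internal simulator machinery ------------------------------------------

# population SD of the zero-phase low-pass applied to unit white noise
# (sqrt of the impulse-response energy), cached per (fs, cutoff)
sway_filter_sd <- local({
  cache <- new.env(parent = emptyenv())
  function(fs, cutoff) {
    key <- paste(fs, cutoff)
    if (is.null(cache[[key]])) {
      imp <- c(1, numeric(8L * fs))
      h <- butter_lowpass_zerophase(imp, fs = fs, cutoff = cutoff, order = 2L)
      cache[[key]] <- sqrt(sum(h^2))
    }
    cache[[key]]
  }
})

# low-passed Gaussian sway scaled so its *population* SD equals sd_target
# (sample-SD rescaling would inflate short windows of the slow process)
sway_noise <- function(n, fs, sd_target, cutoff = 1) {
  if (sd_target <= 0 || n < 16L) return(numeric(n))
  x <- butter_lowpass_zerophase(stats::rnorm(n), fs = fs, cutoff = cutoff, order = 2L)
  x / sway_filter_sd(fs, cutoff) * sd_target
}

# foot centers (ml, ap) in mm for a subject/protocol; row = left, right
foot_centers <- function(subject, protocol, geometry) {
  fl <- subject$foot_length * 10  # cm -> mm
  fw <- subject$foot_width * 10
  cx <- geometry$width_mm / 2
  cy <- geometry$length_mm / 2
  dom <- subject$dominant_foot
  switch(protocol$protocol_id,
    one_leg = {
      m <- matrix(c(cx, cy, cx, cy), 2, 2, byrow = TRUE)
      rownames(m) <- c("left", "right"); m
    },
    tandem = {
      # dominant foot in front, heel-to-toe along AP
      front <- c(cx, cy + fl / 2 + 8)
      back <- c(cx, cy - fl / 2 - 8)
      m <- if (dom == "R") rbind(left = back, right = front)
      else rbind(left = front, right = back)
      m
    },
    rbind(left = c(cx - (fw + 110) / 2, cy),   # squat / walking: hip-width stance
          right = c(cx + (fw + 110) / 2, cy)))
}

# per-foot load shares and total load (kgf) over the 1000 Hz time base
load_schedule <- function(t, protocol, weight, dominant = "R") {
  sp <- protocol$sway_params
  n <- length(t)
  total <- rep(weight, n)
  share_left <- rep(0.5, n)
  switch(protocol$protocol_id,
    one_leg = {
      share_left <- rep(if (dominant == "L") 1 else 0, n)
    },
    tandem = NULL,
    squat = {
      total <- weight * (1 + sp$load_mod * sin(2 * pi * t / sp$period))
    },
    walk_in_place = {
      share_left <- 0.5 + sp$share_amp * sin(2 * pi * sp$cadence * t)
      total <- weight * (1 + sp$load_mod * sin(2 * pi * 2 * sp$cadence * t))
    })
  cbind(left = total * share_left, right = total * (1 - share_left))
}

#' Simulate one synthetic balance trial
#'
#' Generates the analytic ground truth and the raw multi-rate sensor
#' streams for one subject performing one protocol: ground-truth CoP at
#' 1000 Hz (the load-weighted centroid of the simulated foot loads), the raw
#' tactile stream at ~14 Hz with the requested defect model, 20 no-load
#' calibration frames, a 33-keypoint skeleton at 30 Hz projected into both
#' stereo views, and the protocol-consistent joint-angle tracks. Stream
#' starts are jittered uniformly within one device frame interval to emulate
#' manual triggering.
#'
#' @param subject one row of [make_cohort()].
#' @param protocol a [protocol_spec()].
#' @param noise a [noise_model()].
#' @param geometry a [sensor_geometry()].
#' @param seed integer seed; identical inputs + seed give identical trials.
#' @param cameras stereo rig from [default_stereo_rig()].
#' @param fs_truth,fs_tactile,fs_camera native sampling rates, Hz.
#' @param kp_noise_px Gaussian pixel noise SD added to the 2D keypoints.
#' @return `synthetic_trial` object.
#' @export
simulate_trial <- function(subject, protocol, noise = noise_model(),
                           geometry = sensor_geometry(), seed = 1L,
                           cameras = default_stereo_rig(),
                           fs_truth = 1000, fs_tactile = 14, fs_camera = 30,
                           kp_noise_px = 0) {
  stopifnot(inherits(protocol, "protocol_spec"), inherits(noise, "noise_model"))
  if (!is_sensor_geometry(geometry)) abort_invalid("geometry must be a sensor_geometry")
  if (protocol$duration_s <= 0) abort_invalid("duration must be > 0")
  subject <- as.list(subject)
  dur <- protocol$duration_s
  sp <- protocol$sway_params

  t_truth <- seq(0, dur, by = 1 / fs_truth)
  n <- length(t_truth)
  centers <- foot_centers(subject, protocol, geometry)
  loads <- load_schedule(t_truth, protocol, subject$weight, subject$dominant_foot)

  sway <- with_seed(derive_seed(seed, "sway"), {
    cbind(ml = sway_noise(n, fs_truth, sp$sd_ml, sp$lp_cutoff),
          ap = sway_noise(n, fs_truth, sp$sd_ap, sp$lp_cutoff))
  })
  det_ap <- if (protocol$protocol_id == "squat")
    sp$ap_amp * ((1 - cos(2 * pi * t_truth / sp$period)) / 2 - 0.5) else 0

  # per-foot CoP: foot center + shared body sway (+ deterministic component)
  foot_cop <- array(0, dim = c(n, 2L, 2L), dimnames = list(NULL, c("left", "right"), c("ml", "ap")))
  for (f in 1:2) {
    foot_cop[, f, "ml"] <- centers[f, 1] + sway[, "ml"]
    foot_cop[, f, "ap"] <- centers[f, 2] + sway[, "ap"] + det_ap
  }
  tot <- loads[, 1] + loads[, 2]
  truth_ml <- (loads[, 1] * foot_cop[, 1, "ml"] + loads[, 2] * foot_cop[, 2, "ml"]) / tot
  truth_ap <- (loads[, 1] * foot_cop[, 1, "ap"] + loads[, 2] * foot_cop[, 2, "ap"]) / tot

  clamped <- truth_ml < 0 | truth_ml > geometry$width_mm |
    truth_ap < 0 | truth_ap > geometry$length_mm
  if (any(clamped)) {
    warning("truth CoP clamped to the mat extent for some samples")
    truth_ml <- pmin(pmax(truth_ml, 0), geometry$width_mm)
    truth_ap <- pmin(pmax(truth_ap, 0), geometry$length_mm)
  }

  trial <- structure(list(
    subject = subject, protocol = protocol, noise = noise,
    geometry = geometry, seed = seed,
    truth_cop = data.frame(timestamp = t_truth, ml_mm = truth_ml, ap_mm = truth_ap),
    total_load = tot, foot_cop = foot_cop, foot_load = loads,
    meta = list(clamped_samples = sum(clamped))), class = "synthetic_trial")

  trial$skeleton <- simulate_skeleton(trial, fs_camera)
  kp <- simulate_skeleton_and_project(trial, cameras$cam_a, cameras$cam_b,
                                      noise_px = kp_noise_px,
                                      seed = derive_seed(seed, "kp"))
  trial$keypoints_2d <- kp
  trial$truth_kinematics <- extract_joint_angles(trial$skeleton$points)

  trial$raw_tactile <- render_pressure_sequence(trial, noise, geometry,
                                                fs_tactile = fs_tactile,
                                                seed = derive_seed(seed, "tactile"))
  trial$no_load_frames <- render_no_load_frames(noise, geometry, n_frames = 20L,
                                                seed = derive_seed(seed, "baseline"))
  trial
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> %s / %s, %.0f s, %d tactile frames\n",
              x$subject$subject_id, x$protocol$protocol_id,
              x$protocol$duration_s, length(x$raw_tactile$timestamps)))
  invisible(x)
}

# pressure scale (kPa per unit of normalised blob mass): chosen so that a
# 73 kg reference subject in double stance peaks at ~60% of the 14 kPa
# saturation. Computed once from the discretised reference blob.
pressure_scale_kpa <- local({
  cache <- new.env(parent = emptyenv())
  function(geometry) {
    key <- paste(geometry$pitch_length_mm, geometry$pitch_width_mm)
    if (!is.null(cache[[key]])) return(cache[[key]])
    sig_ap <- 260 / 4.5; sig_ml <- 96 / 3.5     # reference foot blob, mm
    rmax <- 2.2
    ya <- seq(-3 * sig_ap, 3 * sig_ap, by = geometry$pitch_length_mm)
    xa <- seq(-3 * sig_ml, 3 * sig_ml, by = geometry$pitch_width_mm)
    q <- outer(ya^2 / sig_ap^2, xa^2 / sig_ml^2, `+`)
    b <- pmax(exp(-q / 2) - exp(-rmax^2 / 2), 0)
    peak_frac <- max(b) / sum(b)
    cache[[key]] <- 0.6 * 14 / (73 / 2 * peak_frac)
    cache[[key]]
  }
})

# render one foot blob into the frame matrix (64 x 64), returns TRUE if the
# blob support was clipped by the mat edge
add_foot_blob <- function(frame, ml, ap, load_kgf, fl_mm, fw_mm, geometry, scale) {
  sig_ml <- fw_mm / 3.5; sig_ap <- fl_mm / 4.5
  rmax <- 2.2
  rows <- which(abs(grid_coord(seq_len(geometry$n_rows), geometry$pitch_length_mm, FALSE) - ap)
                <= rmax * sig_ap)
  cols <- which(abs(grid_coord(seq_len(geometry$n_cols), geometry$pitch_width_mm, FALSE) - ml)
                <= rmax * sig_ml)
  clipped <- (ap - rmax * sig_ap < geometry$pitch_length_mm) ||
    (ap + rmax * sig_ap > geometry$length_mm) ||
    (ml - rmax * sig_ml < geometry$pitch_width_mm) ||
    (ml + rmax * sig_ml > geometry$width_mm)
  if (!length(rows) || !length(cols)) return(list(frame = frame, clipped = TRUE))
  ya <- grid_coord(rows, geometry$pitch_length_mm, FALSE)
  xa <- grid_coord(cols, geometry$pitch_width_mm, FALSE)
  q <- outer((ya - ap)^2 / sig_ap^2, (xa - ml)^2 / sig_ml^2, `+`)
  b <- pmax(exp(-q / 2) - exp(-rmax^2 / 2), 0)
  s <- sum(b)
  # total rendered mass is exactly load * scale (conservation), and the peak
  # cell sits near load * scale * cell_area / (2 pi sig_ap sig_ml)
  if (s > 0) frame[rows, cols] <- frame[rows, cols] + load_kgf * scale * b / s
  list(frame = frame, clipped = clipped)
}

#' Render the raw tactile stream for a simulated trial
#'
#' Each foot is rendered as a truncated anisotropic Gaussian pressure blob
#' centred on that foot's instantaneous CoP and scaled by its instantaneous
#' load, then corrupted by the defect model in order: gamma nonlinearity,
#' per-module gain/offset (+ drift), salt-and-pepper noise, frame drops. In
#' ideal linear mode the pressure-weighted centroid of the stitched frame
#' equals the analytic CoP to within half a cell pitch.
#'
#' @param trial a [simulate_trial()] result (or its truth/loads core).
#' @param noise a [noise_model()].
#' @param geometry a [sensor_geometry()].
#' @param fs_tactile nominal tactile frame rate, Hz.
#' @param seed seed for the stochastic defect draws.
#' @return `raw_tactile_stream`: list with `modules` (four `T x 1024`
#'   matrices, row-major tile order), `timestamps`, `expected_timestamps`
#'   (pre-drop grid), `dropped`, `start_jitter_s`, `clipped_frames`.
#' @export
render_pressure_sequence <- function(trial, noise = trial$noise,
                                     geometry = trial$geometry,
                                     fs_tactile = 14, seed = trial$seed) {
  sat <- 14  # kPa sensor saturation
  scale <- pressure_scale_kpa(geometry)
  fl <- trial$subject$foot_length * 10; fw <- trial$subject$foot_width * 10
  t_truth <- trial$truth_cop$timestamp
  with_seed(derive_seed(seed, "render"), {
    jitter <- stats::runif(1, 0, 1 / fs_tactile)
    tt <- seq(jitter, max(t_truth), by = 1 / fs_tactile)
    Tn <- length(tt)
    n_cells <- geometry$n_rows * geometry$n_cols
    frames <- matrix(0, Tn, n_cells)
    clipped <- logical(Tn)
    # resample the per-foot schedules onto the tactile grid once
    load_t <- sapply(1:2, function(f)
      stats::approx(t_truth, trial$foot_load[, f], tt, rule = 2)$y)
    ml_t <- sapply(1:2, function(f)
      stats::approx(t_truth, trial$foot_cop[, f, "ml"], tt, rule = 2)$y)
    ap_t <- sapply(1:2, function(f)
      stats::approx(t_truth, trial$foot_cop[, f, "ap"], tt, rule = 2)$y)
    for (k in seq_len(Tn)) {
      fr <- matrix(0, geometry$n_rows, geometry$n_cols)
      for (f in 1:2) {
        if (load_t[k, f] <= 1e-9) next
        r <- add_foot_blob(fr, ml_t[k, f], ap_t[k, f], load_t[k, f], fl, fw,
                           geometry, scale)
        fr <- r$frame; clipped[k] <- clipped[k] || r$clipped
      }
      frames[k, ] <- as.vector(pmin(fr, sat))
    }
    if (any(clipped)) warning(sprintf("%d frames had foot blobs clipped at the mat edge",
                                      sum(clipped)))
    corrupted <- apply_sensor_defects(frames, tt, noise, geometry, sat)
    keep <- rep(TRUE, Tn)
    if (noise$drop_rate > 0 && Tn > 2L) {
      keep <- stats::runif(Tn) >= noise$drop_rate
      keep[c(1L, Tn)] <- TRUE  # retain endpoints so gaps are interpolatable
    }
    modules <- lapply(seq_len(4L), function(m) {
      idx <- module_cell_index(geometry, m)
      corrupted[keep, idx, drop = FALSE]
    })
    structure(list(modules = modules, timestamps = tt[keep],
                   expected_timestamps = tt, dropped = which(!keep),
                   start_jitter_s = jitter, clipped_frames = sum(clipped),
                   geometry = geometry),
              class = "raw_tactile_stream")
  })
}

# column-major cell indices of module m (row-major tile order) in the
# stitched frame vector
module_cell_index <- function(geometry, m) {
  ms <- geometry$module_shape; tl <- geometry$module_tiling
  tr <- (m - 1L) %/% tl[2] + 1L; tc <- (m - 1L) %% tl[2] + 1L
  rows <- (tr - 1L) * ms[1] + seq_len(ms[1])
  cols <- (tc - 1L) * ms[2] + seq_len(ms[2])
  as.vector(outer(rows, (cols - 1L) * geometry$n_rows, `+`))
}

# defect chain on a T x n_cells frame matrix (stitched layout)
apply_sensor_defects <- function(frames, timestamps, noise, geometry, sat = 14) {
  out <- frames
  if (noise$gamma != 1) out <- sat * (out / sat)^noise$gamma
  cell_mod <- integer(ncol(out))
  for (m in 1:4) cell_mod[module_cell_index(geometry, m)] <- m
  gain <- noise$module_gain[cell_mod]
  base <- noise$module_baseline[cell_mod]
  out <- sweep(out, 2L, gain, `*`)
  out <- sweep(out, 2L, base, `+`)
  if (noise$drift_rate != 0)
    out <- out + timestamps / 60 * noise$drift_rate  # recycles down columns (rows = time)
  if (noise$sp_noise_rate > 0) {
    n_hit <- stats::rbinom(1L, length(out), noise$sp_noise_rate)
    if (n_hit > 0) {
      hit <- sample.int(length(out), n_hit)
      out[hit] <- ifelse(stats::runif(n_hit) < 0.5, 0, sat)
    }
  }
  pmin(pmax(out, 0), sat)
}

# no-load calibration frames: defect chain applied to an all-zero field
render_no_load_frames <- function(noise, geometry, n_frames = 20L, seed = 1L) {
  with_seed(seed, {
    n_cells <- geometry$n_rows * geometry$n_cols
    frames <- matrix(0, n_frames, n_cells)
    ts <- seq(0, by = 1 / 14, length.out = n_frames)
    frames <- apply_sensor_defects(frames, ts, noise, geometry)
    pressure_sequence(frames, ts, stage = "raw", geometry = geometry)
  })
}

#' Stitch a raw module stream into a pressure sequence
#' @param stream a `raw_tactile_stream`.
#' @return raw-stage [pressure_sequence()] of stitched 64 x 64 frames.
#' @export
stitch_stream <- function(stream) {
  g <- stream$geometry
  Tn <- length(stream$timestamps)
  frames <- matrix(0, Tn, g$n_rows * g$n_cols)
  for (m in 1:4) frames[, module_cell_index(g, m)] <- stream$modules[[m]]
  pressure_sequence(frames, stream$timestamps, stage = "raw", geometry = g)
}

# --- skeleton ---------------------------------------------------------------

# world coords: x = ML (m, 0 at mat center), y = AP (m, 0 at mat center,
# cameras at +y), z = up
mat_to_world <- function(ml_mm, ap_mm, geometry) {
  cbind((ml_mm - geometry$width_mm / 2) / 1000,
        (ap_mm - geometry$length_mm / 2) / 1000, 0)
}

# 33-keypoint skeleton track at the camera rate, consistent with the
# protocol (squat: knee flexion phase-locked to the AP CoP oscillation;
# walking: alternating knee flexion/foot lift at the cadence)
simulate_skeleton <- function(trial, fs_camera = 30) {
  g <- trial$geometry
  sub <- trial$subject
  sp <- trial$protocol$sway_params
  h <- sub$height / 100
  L1 <- 0.245 * h; L2 <- 0.246 * h  # thigh, shank (m)
  ankle_h <- 0.039 * h
  t <- seq(0, trial$protocol$duration_s, by = 1 / fs_camera)
  Tn <- length(t)
  centers <- foot_centers(sub, trial$protocol, g)
  fw_world <- mat_to_world(centers[, 1], centers[, 2], g)
  cop_ml <- stats::approx(trial$truth_cop$timestamp, trial$truth_cop$ml_mm, t, rule = 2)$y
  cop_ap <- stats::approx(trial$truth_cop$timestamp, trial$truth_cop$ap_mm, t, rule = 2)$y
  body <- mat_to_world(cop_ml, cop_ap, g)

  depth <- rep(0, Tn); lift <- matrix(0, Tn, 2)
  knee_fwd <- matrix(0, Tn, 2)
  pid <- trial$protocol$protocol_id
  if (pid == "squat") depth <- sp$depth_frac * h * (1 - cos(2 * pi * t / sp$period)) / 2
  if (pid == "walk_in_place") {
    ph <- sin(2 * pi * sp$cadence * t)
    lift[, 1] <- sp$lift_frac * h * pmax(-ph, 0)  # left lifts when unloaded
    lift[, 2] <- sp$lift_frac * h * pmax(ph, 0)
  }
  if (pid == "one_leg") {
    lifted <- if (sub$dominant_foot == "L") 2L else 1L
    lift[, lifted] <- 0.28 * L2
    knee_fwd[, lifted] <- 0.25 * L2
  }

  hip_half <- 0.052 * h; sho_half <- 0.115 * h
  pts <- array(NA_real_, dim = c(Tn, 33L, 3L))
  lm <- pose_landmarks
  fl_m <- sub$foot_length / 100
  for (k in seq_len(Tn)) {
    hip_z <- 0.530 * h - depth[k]
    hip_c <- c(body[k, 1], body[k, 2] - 0.3 * depth[k], hip_z)
    sho_c <- c(body[k, 1], body[k, 2] - 0.45 * depth[k], 0.818 * h - depth[k])
    hips <- rbind(hip_c + c(-hip_half, 0, 0), hip_c + c(hip_half, 0, 0))
    shos <- rbind(sho_c + c(-sho_half, 0, 0), sho_c + c(sho_half, 0, 0))
    for (s in 1:2) {
      A <- c(fw_world[s, 1], fw_world[s, 2] + knee_fwd[k, s], ankle_h + lift[k, s])
      H <- hips[s, ]
      D <- H - A; d <- sqrt(sum(D^2))
      dmax <- (L1 + L2) * 0.9999
      if (d > dmax) { H <- A + D / d * dmax; D <- H - A; d <- dmax }
      u <- D / d
      w <- c(0, 1, 0) - sum(c(0, 1, 0) * u) * u
      nw <- sqrt(sum(w^2)); w <- if (nw > 1e-9) w / nw else c(1, 0, 0)
      a2 <- (L2^2 - L1^2 + d^2) / (2 * d)
      h2 <- sqrt(max(L2^2 - a2^2, 0))
      knee <- A + a2 * u + h2 * w
      pts[k, lm$hip[s], ] <- H
      pts[k, lm$knee[s], ] <- knee
      pts[k, lm$ankle[s], ] <- A
      pts[k, lm$heel[s], ] <- A + c(0, -0.3 * fl_m, -0.6 * ankle_h)
      pts[k, lm$foot_index[s], ] <- A + c(0, 0.6 * fl_m, -0.6 * ankle_h)
      pts[k, lm$shoulder[s], ] <- shos[s, ]
      # arms crossed over the chest
      chest <- sho_c + c(0, 0.10 * h * 0.5, -0.10 * h)
      pts[k, lm$elbow[s], ] <- chest + c(ifelse(s == 1, -0.08, 0.08) * h, 0.02, -0.02)
      pts[k, lm$wrist[s], ] <- chest + c(ifelse(s == 1, 0.05, -0.05) * h, 0.03, 0)
    }
    head <- sho_c + c(0, 0.02, 0.112 * h)
    pts[k, lm$nose, ] <- head + c(0, 0.05, 0)
    # remaining face / hand landmarks: small fixed offsets around head/wrists
    face_ids <- setdiff(2:11, lm$nose)
    for (i in seq_along(face_ids))
      pts[k, face_ids[i], ] <- head + c(((i %% 5) - 2) * 0.012, 0.04, ((i %/% 5) - 0.5) * 0.02)
    hand_ids <- 18:23
    for (i in seq_along(hand_ids))
      pts[k, hand_ids[i], ] <- pts[k, lm$wrist[(i %% 2) + 1L], ] + c(0, 0.02, -0.01 * i / 3)
  }
  list(timestamps = t, points = pts, fs = fs_camera)
}

#' Project the trial skeleton into both stereo views
#'
#' Exact pinhole projection of the 33-keypoint 3D skeleton into each
#' calibrated view, with optional Gaussian pixel noise. Keypoints behind a
#' camera are marked invalid and not projected.
#'
#' @param trial a [simulate_trial()] result (needs `$skeleton`).
#' @param cam_a,cam_b [camera_model()] objects.
#' @param noise_px Gaussian pixel noise SD (0 = exact projection).
#' @param seed seed for the pixel noise.
#' @return list of per-camera lists: `px` (`T x 33 x 2`), `valid` (`T x 33`),
#'   plus shared `timestamps`.
#' @export
simulate_skeleton_and_project <- function(trial, cam_a, cam_b, noise_px = 0,
                                          seed = 1L) {
  sk <- trial$skeleton %||% simulate_skeleton(trial)
  d <- dim(sk$points)
  flat <- matrix(sk$points, d[1] * d[2], 3L)
  out <- with_seed(seed, lapply(list(cam_a = cam_a, cam_b = cam_b), function(cam) {
    pr <- project_points(cam, flat)
    px <- pr$px
    if (noise_px > 0) px <- px + stats::rnorm(length(px), 0, noise_px)
    list(px = array(px, dim = c(d[1], d[2], 2L)),
         valid = matrix(pr$valid, d[1], d[2]))
  }))
  out$timestamps <- sk$timestamps
  out
}

#' Protocol schedule of the default study design
#'
#' Four balance tasks, each performed twice, i.e. 8 trials per subject.
#'
#' @param reps repetitions of each task.
#' @return data.frame with `trial_idx`, `protocol_id`, `rep`.
#' @export
protocol_schedule <- function(reps = 2L) {
  ids <- c("one_leg", "tandem", "squat", "walk_in_place")
  data.frame(trial_idx = seq_len(length(ids) * reps),
             protocol_id = rep(ids, each = reps),
             rep = rep(seq_len(reps), times = length(ids)),
             stringsAsFactors = FALSE)
}
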
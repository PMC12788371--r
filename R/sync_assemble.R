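#' Zero-phase low-pass filtering of the reference CoP stream
#'
#' The force-plate-derived ground truth (nominally 1000 Hz) is filtered per
#' axis with a zero-phase fourth-order Butterworth low-pass, cutoff 10 Hz,
#' before downsampling.
#'
#' @param cop data.frame with `timestamp`, `ml_mm`, `ap_mm`.
#' @param fs sampling rate, Hz (> 20).
#' @param cutoff cutoff frequency, Hz.
#' @return data.frame of the same shape.
#' @export
lowpass_truth_cop <- function(cop, fs = 1000, cutoff = 10) {
  if (fs <= 2 * cutoff) abort_invalid("fs must exceed twice the cutoff")
  if (nrow(cop) < 32L) abort_invalid("CoP stream too short to filter")
  out <- cop
  out$ml_mm <- butter_lowpass_zerophase(cop$ml_mm, fs = fs, cutoff = cutoff)
  out$ap_mm <- butter_lowpass_zerophase(cop$ap_mm, fs = fs, cutoff = cutoff)
  out
}

#' Fraction of spectral energy below a frequency
#'
#' Welch power spectral density (Hann window, 50% overlap, default segment
#' length 1024) of a uniformly sampled signal; returns the fraction of total
#' spectral energy at frequencies `<= f_upper`. Used to verify that
#' downsampling the filtered reference CoP to 14 Hz aliases a negligible
#' amount of energy.
#'
#' @param x numeric vector, uniformly sampled.
#' @param fs sampling rate, Hz.
#' @param f_upper upper frequency bound, Hz.
#' @param nseg Welch segment length (capped at `length(x)`).
#' @return fraction in `[0, 1]`; 1.0 with a warning when `f_upper` is at or
#'   above the Nyquist frequency.
#' @export
psd_energy_fraction <- function(x, fs, f_upper, nseg = 1024L) {
  if (length(x) < 64L) abort_invalid("need >= 64 samples for a PSD estimate")
  if (f_upper >= fs / 2) {
    warning("f_upper is at or above Nyquist; returning 1")
    return(1.0)
  }
  w <- welch_psd(x, fs, nseg)
  sum(w$psd[w$freq <= f_upper]) / sum(w$psd)
}

# Welch periodogram: Hann window, 50% overlap, mean of modified periodograms
welch_psd <- function(x, fs, nseg = 1024L) {
  n <- length(x)
  nseg <- min(as.integer(nseg), n)
  step <- max(1L, nseg %/% 2L)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann
  starts <- seq(1L, n - nseg + 1L, by = step)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_len(nfreq)]
  }
  psd <- acc / length(starts) / (fs * sum(win^2))
  # double the interior bins to account for the folded negative frequencies
  if (nfreq > 2L) psd[2:(nfreq - 1L)] <- 2 * psd[2:(nfreq - 1L)]
  list(freq = (seq_len(nfreq) - 1L) * fs / nseg, psd = psd)
}

#' Resample a timed stream onto a reference timestamp grid
#'
#' Linear interpolation of the stream values at the reference timestamps
#' (frames are interpolated per cell). Reference timestamps slightly outside
#' the stream's span (within `tol`) are clamped to the nearest sample;
#' beyond that the call errors, naming the offending timestamp.
#'
#' @param timestamps strictly increasing seconds of the stream.
#' @param values vector, or matrix with one row per timestamp.
#' @param ref_timestamps target grid.
#' @param tol extrapolation tolerance, seconds (default: one median stream
#'   interval).
#' @param method `"linear"` or `"nearest"` (for categorical payloads).
#' @return values aligned on `ref_timestamps`.
#' @export
resample_to_reference <- function(timestamps, values, ref_timestamps,
                                  tol = NULL, method = c("linear", "nearest")) {
  method <- match.arg(method)
  ts <- as.numeric(timestamps)
  if (length(ts) < 2L) abort_invalid("stream needs >= 2 samples")
  if (any(diff(ts) <= 0)) abort_invalid("stream timestamps must be strictly increasing")
  rt <- as.numeric(ref_timestamps)
  if (is.null(tol)) tol <- stats::median(diff(ts))
  bad <- rt < ts[1] - tol | rt > ts[length(ts)] + tol
  if (any(bad))
    abort_invalid(sprintf("reference timestamp %.6f s lies outside the stream span [%.6f, %.6f] beyond tolerance %.6f",
                          rt[which(bad)[1]], ts[1], ts[length(ts)], tol))
  rtc <- pmin(pmax(rt, ts[1]), ts[length(ts)])
  if (method == "nearest") {
    i <- findInterval(rtc, ts, all.inside = TRUE)
    pick <- ifelse(rtc - ts[i] > ts[i + 1L] - rtc, i + 1L, i)
    return(if (is.matrix(values)) values[pick, , drop = FALSE] else values[pick])
  }
  i <- findInterval(rtc, ts, all.inside = TRUE)
  a <- (rtc - ts[i]) / (ts[i + 1L] - ts[i])
  a <- pmin(pmax(a, 0), 1)
  if (is.matrix(values))
    values[i, , drop = FALSE] * (1 - a) + values[i + 1L, , drop = FALSE] * a
  else values[i] * (1 - a) + values[i + 1L] * a
}

#' Worst-case trigger synchronization mismatch of two devices
#'
#' A manual trigger is registered at each device's nearest frame timestamp,
#' so the cross-device alignment uncertainty is bounded by half of each
#' sampling interval: `(1/fs_a + 1/fs_b) / 2`, reported in milliseconds.
#' For the 14 Hz tactile mat and 30 Hz cameras this is ~52.4 ms.
#'
#' @param fs_a,fs_b device sampling rates, Hz.
#' @return mismatch bound in milliseconds.
#' @export
sync_mismatch_bound <- function(fs_a, fs_b) {
  assert_scalar_number(fs_a, "fs_a", positive = TRUE)
  assert_scalar_number(fs_b, "fs_b", positive = TRUE)
  (1 / fs_a + 1 / fs_b) / 2 * 1000
}

#' Assemble one synchronized 14 Hz trial record
#'
#' Runs the full synchronization chain on a simulated trial: filters the
#' 1000 Hz reference CoP (10 Hz zero-phase Butterworth), anchors the 14 Hz
#' reference grid at the start of the middle analysis window, preprocesses
#' the raw tactile stream (baseline correction, thresholding, min-max 8-bit
#' quantization, median denoising, drop filling) and aligns it per cell,
#' computes the WMA CoP on the aligned frames, triangulates and filters the
#' stereo keypoints (2 Hz zero-phase Butterworth at 30 Hz), extracts joint
#' angles, aligns them, and differentiates at the synchronized rate.
#'
#' @param trial a [simulate_trial()] result.
#' @param cameras the stereo rig used for the 2D keypoints.
#' @param denoise_frames apply the median denoiser.
#' @param threshold noise-floor threshold (see [apply_correction()]).
#' @param strict_eq1 WMA axis pairing (see [wma_cop()]).
#' @return a `trial_record` (see [build_trial_record()]).
#' @export
assemble_trial <- function(trial, cameras = default_stereo_rig(),
                           denoise_frames = TRUE, threshold = NULL,
                           strict_eq1 = FALSE) {
  g <- trial$geometry
  pr <- trial$protocol
  fs_ref <- 14
  t0 <- (pr$duration_s - pr$analysis_window_s) / 2
  n_ref <- round(pr$analysis_window_s * fs_ref)
  t_ref <- t0 + (seq_len(n_ref) - 1L) / fs_ref

  # reference CoP: zero-phase 10 Hz low-pass, then interpolate on the grid
  truth <- lowpass_truth_cop(trial$truth_cop)
  truth_ref <- cbind(
    ml_mm = resample_to_reference(truth$timestamp, truth$ml_mm, t_ref),
    ap_mm = resample_to_reference(truth$timestamp, truth$ap_mm, t_ref))

  # tactile: preprocess on the native (jittered) grid, then align per cell
  raw_seq <- stitch_stream(trial$raw_tactile)
  baseline <- calibrate_baseline(trial$no_load_frames)
  gray <- preprocess_tactile(raw_seq, baseline,
                             expected_timestamps = trial$raw_tactile$expected_timestamps,
                             threshold = threshold, denoise_frames = denoise_frames)
  nz <- attr(gray, "normalizer")
  frames_ref <- resample_to_reference(gray$timestamps, gray$frames, t_ref)
  gray_ref <- pressure_sequence(round(frames_ref), t_ref, stage = "gray8", geometry = g)
  wma <- wma_cop_sequence(gray_ref, g, strict_eq1 = strict_eq1)

  # kinematics: triangulate both views, 2 Hz zero-phase filter at 30 Hz,
  # joint angles, align, differentiate at 14 Hz
  kp <- trial$keypoints_2d
  P_a <- projection_matrix(cameras$cam_a); P_b <- projection_matrix(cameras$cam_b)
  kpa <- kp$cam_a$px; kpa[!rep_valid(kp$cam_a$valid)] <- NA_real_
  kpb <- kp$cam_b$px; kpb[!rep_valid(kp$cam_b$valid)] <- NA_real_
  tri <- triangulate_tracks(kpa, kpb, P_a, P_b)
  track <- lowpass_track(tri$points, fs = 30, cutoff = 2)
  ang30 <- extract_joint_angles(track)
  ang_ref <- resample_to_reference(kp$timestamps, ang30, t_ref)
  colnames(ang_ref) <- colnames(ang30)
  af <- angular_features(ang_ref, fs = fs_ref)

  settings <- list(protocol_id = protocol_code(pr$protocol_id),
                   sensor_width_mm = g$width_mm, sensor_length_mm = g$length_mm)
  rec <- build_trial_record(
    tactile_gray8 = gray_ref$frames,
    tactile_wma_cop = cbind(ml_mm = wma$ml_mm, ap_mm = wma$ap_mm),
    truth_cop = truth_ref,
    angular_features = af$features,
    timestamps = t_ref,
    subject = trial$subject,
    settings = settings)
  attr(rec, "normalizer") <- nz
  rec
}

rep_valid <- function(valid) array(valid, dim = c(dim(valid), 2L))

#' Integer protocol codes used in stored records
#' @param protocol_id protocol name(s).
#' @export
protocol_code <- function(protocol_id) {
  codes <- c(one_leg = 1L, tandem = 2L, squat = 3L, walk_in_place = 4L)
  unname(codes[protocol_id])
}

#' Build a synchronized multimodal trial record
#'
#' The per-trial container of the 14 Hz synchronized dataset: quantized
#' tactile frames (stored as raw bytes), WMA CoP, reference CoP, the 18
#' angular features, subject characteristics and experimental settings. All
#' datasets must share the same number of samples `T`. Units are millimetres
#' (CoP) and degrees / deg/s / deg/s^2 (angular features), recorded in the
#' container attributes along with a schema version.
#'
#' @param tactile_gray8 `T x 4096` matrix of values in `{0..255}`.
#' @param tactile_wma_cop,truth_cop `T x 2` matrices (ml, ap), mm.
#' @param angular_features `T x 18` matrix.
#' @param timestamps length-`T` seconds at the 14 Hz reference.
#' @param subject named list / one-row data.frame of subject characteristics.
#' @param settings list with `protocol_id` (1..4), `sensor_width_mm`,
#'   `sensor_length_mm`.
#' @return object of class `trial_record`.
#' @export
build_trial_record <- function(tactile_gray8, tactile_wma_cop, truth_cop,
                               angular_features, timestamps, subject, settings) {
  lens <- c(tactile = nrow(tactile_gray8), wma = nrow(tactile_wma_cop),
            truth = nrow(truth_cop), angular = nrow(angular_features),
            timestamps = length(timestamps))
  if (length(unique(lens)) != 1L)
    abort_invalid(paste0("dataset lengths differ: ",
                         paste(names(lens), lens, sep = "=", collapse = ", ")))
  if (!settings$protocol_id %in% 1:4)
    abort_invalid("protocol_id must be in 1..4")
  if (any(tactile_gray8 < 0 | tactile_gray8 > 255))
    abort_invalid("tactile_gray8 values must lie in 0..255")
  rec <- list(
    tactile_gray8 = array(as.raw(round(tactile_gray8)), dim = dim(tactile_gray8)),
    tactile_wma_cop = as.matrix(tactile_wma_cop),
    truth_cop = as.matrix(truth_cop),
    angular_features = as.matrix(angular_features),
    timestamps = as.numeric(timestamps),
    subject = as.list(subject),
    settings = settings)
  attr(rec, "schema_version") <- "copmat-trial-1"
  attr(rec, "units") <- c(cop = "mm", angle = "deg", velocity = "deg/s",
                          acceleration = "deg/s^2", timestamps = "s")
  class(rec) <- "trial_record"
  rec
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> T=%d @14 Hz, subject %s, protocol %d\n",
              length(x$timestamps), x$subject$subject_id %||% "?",
              x$settings$protocol_id))
  invisible(x)
}

#' Number of synchronized samples in a record
#' @param rec a `trial_record`.
#' @export
record_length <- function(rec) length(rec$timestamps)

#' Tactile frames of a record as a numeric matrix in `[0, 1]`
#' @param rec a `trial_record`.
#' @param idx frame indices (default all).
#' @export
record_frames01 <- function(rec, idx = seq_len(record_length(rec))) {
  m <- rec$tactile_gray8[idx, , drop = FALSE]
  matrix(as.integer(m), nrow = length(idx)) / 255
}

#' Write / read a trial record container
#'
#' Single-file serialization of the synchronized trial container. The
#' write-read round trip is bit-identical for integer data and exact for
#' floats.
#'
#' @param rec a `trial_record`.
#' @param path file path.
#' @export
write_trial_record <- function(rec, path) {
  stopifnot(inherits(rec, "trial_record"))
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname write_trial_record
#' @export
read_trial_record <- function(path) {
  rec <- readRDS(path)
  if (!inherits(rec, "trial_record")) abort_invalid("file is not a trial_record")
  rec
}
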
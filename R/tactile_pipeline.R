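#' Timestamped stack of pressure frames
#'
#' Frames are stored as a `T x (n_rows*n_cols)` numeric matrix, one frame per
#' row, cells in column-major order of the 64 x 64 grid. `stage` tags how far
#' through the preprocessing chain the data has travelled:
#' `raw` -> `corrected` -> `normalized`/`gray8` -> `denoised`.
#'
#' @param frames matrix `T x n_cells`, or a 3-d array `T x n_rows x n_cols`,
#'   or a list of `n_rows x n_cols` matrices.
#' @param timestamps seconds, strictly increasing, length `T`.
#' @param stage processing-stage tag.
#' @param geometry a [sensor_geometry()].
#' @return `pressure_sequence` object.
#' @export
pressure_sequence <- function(frames, timestamps, stage = "raw",
                              geometry = sensor_geometry()) {
  stage <- match.arg(stage, c("raw", "corrected", "normalized", "gray8", "denoised"))
  if (is.list(frames)) frames <- do.call(rbind, lapply(frames, as.vector))
  if (is.array(frames) && length(dim(frames)) == 3L) {
    d <- dim(frames)
    frames <- matrix(aperm(frames, c(2L, 3L, 1L)), nrow = d[1], byrow = TRUE)
  }
  frames <- as.matrix(frames)
  n_cells <- geometry$n_rows * geometry$n_cols
  if (ncol(frames) != n_cells)
    abort_invalid(sprintf("frames must have %d cells per frame, got %d",
                          n_cells, ncol(frames)))
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != nrow(frames))
    abort_invalid("length(timestamps) must equal the number of frames")
  if (nrow(frames) > 1L && any(diff(timestamps) <= 0))
    abort_invalid("timestamps must be strictly increasing")
  if (any(frames < 0)) abort_invalid("pressure values must be non-negative")
  structure(list(frames = frames, timestamps = timestamps, stage = stage,
                 geometry = geometry),
            class = "pressure_sequence")
}

#' @export
print.pressure_sequence <- function(x, ...) {
  cat(sprintf("<pressure_sequence> %d frames @ %d cells, stage '%s'\n",
              nrow(x$frames), ncol(x$frames), x$stage))
  invisible(x)
}

#' @rdname pressure_sequence
#' @param x a `pressure_sequence`.
#' @param t frame index.
#' @export
frame_at <- function(x, t) {
  matrix(x$frames[t, ], x$geometry$n_rows, x$geometry$n_cols)
}

n_frames <- function(x) nrow(x$frames)

#' Stitch four sensor modules into the unified 64 x 64 frame
#'
#' The mat is read out as four independent 32 x 32 modules tiled 2 x 2.
#' Modules are given in row-major tile order: (top-left, top-right,
#' bottom-left, bottom-right), where "top" is the low-row end of the grid.
#' Cell `(r, c)` of the output traces to module `(ceiling(r/32),
#' ceiling(c/32))` in tile coordinates.
#'
#' @param modules list of four 32 x 32 matrices in row-major tile order.
#' @param geometry a [sensor_geometry()].
#' @return `n_rows x n_cols` matrix.
#' @export
stitch_modules <- function(modules, geometry = sensor_geometry()) {
  tl <- geometry$module_tiling
  ms <- geometry$module_shape
  if (!is.list(modules) || length(modules) != prod(tl))
    abort_invalid(sprintf("expected %d modules, got %d",
                          prod(tl), if (is.list(modules)) length(modules) else 1L))
  out <- matrix(0, geometry$n_rows, geometry$n_cols)
  k <- 0L
  for (tr in seq_len(tl[1])) for (tc in seq_len(tl[2])) {
    k <- k + 1L
    m <- as.matrix(modules[[k]])
    if (!all(dim(m) == ms))
      abort_invalid(sprintf("module %d has shape %dx%d, expected %dx%d",
                            k, nrow(m), ncol(m), ms[1], ms[2]))
    out[(tr - 1L) * ms[1] + seq_len(ms[1]),
        (tc - 1L) * ms[2] + seq_len(ms[2])] <- m
  }
  out
}

#' Split a stitched frame back into its four modules
#' @param frame stitched `n_rows x n_cols` matrix.
#' @inheritParams stitch_modules
#' @return list of module matrices in row-major tile order.
#' @export
split_modules <- function(frame, geometry = sensor_geometry()) {
  tl <- geometry$module_tiling; ms <- geometry$module_shape
  out <- vector("list", prod(tl)); k <- 0L
  for (tr in seq_len(tl[1])) for (tc in seq_len(tl[2])) {
    k <- k + 1L
    out[[k]] <- frame[(tr - 1L) * ms[1] + seq_len(ms[1]),
                      (tc - 1L) * ms[2] + seq_len(ms[2])]
  }
  out
}

#' No-load baseline calibration
#'
#' Before each session a handful of frames (default 20) are recorded with
#' nothing on the mat; their per-cell mean defines the baseline response that
#' is subtracted from every subsequent frame.
#'
#' @param no_load_frames a [pressure_sequence()], a `T x n_cells` matrix, or a
#'   list of frame matrices.
#' @return `baseline_map`: an `n_rows x n_cols` matrix with attribute
#'   `n_frames_used`.
#' @export
calibrate_baseline <- function(no_load_frames) {
  if (inherits(no_load_frames, "pressure_sequence")) {
    geom <- no_load_frames$geometry
    m <- no_load_frames$frames
  } else {
    geom <- sensor_geometry()
    if (is.list(no_load_frames))
      m <- do.call(rbind, lapply(no_load_frames, as.vector))
    else m <- as.matrix(no_load_frames)
  }
  if (nrow(m) < 1L) abort_invalid("baseline calibration needs >= 1 frame")
  b <- matrix(colMeans(m), geom$n_rows, geom$n_cols)
  structure(b, n_frames_used = nrow(m), class = c("baseline_map", "matrix", "array"))
}

#' Baseline subtraction and noise-floor thresholding
#'
#' `corrected = max(raw - baseline, 0)`, then any cell below `threshold` is
#' zeroed so that only substantial pressure survives.
#'
#' @param x a frame matrix or [pressure_sequence()] at stage `raw`.
#' @param baseline a [calibrate_baseline()] map (or compatible matrix).
#' @param threshold raw units; `NULL` uses 2% of the post-correction full
#'   scale of `x`.
#' @return same shape as `x`, stage `corrected`.
#' @export
apply_correction <- function(x, baseline, threshold = NULL) {
  bvec <- as.vector(unclass(baseline))
  if (inherits(x, "pressure_sequence")) {
    fr <- pmax(sweep(x$frames, 2L, bvec), 0)
    if (is.null(threshold)) threshold <- 0.02 * max(fr)
    if (threshold < 0) abort_invalid("threshold must be >= 0")
    fr[fr < threshold] <- 0
    out <- x; out$frames <- fr; out$stage <- "corrected"
    return(out)
  }
  fr <- pmax(as.matrix(x) - matrix(bvec, nrow(x), ncol(x)), 0)
  if (is.null(threshold)) threshold <- 0.02 * max(fr)
  if (threshold < 0) abort_invalid("threshold must be >= 0")
  fr[fr < threshold] <- 0
  fr
}

#' Min-max normalization and 8-bit quantization
#'
#' Scales the whole collected dataset to `[0, 1]` (a single min/max pair over
#' every frame given) and converts to 8-bit grayscale by multiplying by 255
#' and rounding. The scaling constants are recorded so the mapping can be
#' inverted (and reused at inference on new sessions).
#'
#' @param x a [pressure_sequence()] at stage `corrected`.
#' @param constants optional `c(min, max)` from a previous call.
#' @return `pressure_sequence` at stage `gray8`, values in `{0..255}`, with
#'   attribute `normalizer = c(min, max)`.
#' @export
normalize_quantize <- function(x, constants = NULL) {
  stopifnot(inherits(x, "pressure_sequence"))
  if (is.null(constants)) constants <- range(x$frames)
  lo <- constants[1]; hi <- constants[2]
  if (hi <= lo) {
    warning("degenerate dataset range (max <= min); emitting all zeros")
    g <- matrix(0, nrow(x$frames), ncol(x$frames))
  } else {
    g <- round(pmin(pmax((x$frames - lo) / (hi - lo), 0), 1) * 255)
  }
  out <- x; out$frames <- g; out$stage <- "gray8"
  attr(out, "normalizer") <- c(min = lo, max = hi)
  out
}

#' Invert the 8-bit quantization back to normalized units
#' @param x gray8 `pressure_sequence` with a `normalizer` attribute.
#' @export
dequantize <- function(x) {
  nz <- attr(x, "normalizer")
  if (is.null(nz)) abort_invalid("no normalizer recorded on this sequence")
  out <- x
  out$frames <- x$frames / 255 * (nz[["max"]] - nz[["min"]]) + nz[["min"]]
  out$stage <- "corrected"
  out
}

# 3x3 median with edge replication on one frame matrix
median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- c(1L, seq_len(nr - 1L)); dn <- c(seq_len(nr)[-1L], nr)
  lf <- c(1L, seq_len(nc - 1L)); rt <- c(seq_len(nc)[-1L], nc)
  e <- list(m[up, lf], m[up, ], m[up, rt],
            m[, lf],  m,      m[, rt],
            m[dn, lf], m[dn, ], m[dn, rt])
  # Paeth median-of-9 sorting network (19 pairwise min/max exchanges)
  p <- function(a, b) { lo <- pmin(e[[a]], e[[b]]); e[[b]] <<- pmax(e[[a]], e[[b]]); e[[a]] <<- lo }
  p(2,3); p(5,6); p(8,9); p(1,2); p(4,5); p(7,8); p(2,3); p(5,6); p(8,9)
  p(1,4); p(6,9); p(5,8); p(4,7); p(2,5); p(3,6); p(5,8); p(5,3); p(7,5); p(5,3)
  matrix(e[[5]], nr, nc)
}

#' Salt-and-pepper denoising
#'
#' A 3 x 3 median filter with edge replication, the standard remedy for
#' isolated stuck-cell spikes in the quantized pressure images.
#'
#' @param x a frame matrix or a gray8 [pressure_sequence()].
#' @return same shape, stage `denoised`.
#' @export
denoise <- function(x) {
  if (inherits(x, "pressure_sequence")) {
    g <- x$geometry
    out <- x
    out$frames <- t(apply(x$frames, 1L, function(v)
      as.vector(median3x3(matrix(v, g$n_rows, g$n_cols)))))
    out$stage <- "denoised"
    return(out)
  }
  median3x3(as.matrix(x))
}

#' Fill dropped tactile frames by per-cell linear interpolation
#'
#' The mat occasionally skips a frame; missing timestamps are reconstructed
#' cell-by-cell from the nearest surviving neighbours (linear in time), and
#' leading/trailing gaps take the nearest surviving frame.
#'
#' @param x a [pressure_sequence()] with the surviving frames.
#' @param expected_timestamps the full nominal acquisition grid, seconds.
#' @param tol matching tolerance in seconds; defaults to 45% of the median
#'   expected interval.
#' @return `pressure_sequence` on the expected grid.
#' @export
fill_dropped_frames <- function(x, expected_timestamps, tol = NULL) {
  stopifnot(inherits(x, "pressure_sequence"))
  if (n_frames(x) < 2L) abort_invalid("need >= 2 surviving frames to interpolate")
  ts <- x$timestamps
  et <- as.numeric(expected_timestamps)
  if (any(diff(et) <= 0)) abort_invalid("expected timestamps must be increasing")
  if (is.null(tol)) tol <- 0.45 * stats::median(diff(et))
  # map each expected time to a surviving frame, if close enough
  idx <- findInterval(et, ts)
  match_idx <- integer(length(et))
  for (k in seq_along(et)) {
    cand <- c(idx[k], idx[k] + 1L)
    cand <- cand[cand >= 1L & cand <= length(ts)]
    d <- abs(ts[cand] - et[k])
    if (length(d) && min(d) <= tol) match_idx[k] <- cand[which.min(d)]
  }
  out <- matrix(0, length(et), ncol(x$frames))
  for (k in seq_along(et)) {
    if (match_idx[k] > 0L) { out[k, ] <- x$frames[match_idx[k], ]; next }
    i <- findInterval(et[k], ts)
    if (i < 1L) out[k, ] <- x$frames[1L, ]
    else if (i >= length(ts)) out[k, ] <- x$frames[length(ts), ]
    else {
      a <- (et[k] - ts[i]) / (ts[i + 1L] - ts[i])
      out[k, ] <- (1 - a) * x$frames[i, ] + a * x$frames[i + 1L, ]
    }
  }
  pressure_sequence(out, et, stage = x$stage, geometry = x$geometry)
}

#' Weighted-mean-approach (WMA) center of pressure of one frame
#'
#' The CoP is the pressure-weighted average of cell indices scaled to
#' physical units: per axis `(sum(i * w_i) / sum(w_i)) * pitch` with 1-based
#' indices. By default the ML coordinate spans the 60 cm width axis (grid
#' columns) and AP the 80 cm length axis (grid rows). `strict_eq1 = TRUE`
#' instead pairs the column average with `length/64` and the row average with
#' `width/64` — the literal printed form of the formula, retained because the
#' intended axis pairing is ambiguous for a non-square mat.
#'
#' @param frame `n_rows x n_cols` non-negative matrix.
#' @param geometry a [sensor_geometry()].
#' @param strict_eq1 use the literal axis/extent pairing (see above).
#' @return list with `ml_mm`, `ap_mm`, `no_load`. An all-zero frame yields a
#'   typed no-load marker (`no_load = TRUE`, coordinates `NA`) rather than a
#'   spurious position.
#' @export
wma_cop <- function(frame, geometry = sensor_geometry(), strict_eq1 = FALSE) {
  m <- as.matrix(frame)
  tot <- sum(m)
  if (tot <= 0)
    return(structure(list(ml_mm = NA_real_, ap_mm = NA_real_, no_load = TRUE),
                     class = "cop_sample"))
  xbar <- sum(colSums(m) * seq_len(ncol(m))) / tot  # column (width-axis) index
  ybar <- sum(rowSums(m) * seq_len(nrow(m))) / tot  # row (length-axis) index
  cc <- geometry$cell_center
  if (strict_eq1) {
    ml <- grid_coord(xbar, geometry$length_mm / geometry$n_cols, cc)
    ap <- grid_coord(ybar, geometry$width_mm / geometry$n_rows, cc)
  } else {
    ml <- grid_coord(xbar, geometry$pitch_width_mm, cc)
    ap <- grid_coord(ybar, geometry$pitch_length_mm, cc)
  }
  structure(list(ml_mm = ml, ap_mm = ap, no_load = FALSE), class = "cop_sample")
}

#' WMA CoP for every frame of a sequence
#'
#' @inheritParams wma_cop
#' @param x a [pressure_sequence()].
#' @return data.frame with `timestamp`, `ml_mm`, `ap_mm`, `no_load`.
#' @export
wma_cop_sequence <- function(x, geometry = x$geometry, strict_eq1 = FALSE) {
  fr <- x$frames
  nr <- geometry$n_rows; nc <- geometry$n_cols
  # cells are column-major: cell j -> row (j-1) %% nr + 1, col (j-1) %/% nr + 1
  j <- seq_len(nr * nc)
  rowidx <- (j - 1L) %% nr + 1L
  colidx <- (j - 1L) %/% nr + 1L
  tot <- rowSums(fr)
  xbar <- as.vector(fr %*% colidx) / tot
  ybar <- as.vector(fr %*% rowidx) / tot
  cc <- geometry$cell_center
  if (strict_eq1) {
    ml <- grid_coord(xbar, geometry$length_mm / nc, cc)
    ap <- grid_coord(ybar, geometry$width_mm / nr, cc)
  } else {
    ml <- grid_coord(xbar, geometry$pitch_width_mm, cc)
    ap <- grid_coord(ybar, geometry$pitch_length_mm, cc)
  }
  no_load <- tot <= 0
  ml[no_load] <- NA_real_; ap[no_load] <- NA_real_
  data.frame(timestamp = x$timestamps, ml_mm = ml, ap_mm = ap, no_load = no_load)
}

#' @export
print.cop_sample <- function(x, ...) {
  if (isTRUE(x$no_load)) cat("<cop_sample> no load\n")
  else cat(sprintf("<cop_sample> ML %.2f mm, AP %.2f mm\n", x$ml_mm, x$ap_mm))
  invisible(x)
}

#' Full tactile preprocessing chain
#'
#' Baseline correction, thresholding, dataset min-max 8-bit quantization,
#' optional median denoising, and drop filling onto the nominal grid.
#'
#' @param raw a raw-stage [pressure_sequence()].
#' @param baseline a [calibrate_baseline()] map.
#' @param expected_timestamps nominal acquisition grid (`NULL` to skip drop
#'   filling).
#' @param threshold see [apply_correction()].
#' @param denoise_frames apply the 3 x 3 median filter.
#' @param constants optional normalization constants to reuse.
#' @return gray8/denoised `pressure_sequence` with `normalizer` attribute.
#' @export
preprocess_tactile <- function(raw, baseline, expected_timestamps = NULL,
                               threshold = NULL, denoise_frames = TRUE,
                               constants = NULL) {
  x <- apply_correction(raw, baseline, threshold = threshold)
  x <- normalize_quantize(x, constants = constants)
  nz <- attr(x, "normalizer")
  if (denoise_frames) x <- denoise(x)
  if (!is.null(expected_timestamps)) x <- fill_dropped_frames(x, expected_timestamps)
  attr(x, "normalizer") <- nz
  x
}
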
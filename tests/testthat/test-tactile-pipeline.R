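g64 <- sensor_geometry()

test_that("module stitching places tiles and round-trips", {
  mods <- lapply(1:4, function(v) matrix(v, 32, 32))
  st <- stitch_modules(mods, g64)
  expect_equal(dim(st), c(64L, 64L))
  expect_equal(st[1, 1], 1); expect_equal(st[1, 64], 2)
  expect_equal(st[64, 1], 3); expect_equal(st[64, 64], 4)
  rmods <- lapply(1:4, function(i) matrix(runif(32 * 32), 32, 32))
  expect_equal(split_modules(stitch_modules(rmods, g64), g64), rmods)
  expect_error(stitch_modules(rmods[1:3], g64), "modules")
  expect_error(stitch_modules(c(rmods[1:3], list(matrix(0, 16, 32))), g64), "shape")
})

test_that("baseline calibration and correction follow the piecewise definition", {
  frames <- matrix(3, 20, 64 * 64)
  base <- calibrate_baseline(pressure_sequence(frames, seq_len(20), "raw", g64))
  expect_equal(attr(base, "n_frames_used"), 20L)
  expect_true(all(unclass(base) == 3))
  corr <- apply_correction(matrix(3, 64, 64), base, threshold = 0)
  expect_true(all(corr == 0))
  b1 <- matrix(3, 64, 64)
  f <- matrix(10, 64, 64); f[1, 2] <- 4
  corr <- apply_correction(f, b1, threshold = 2)
  expect_equal(corr[2, 2], 7)
  expect_equal(corr[1, 2], 0)  # 4 - 3 = 1 < threshold
})

test_that("correction matches a brute-force per-cell oracle on random frames", {
  set.seed(1)
  for (i in 1:20) {
    nl <- matrix(runif(5 * 64 * 64, 0, 2), 5)
    raw <- matrix(runif(64 * 64, 0, 10), 64, 64)
    thr <- runif(1, 0, 1)
    base <- calibrate_baseline(nl)
    got <- apply_correction(raw, base, threshold = thr)
    ref <- pmax(raw - matrix(colMeans(nl), 64, 64), 0)
    ref[ref < thr] <- 0
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("min-max quantization maps the dataset range onto 0..255", {
  fr <- matrix(c(0, 25, 50, 10), 2, 2)
  ps <- pressure_sequence(rbind(as.vector(matrix(0, 64, 64))), 1, "corrected", g64)
  ps$frames[1, 1:4] <- c(0, 25, 50, 10)
  q <- normalize_quantize(ps)
  expect_equal(q$frames[1, 3], 255)
  expect_equal(q$frames[1, 1], 0)
  expect_equal(q$frames[1, 2], round(25 / 50 * 255))
  # degenerate range
  psc <- pressure_sequence(matrix(5, 3, 64 * 64), 1:3, "corrected", g64)
  expect_warning(qc <- normalize_quantize(psc), "degenerate")
  expect_true(all(qc$frames == 0))
})

test_that("dequantization recovers values within half a quantization step", {
  set.seed(2)
  ps <- pressure_sequence(matrix(runif(3 * 4096, 0, 7), 3), c(0, 1, 2), "corrected", g64)
  q <- normalize_quantize(ps)
  dq <- dequantize(q)
  step <- diff(range(ps$frames)) / 255
  expect_lt(max(abs(dq$frames - ps$frames)), step / 2 + 1e-12)
})

test_that("median denoiser kills isolated spikes and matches a brute-force oracle", {
  const <- matrix(7, 64, 64)
  expect_equal(denoise(const), const)
  spike <- matrix(0, 64, 64); spike[10, 20] <- 255
  expect_true(all(denoise(spike) == 0))
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
    ref <- matrix(0, 64, 64)
    for (r in 1:64) for (cc in 1:64) {
      rr <- pmin(pmax(r + (-1:1), 1), 64); c2 <- pmin(pmax(cc + (-1:1), 1), 64)
      ref[r, cc] <- stats::median(as.vector(m[rr, c2]))
    }
    expect_equal(denoise(m), ref, ignore_attr = TRUE)
  }
})

test_that("dropped frames are rebuilt by per-cell linear interpolation", {
  fr <- rbind(rep(0, 4096), rep(10, 4096))
  ps <- pressure_sequence(fr, c(0, 2), "corrected", g64)
  filled <- fill_dropped_frames(ps, c(0, 1, 2))
  expect_equal(filled$frames[2, ], rep(5, 4096))
  # no gaps -> identity
  ps3 <- pressure_sequence(rbind(fr, rep(3, 4096)), c(0, 1, 2), "corrected", g64)
  expect_equal(fill_dropped_frames(ps3, c(0, 1, 2))$frames, ps3$frames)
  # linear-in-time signals recovered exactly under 20% drops
  set.seed(4)
  tt <- 0:24 / 14
  slope <- runif(4096, -2, 2); icept <- runif(4096, 8, 12)
  full <- outer(tt, slope) + matrix(icept, 25, 4096, byrow = TRUE)
  keep <- sort(c(1, 25, sample(2:24, 18)))
  ps <- pressure_sequence(full[keep, ], tt[keep], "corrected", g64)
  rec <- fill_dropped_frames(ps, tt)
  expect_lt(max(abs(rec$frames - full)), 1e-9)
  expect_error(fill_dropped_frames(
    pressure_sequence(fr[1, , drop = FALSE], 0, "corrected", g64), c(0, 1)), ">= 2")
})

test_that("WMA CoP follows the weighted-mean formula on canonical frames", {
  f <- matrix(0, 64, 64); f[10, 64] <- 5
  s <- wma_cop(f, g64)
  expect_equal(s$ml_mm, 600)           # delta load at the far width edge
  expect_equal(s$ap_mm, 10 * 800 / 64)
  u <- matrix(1, 64, 64)
  expect_equal(wma_cop(u, g64)$ml_mm, 32.5 * 600 / 64)  # mean index 32.5
  expect_equal(wma_cop(u, g64)$ap_mm, 32.5 * 800 / 64)
  z <- wma_cop(matrix(0, 64, 64), g64)
  expect_true(z$no_load)
  expect_true(is.na(z$ml_mm))
})

test_that("strict printed-formula mode pairs the column average with length/64", {
  f <- matrix(0, 64, 64); f[1, 64] <- 1
  s <- wma_cop(f, g64, strict_eq1 = TRUE)
  expect_equal(s$ml_mm, 64 * 800 / 64)  # L/64 scaling on the x index
  expect_equal(s$ap_mm, 1 * 600 / 64)
})

test_that("WMA matches a brute-force double loop and obeys invariances", {
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(runif(64 * 64), 64, 64)
    s <- wma_cop(m, g64)
    num_ml <- 0; num_ap <- 0; tot <- 0
    for (r in 1:64) for (cc in 1:64) {
      w <- m[r, cc]; tot <- tot + w
      num_ml <- num_ml + cc * w; num_ap <- num_ap + r * w
    }
    expect_equal(s$ml_mm, num_ml / tot * 600 / 64, tolerance = 1e-12)
    expect_equal(s$ap_mm, num_ap / tot * 800 / 64, tolerance = 1e-12)
    # scale invariance
    s2 <- wma_cop(m * runif(1, 0.5, 10), g64)
    expect_equal(s2$ml_mm, s$ml_mm, tolerance = 1e-9)
  }
  # translation equivariance: shift mass by k cells
  m <- matrix(0, 64, 64); m[20:30, 20:30] <- runif(121)
  s0 <- wma_cop(m, g64)
  k <- 7
  m2 <- matrix(0, 64, 64); m2[20:30, (20 + k):(30 + k)] <- m[20:30, 20:30]
  expect_equal(wma_cop(m2, g64)$ml_mm - s0$ml_mm, k * 600 / 64, tolerance = 1e-9)
})

test_that("sequence WMA agrees with per-frame WMA", {
  set.seed(6)
  fr <- matrix(runif(5 * 4096), 5)
  ps <- pressure_sequence(fr, 1:5, "corrected", g64)
  df <- wma_cop_sequence(ps)
  for (i in 1:5) {
    s <- wma_cop(matrix(fr[i, ], 64, 64), g64)
    expect_equal(df$ml_mm[i], s$ml_mm, tolerance = 1e-12)
    expect_equal(df$ap_mm[i], s$ap_mm, tolerance = 1e-12)
  }
})

test_that("preprocessing preserves shape and non-negativity at every stage", {
  tr <- sim_test_trial("tandem", duration = 10, window = 6,
                       noise = default_sensor_defects(2), seed = 11)
  raw <- stitch_stream(tr$raw_tactile)
  base <- calibrate_baseline(tr$no_load_frames)
  out <- preprocess_tactile(raw, base, tr$raw_tactile$expected_timestamps)
  expect_equal(ncol(out$frames), 4096L)
  expect_true(all(out$frames >= 0))
  expect_true(all(out$frames <= 255))
  expect_equal(length(out$timestamps), length(tr$raw_tactile$expected_timestamps))
  # bit-reproducible
  out2 <- preprocess_tactile(raw, base, tr$raw_tactile$expected_timestamps)
  expect_identical(out$frames, out2$frames)
})
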
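test_that("model specs encode the four benchmark architectures", {
  zoo <- model_zoo()
  expect_named(zoo, c("resnet_bilstm", "cnn_bilstm", "cnn_lstm", "bilstm"))
  expect_equal(zoo$resnet_bilstm$encoder, "resnet")
  expect_equal(zoo$cnn_lstm$decoder, "lstm")
  expect_equal(zoo$bilstm$encoder, "none")
  expect_true(all(vapply(zoo, `[[`, logical(1), "use_angular")))
  expect_false(model_zoo(use_angular = FALSE)$bilstm$use_angular)
})

test_that("forward contract: per-frame two-dimensional CoP output", {
  B <- 2L; Tw <- 4L
  set.seed(1)
  batch <- list(frames = matrix(runif(B * Tw * 4096), B * Tw, 4096),
                wma = matrix(rnorm(B * Tw * 2), B * Tw, 2),
                ang = matrix(rnorm(B * Tw * 18), B * Tw, 18),
                static = matrix(rnorm(B * 12), B, 12),
                target = matrix(rnorm(B * Tw * 2), B * Tw, 2), B = B, Tw = Tw)
  for (sp in model_zoo(hidden_dim = 8L, encoder_dim = 8L)) {
    m <- build_model(sp, static_dim = 12L, seed = 3)
    pred <- copmat:::forward_cop_model(m, batch)$pred
    expect_equal(dim(pred), c(B * Tw, 2L))
  }
})

test_that("the flatten baseline feeds 4096 per-frame features into the decoder", {
  m <- build_model(cop_model_spec("none", "bilstm"), static_dim = 12L, seed = 1)
  expect_equal(m$fuse_dim, 4096L + 2L + 18L)
  m_ot <- build_model(cop_model_spec("none", "bilstm", use_angular = FALSE),
                      static_dim = 12L, seed = 1)
  expect_equal(m_ot$fuse_dim, 4096L + 2L)
})

test_that("the resnet encoder contains residual blocks and no pooling operators", {
  m <- build_model(cop_model_spec("resnet", "bilstm"), static_dim = 12L, seed = 1)
  inv <- model_inventory(m)
  expect_false(any(grepl("pool", inv$type, ignore.case = TRUE)))
  expect_gte(sum(inv$type == "residual_block"), 2L)
  expect_gte(sum(inv$type == "conv_strided"), 3L)
  # every downsampling stage is a strided convolution
  strides <- vapply(m$plans, `[[`, numeric(1), "stride")
  expect_true(all(strides[c("stem", "down1", "down2")] > 1))
})

test_that("ablating angular features changes the decoder input width by 18", {
  wa <- build_model(cop_model_spec("resnet", "bilstm", use_angular = TRUE),
                    static_dim = 12L, seed = 1)
  ot <- build_model(cop_model_spec("resnet", "bilstm", use_angular = FALSE),
                    static_dim = 12L, seed = 1)
  expect_equal(wa$fuse_dim - ot$fuse_dim, 18L)
  expect_equal(nrow(wa$params$lstm1f_Wx) - nrow(ot$params$lstm1f_Wx), 18L)
  # static features enter after the decoder: head width tracks static_dim
  s5 <- build_model(cop_model_spec("resnet", "bilstm"), static_dim = 5L, seed = 1)
  expect_equal(nrow(wa$params$head1_W) - nrow(s5$params$head1_W), 12L - 5L)
})

test_that("bidirectionality doubles the decoder output width", {
  bi <- build_model(cop_model_spec("cnn2d", "bilstm", hidden_dim = 16L),
                    static_dim = 12L, seed = 1)
  un <- build_model(cop_model_spec("cnn2d", "lstm", hidden_dim = 16L),
                    static_dim = 12L, seed = 1)
  expect_equal(bi$dec_out_dim, 2L * un$dec_out_dim)
})

test_that("window extraction respects trial boundaries and the count formula", {
  recs <- list(fake_record(1120, "S01"), fake_record(1120, "S02", 3L))
  ds <- window_dataset(recs, window_len = 28L, window_stride = 14L)
  expect_equal(sum(ds$index$record == 1), floor((1120 - 28) / 14) + 1)  # 79
  expect_equal(sum(ds$index$record == 2), 79L)
  # no window crosses a trial boundary
  expect_true(all(ds$index$start + 28L - 1L <= 1120L))
  # non-overlapping partition when stride = length
  dsn <- window_dataset(list(fake_record(100)), window_len = 20L, window_stride = 20L)
  expect_equal(nrow(dsn$index), 5L)
  expect_equal(dsn$index$start, seq(1L, 81L, by = 20L))
  expect_error(window_dataset(list(fake_record(20)), window_len = 28L), "window_len")
})

test_that("training is deterministic and overfits a single trial", {
  recs <- model_test_records()[1]
  cf <- train_config(lr = 5e-3, epochs = 60L, step_size = 40L, gamma = 0.5,
                     batch_size = 16L, window_len = 10L, window_stride = 10L,
                     seed = 5)
  sp <- cop_model_spec("cnn2d", "bilstm")
  f1 <- train_model(NULL, recs, cf, spec = sp)
  expect_false(any(!is.finite(f1$history)))
  # capacity check: a single trial is essentially memorised
  expect_lt(tail(f1$history, 1), 1)   # MSE < 1 mm^2
  f2 <- train_model(NULL, recs, cf, spec = sp)
  expect_identical(f1$model$params, f2$model$params)
  # learning-rate history follows the schedule
  expect_equal(f1$lr, lr_schedule(cf))
})

test_that("divergent training aborts with diagnostics instead of NaN weights", {
  recs <- model_test_records()[1]
  cf <- train_config(lr = 1e154, epochs = 4L, batch_size = 8L,
                     window_len = 10L, window_stride = 10L, seed = 5)
  expect_error(train_model(NULL, recs, cf, spec = cop_model_spec("cnn2d", "lstm")),
               "NaN|Inf")
})

test_that("prediction covers every frame of a trial", {
  recs <- model_test_records()
  cf <- train_config(lr = 3e-3, epochs = 2L, batch_size = 8L,
                     window_len = 12L, window_stride = 12L, seed = 5)
  fit <- train_model(NULL, recs[1:2], cf, spec = cop_model_spec("cnn2d", "lstm"))
  p <- predict_cop(fit$model, recs[[3]], 12L)
  expect_equal(dim(p), c(record_length(recs[[3]]), 2L))
  expect_false(anyNA(p))
  # T not a multiple of the window length
  p2 <- predict_cop(fit$model, recs[[3]], 13L)
  expect_false(anyNA(p2))
})

test_that("grid search is exhaustive and discriminates sabotaged settings", {
  recs <- model_test_records()
  specs <- list(cnn_lstm = cop_model_spec("cnn2d", "lstm"))
  cf <- train_config(lr = 3e-3, epochs = 2L, batch_size = 8L,
                     window_len = 10L, window_stride = 10L, seed = 2)
  g1 <- grid_search(list(lr = 3e-3), recs, specs, config = cf)
  expect_equal(nrow(g1$table), 1L)
  expect_equal(g1$best$cnn_lstm$config$lr, 3e-3)
  g2 <- grid_search(list(lr = c(3e-3, 1e-3), hidden_dim = c(8L, 16L)),
                    recs, specs, config = cf)
  expect_equal(nrow(g2$table), 4L)
  g3 <- grid_search(list(lr = c(3e-3, 1e3)), recs, specs, config = cf)
  expect_equal(g3$best$cnn_lstm$config$lr, 3e-3)
  expect_error(grid_search(list(), recs, specs), "non-empty")
})
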
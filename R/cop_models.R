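#' Specification of an encoder-decoder CoP regressor
#'
#' The four benchmarked architectures share one template: a per-frame
#' spatial encoder over the 64 x 64 pressure image (`cnn2d`: plain strided
#' convolutions; `resnet`: identity-shortcut residual blocks with stride-2
#' convolutions for all downsampling and no pooling layers; `none`: the
#' image is flattened to 4096 features), first-stage fusion that
#' concatenates the WMA CoP (and, in the WA condition, the 18 angular
#' features) to each frame's encoding, a recurrent decoder over the window
#' (`lstm` or `bilstm`; bidirectionality doubles the output width),
#' second-stage fusion that concatenates the static subject/settings
#' features to each frame's decoder output, and a fully connected head
#' emitting the per-frame (ML, AP) CoP in mm.
#'
#' @param encoder `"cnn2d"`, `"resnet"`, or `"none"`.
#' @param decoder `"lstm"` or `"bilstm"`.
#' @param encoder_dim per-frame spatial feature size D (ignored for
#'   `encoder = "none"`, where D = 4096).
#' @param hidden_dim recurrent state size.
#' @param n_layers recurrent depth.
#' @param use_angular include the 18 angular features (WA condition) or not
#'   (OT condition).
#' @param head_dim hidden width of the FC head.
#' @param channels convolution channel widths of the three encoder stages.
#' @return `cop_model_spec` object.
#' @export
cop_model_spec <- function(encoder = c("resnet", "cnn2d", "none"),
                           decoder = c("bilstm", "lstm"),
                           encoder_dim = 32L, hidden_dim = 32L, n_layers = 1L,
                           use_angular = TRUE, head_dim = 32L,
                           channels = c(6L, 12L, 18L)) {
  encoder <- match.arg(encoder)
  decoder <- match.arg(decoder)
  stopifnot(encoder_dim >= 1, hidden_dim >= 1, n_layers >= 1, head_dim >= 1)
  structure(list(encoder = encoder, decoder = decoder,
                 encoder_dim = as.integer(encoder_dim),
                 hidden_dim = as.integer(hidden_dim),
                 n_layers = as.integer(n_layers),
                 use_angular = isTRUE(use_angular),
                 head_dim = as.integer(head_dim),
                 channels = as.integer(channels)),
            class = "cop_model_spec")
}

#' The four benchmark architectures
#'
#' ResNet-Bi-LSTM, CNN-Bi-LSTM, CNN-LSTM, and the no-encoder Bi-LSTM
#' baseline that consumes flattened pressure images.
#'
#' @param use_angular input condition (WA = `TRUE`, OT = `FALSE`).
#' @param ... passed to [cop_model_spec()].
#' @return named list of `cop_model_spec`s.
#' @export
model_zoo <- function(use_angular = TRUE, ...) {
  list(resnet_bilstm = cop_model_spec("resnet", "bilstm", use_angular = use_angular, ...),
       cnn_bilstm = cop_model_spec("cnn2d", "bilstm", use_angular = use_angular, ...),
       cnn_lstm = cop_model_spec("cnn2d", "lstm", use_angular = use_angular, ...),
       bilstm = cop_model_spec("none", "bilstm", use_angular = use_angular, ...))
}

#' Training configuration
#'
#' @param lr initial Adam learning rate.
#' @param step_size epochs between learning-rate decays (StepLR schedule).
#' @param gamma multiplicative decay factor in `(0, 1]`.
#' @param epochs training epochs.
#' @param batch_size windows per minibatch.
#' @param window_len,window_stride training window length/stride, frames.
#' @param windows_per_epoch optional cap on windows visited per epoch
#'   (sampled without replacement); `NULL` uses all.
#' @param seed RNG seed for initialisation, shuffling and sampling.
#' @export
train_config <- function(lr = 1e-3, step_size = 10L, gamma = 0.5, epochs = 20L,
                         batch_size = 16L, window_len = 28L, window_stride = 14L,
                         windows_per_epoch = NULL, seed = 1L) {
  assert_scalar_number(lr, "lr", positive = TRUE)
  if (gamma <= 0 || gamma > 1) abort_invalid("gamma must be in (0, 1]")
  if (window_len < 2) abort_invalid("window_len must be >= 2")
  structure(list(lr = lr, step_size = as.integer(step_size), gamma = gamma,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 window_len = as.integer(window_len),
                 window_stride = as.integer(window_stride),
                 windows_per_epoch = windows_per_epoch, seed = as.integer(seed)),
            class = "train_config")
}

#' StepLR learning-rate schedule
#' @param config a [train_config()].
#' @return per-epoch learning rates (`lr * gamma^floor((epoch-1)/step_size)`).
#' @export
lr_schedule <- function(config) {
  e <- seq_len(config$epochs)
  config$lr * config$gamma^((e - 1L) %/% config$step_size)
}

# ---- windowing -------------------------------------------------------------

#' Cut synchronized trials into overlapping training windows
#'
#' Windows of `window_len` frames at `window_stride` within each trial; no
#' window spans two trials. Subject and protocol identity travel with each
#' window for fold assignment.
#'
#' @param records list of `trial_record`s.
#' @param window_len,window_stride frames.
#' @return `window_dataset`: the records plus an index data.frame
#'   (`record`, `start`, `subject_id`, `protocol_id`).
#' @export
window_dataset <- function(records, window_len = 28L, window_stride = 14L) {
  stopifnot(length(records) >= 1L)
  window_len <- as.integer(window_len); window_stride <- as.integer(window_stride)
  Ts <- vapply(records, record_length, integer(1))
  if (window_len > min(Ts))
    abort_invalid(sprintf("window_len %d exceeds the shortest trial (T=%d)",
                          window_len, min(Ts)))
  idx <- do.call(rbind, lapply(seq_along(records), function(r) {
    starts <- seq(1L, Ts[r] - window_len + 1L, by = window_stride)
    data.frame(record = r, start = starts,
               subject_id = records[[r]]$subject$subject_id,
               protocol_id = records[[r]]$settings$protocol_id,
               stringsAsFactors = FALSE)
  }))
  structure(list(records = records, index = idx, window_len = window_len,
                 window_stride = window_stride),
            class = "window_dataset")
}

# ---- feature scaling -------------------------------------------------------

# static feature vector of one record: the six subject characteristics
# (weight, gender, lean mass, upper/lower limb length, waist-hip ratio),
# protocol one-hot, and the sensor dimensions
static_features <- function(rec) {
  s <- rec$subject
  proto <- numeric(4); proto[rec$settings$protocol_id] <- 1
  c(weight = s$weight, lean_mass = s$lean_mass,
    upper_limb_length = s$upper_limb_length,
    lower_limb_length = s$lower_limb_length,
    waist_hip_ratio = s$waist_hip_ratio,
    gender_m = as.numeric(s$gender == "M"),
    protocol_1 = proto[1], protocol_2 = proto[2],
    protocol_3 = proto[3], protocol_4 = proto[4],
    sensor_width_mm = rec$settings$sensor_width_mm,
    sensor_length_mm = rec$settings$sensor_length_mm)
}

# z-scoring statistics fitted on the training records only
fit_scalers <- function(records) {
  wma <- do.call(rbind, lapply(records, `[[`, "tactile_wma_cop"))
  ang <- do.call(rbind, lapply(records, `[[`, "angular_features"))
  sta <- do.call(rbind, lapply(records, static_features))
  zstat <- function(m) {
    mu <- colMeans(m); sd <- apply(m, 2L, stats::sd)
    sd[!is.finite(sd) | sd < 1e-9] <- 1
    list(mu = mu, sd = sd)
  }
  # one-hot / binary static columns are passed through unscaled
  sta_stat <- zstat(sta)
  pass <- grepl("^(gender_|protocol_)", colnames(sta))
  sta_stat$mu[pass] <- 0; sta_stat$sd[pass] <- 1
  list(wma = zstat(wma), ang = zstat(ang), static = sta_stat)
}

zapply <- function(m, st) sweep(sweep(m, 2L, st$mu), 2L, st$sd, `/`)

# materialise a minibatch: rows index into ds$index
make_batch <- function(ds, rows, scalers, use_angular) {
  Tw <- ds$window_len
  B <- length(rows)
  sel <- ds$index[rows, , drop = FALSE]
  pieces_f <- vector("list", B); pieces_w <- vector("list", B)
  pieces_a <- vector("list", B); pieces_y <- vector("list", B)
  sta <- matrix(0, B, length(static_features(ds$records[[1]])))
  for (b in seq_len(B)) {
    rec <- ds$records[[sel$record[b]]]
    span <- sel$start[b]:(sel$start[b] + Tw - 1L)
    pieces_f[[b]] <- record_frames01(rec, span)
    pieces_w[[b]] <- rec$tactile_wma_cop[span, , drop = FALSE]
    if (use_angular) pieces_a[[b]] <- rec$angular_features[span, , drop = FALSE]
    pieces_y[[b]] <- rec$truth_cop[span, , drop = FALSE]
    sta[b, ] <- static_features(rec)
  }
  list(frames = do.call(rbind, pieces_f),
       wma = zapply(do.call(rbind, pieces_w), scalers$wma),
       ang = if (use_angular) zapply(do.call(rbind, pieces_a), scalers$ang) else NULL,
       static = zapply(sta, scalers$static),
       target = do.call(rbind, pieces_y),
       B = B, Tw = Tw)
}

# ---- model construction ----------------------------------------------------

#' Build an encoder-decoder CoP model
#'
#' Initialises all parameters (He-scaled convolutions and FC layers,
#' uniform LSTM weights with forget-gate bias 1) and precomputes the
#' convolution index plans for the 64 x 64 input.
#'
#' @param spec a [cop_model_spec()].
#' @param static_dim number of static features concatenated after the
#'   decoder.
#' @param seed initialisation seed.
#' @param in_h,in_w input image size.
#' @return `cop_model` object (parameters, plans, spec).
#' @export
build_model <- function(spec, static_dim = 12L, seed = 1L, in_h = 64L, in_w = 64L) {
  stopifnot(inherits(spec, "cop_model_spec"))
  ch <- spec$channels
  plans <- list()
  params <- list()
  conv_seq <- NULL
  with_seed(derive_seed(seed, "init", spec$encoder, spec$decoder), {
    if (spec$encoder %in% c("cnn2d", "resnet")) {
      # all downsampling by strided convolutions; residual blocks (identity
      # shortcuts) sit after the resolution has dropped to keep desk-scale
      # training tractable
      conv_seq <- if (spec$encoder == "resnet")
        list(list(op = "conv", name = "stem"),
             list(op = "conv", name = "down1"),
             list(op = "block", name = "blk1"),
             list(op = "conv", name = "down2"),
             list(op = "block", name = "blk2"),
             list(op = "block", name = "blk3"))
      else
        list(list(op = "conv", name = "stem"),
             list(op = "conv", name = "conv2"),
             list(op = "conv", name = "conv3"))
      geomspec <- list(
        stem = list(in_ch = 1L, out_ch = ch[1], k = 5L, stride = 4L, pad = 2L),
        down1 = list(in_ch = ch[1], out_ch = ch[2], k = 3L, stride = 2L, pad = 1L),
        blk1 = list(in_ch = ch[2], out_ch = ch[2], k = 3L, stride = 1L, pad = 1L),
        down2 = list(in_ch = ch[2], out_ch = ch[3], k = 3L, stride = 2L, pad = 1L),
        blk2 = list(in_ch = ch[3], out_ch = ch[3], k = 3L, stride = 1L, pad = 1L),
        blk3 = list(in_ch = ch[3], out_ch = ch[3], k = 3L, stride = 1L, pad = 1L),
        conv2 = list(in_ch = ch[1], out_ch = ch[2], k = 3L, stride = 2L, pad = 1L),
        conv3 = list(in_ch = ch[2], out_ch = ch[3], k = 3L, stride = 2L, pad = 1L))
      cur_h <- in_h; cur_w <- in_w; cur_c <- 1L
      for (st in conv_seq) {
        gs <- geomspec[[st$name]]
        pln <- make_conv_plan(cur_h, cur_w, gs$in_ch, gs$k, gs$k, gs$out_ch,
                              gs$stride, gs$pad)
        if (st$op == "conv") {
          plans[[st$name]] <- pln
          params[[paste0(st$name, "_W")]] <- he_init(pln$K, gs$out_ch)
          params[[paste0(st$name, "_b")]] <- numeric(gs$out_ch)
        } else {
          for (half in c("a", "b")) {
            plans[[paste0(st$name, half)]] <- pln
            params[[paste0(st$name, half, "_W")]] <- he_init(pln$K, gs$out_ch)
            params[[paste0(st$name, half, "_b")]] <- numeric(gs$out_ch)
          }
        }
        cur_h <- pln$out_h; cur_w <- pln$out_w; cur_c <- gs$out_ch
      }
      flat_dim <- cur_h * cur_w * cur_c
      params$enc_fc_W <- he_init(flat_dim, spec$encoder_dim)
      params$enc_fc_b <- numeric(spec$encoder_dim)
      D <- spec$encoder_dim
    } else D <- in_h * in_w

    fuse_dim <- D + 2L + if (spec$use_angular) 18L else 0L
    din <- fuse_dim
    for (l in seq_len(spec$n_layers)) {
      if (spec$decoder == "bilstm") {
        params <- init_lstm_params(paste0("lstm", l, "f"), din, spec$hidden_dim, params)
        params <- init_lstm_params(paste0("lstm", l, "r"), din, spec$hidden_dim, params)
        din <- 2L * spec$hidden_dim
      } else {
        params <- init_lstm_params(paste0("lstm", l, "f"), din, spec$hidden_dim, params)
        din <- spec$hidden_dim
      }
    }
    dec_out <- din
    params$head1_W <- he_init(dec_out + static_dim, spec$head_dim)
    params$head1_b <- numeric(spec$head_dim)
    params$out_W <- 0.01 * he_init(spec$head_dim, 2L)
    params$out_b <- numeric(2L)
  })
  structure(list(spec = spec, params = params, plans = plans,
                 conv_seq = conv_seq,
                 static_dim = as.integer(static_dim),
                 fuse_dim = D + 2L + if (spec$use_angular) 18L else 0L,
                 dec_out_dim = if (spec$decoder == "bilstm")
                   2L * spec$hidden_dim else spec$hidden_dim,
                 scalers = NULL),
            class = "cop_model")
}

#' @export
print.cop_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<cop_model> %s-%s%s, %d parameters\n", x$spec$encoder,
              x$spec$decoder, if (x$spec$use_angular) " (WA)" else " (OT)", np))
  invisible(x)
}

#' Layer inventory of a model
#'
#' Lists every operator in forward order with its type; used to verify
#' architectural contracts (e.g. that the ResNet encoder contains no
#' pooling operators).
#'
#' @param model a [build_model()] result.
#' @return data.frame with `name` and `type`.
#' @export
model_inventory <- function(model) {
  sp <- model$spec
  rows <- list()
  add <- function(name, type) rows[[length(rows) + 1L]] <<- data.frame(name = name, type = type)
  if (sp$encoder == "none") add("flatten", "flatten")
  if (sp$encoder %in% c("cnn2d", "resnet")) {
    for (st in model$conv_seq)
      add(st$name, if (st$op == "block") "residual_block" else "conv_strided")
    add("enc_fc", "fully_connected")
  }
  add("fusion_wma_angular", "concat")
  for (l in seq_len(sp$n_layers))
    add(paste0(sp$decoder, l), if (sp$decoder == "bilstm") "bilstm" else "lstm")
  add("fusion_static", "concat")
  add("head", "fully_connected")
  add("out", "fully_connected")
  do.call(rbind, rows)
}

# ---- forward / backward ----------------------------------------------------

conv_relu_fwd <- function(X, params, plans, nm, cache) {
  cv <- conv_fwd(X, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]], plans[[nm]])
  rl <- relu_fwd(cv$Y)
  cache[[nm]] <- list(M = cv$M, mask = rl$mask, N = ncol(X))
  list(Y = rl$Y, cache = cache)
}

forward_cop_model <- function(model, batch) {
  sp <- model$spec; pm <- model$params; pl <- model$plans
  cache <- list()
  N <- nrow(batch$frames)
  if (sp$encoder == "none") {
    FT <- batch$frames
  } else {
    # conv path runs on transposed (features x N) activations
    X <- t(batch$frames)
    for (st in model$conv_seq) {
      if (st$op == "conv") {
        r <- conv_relu_fwd(X, pm, pl, st$name, cache); X <- r$Y; cache <- r$cache
      } else {
        ident <- X
        a <- conv_relu_fwd(X, pm, pl, paste0(st$name, "a"), cache); cache <- a$cache
        bnm <- paste0(st$name, "b")
        cv <- conv_fwd(a$Y, pm[[paste0(bnm, "_W")]], pm[[paste0(bnm, "_b")]], pl[[bnm]])
        S <- cv$Y + ident
        rl <- relu_fwd(S)
        cache[[bnm]] <- list(M = cv$M, mask = rl$mask, N = N)
        X <- rl$Y
      }
    }
    cache$enc_flat <- t(X)
    FE <- fc_fwd(cache$enc_flat, pm$enc_fc_W, pm$enc_fc_b)
    rl <- relu_fwd(FE)
    cache$enc_fc_mask <- rl$mask
    FT <- rl$Y
  }
  Z <- if (sp$use_angular) cbind(FT, batch$wma, batch$ang) else cbind(FT, batch$wma)
  cache$Z <- Z
  Xd <- Z
  for (l in seq_len(sp$n_layers)) {
    f <- lstm_fwd(Xd, pm[[paste0("lstm", l, "f_Wx")]], pm[[paste0("lstm", l, "f_Wh")]],
                  pm[[paste0("lstm", l, "f_b")]], batch$B, batch$Tw, reverse = FALSE)
    cache[[paste0("lstm", l, "f")]] <- list(cache = f$cache, X = Xd)
    if (sp$decoder == "bilstm") {
      rv <- lstm_fwd(Xd, pm[[paste0("lstm", l, "r_Wx")]], pm[[paste0("lstm", l, "r_Wh")]],
                     pm[[paste0("lstm", l, "r_b")]], batch$B, batch$Tw, reverse = TRUE)
      cache[[paste0("lstm", l, "r")]] <- list(cache = rv$cache, X = Xd)
      Xd <- cbind(f$Y, rv$Y)
    } else Xd <- f$Y
  }
  static_rep <- batch$static[rep(seq_len(batch$B), each = batch$Tw), , drop = FALSE]
  U <- cbind(Xd, static_rep)
  cache$U <- U
  H1 <- fc_fwd(U, pm$head1_W, pm$head1_b)
  rl1 <- relu_fwd(H1)
  cache$head1_mask <- rl1$mask
  cache$H1 <- rl1$Y
  pred <- fc_fwd(rl1$Y, pm$out_W, pm$out_b)
  list(pred = pred, cache = cache)
}

backward_cop_model <- function(model, batch, cache, dPred) {
  sp <- model$spec; pm <- model$params; pl <- model$plans
  gr <- list()
  N <- nrow(batch$frames)
  bo <- fc_bwd(dPred, cache$H1, pm$out_W)
  gr$out_W <- bo$dW; gr$out_b <- bo$db
  dH1 <- relu_bwd(bo$dX, cache$head1_mask)
  bh <- fc_bwd(dH1, cache$U, pm$head1_W)
  gr$head1_W <- bh$dW; gr$head1_b <- bh$db
  dU <- bh$dX
  dXd <- dU[, seq_len(model$dec_out_dim), drop = FALSE]
  for (l in rev(seq_len(sp$n_layers))) {
    hn <- sp$hidden_dim
    if (sp$decoder == "bilstm") {
      cf <- cache[[paste0("lstm", l, "f")]]; cr <- cache[[paste0("lstm", l, "r")]]
      bf <- lstm_bwd(dXd[, seq_len(hn), drop = FALSE], cf$X,
                     pm[[paste0("lstm", l, "f_Wx")]], pm[[paste0("lstm", l, "f_Wh")]],
                     pm[[paste0("lstm", l, "f_b")]], batch$B, batch$Tw, cf$cache, FALSE)
      br <- lstm_bwd(dXd[, hn + seq_len(hn), drop = FALSE], cr$X,
                     pm[[paste0("lstm", l, "r_Wx")]], pm[[paste0("lstm", l, "r_Wh")]],
                     pm[[paste0("lstm", l, "r_b")]], batch$B, batch$Tw, cr$cache, TRUE)
      gr[[paste0("lstm", l, "f_Wx")]] <- bf$dWx; gr[[paste0("lstm", l, "f_Wh")]] <- bf$dWh
      gr[[paste0("lstm", l, "f_b")]] <- bf$db
      gr[[paste0("lstm", l, "r_Wx")]] <- br$dWx; gr[[paste0("lstm", l, "r_Wh")]] <- br$dWh
      gr[[paste0("lstm", l, "r_b")]] <- br$db
      dXd <- bf$dX + br$dX
    } else {
      cf <- cache[[paste0("lstm", l, "f")]]
      bf <- lstm_bwd(dXd, cf$X, pm[[paste0("lstm", l, "f_Wx")]],
                     pm[[paste0("lstm", l, "f_Wh")]], pm[[paste0("lstm", l, "f_b")]],
                     batch$B, batch$Tw, cf$cache, FALSE)
      gr[[paste0("lstm", l, "f_Wx")]] <- bf$dWx; gr[[paste0("lstm", l, "f_Wh")]] <- bf$dWh
      gr[[paste0("lstm", l, "f_b")]] <- bf$db
      dXd <- bf$dX
    }
  }
  # dXd now holds the gradient w.r.t. the fused per-frame features Z
  if (sp$encoder != "none") {
    D <- sp$encoder_dim
    dFT <- dXd[, seq_len(D), drop = FALSE]
    dFE <- relu_bwd(dFT, cache$enc_fc_mask)
    be <- fc_bwd(dFE, cache$enc_flat, pm$enc_fc_W)
    gr$enc_fc_W <- be$dW; gr$enc_fc_b <- be$db
    dX <- t(be$dX)  # back into the (features x N) conv orientation
    back_conv_relu <- function(dY, nm) {
      c0 <- cache[[nm]]
      dYr <- relu_bwd(dY, c0$mask)
      cb <- conv_bwd(dYr, c0$M, pm[[paste0(nm, "_W")]], pl[[nm]], c0$N)
      gr[[paste0(nm, "_W")]] <<- cb$dW; gr[[paste0(nm, "_b")]] <<- cb$db
      cb$dX
    }
    for (st in rev(model$conv_seq)) {
      if (st$op == "conv") {
        dX <- back_conv_relu(dX, st$name)
      } else {
        bnm <- paste0(st$name, "b")
        c0 <- cache[[bnm]]
        dS <- relu_bwd(dX, c0$mask)
        cb <- conv_bwd(dS, c0$M, pm[[paste0(bnm, "_W")]], pl[[bnm]], c0$N)
        gr[[paste0(bnm, "_W")]] <- cb$dW; gr[[paste0(bnm, "_b")]] <- cb$db
        dA <- back_conv_relu(cb$dX, paste0(st$name, "a"))
        dX <- dA + dS  # identity shortcut
      }
    }
  }
  gr
}

# ---- training --------------------------------------------------------------

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a CoP model on synchronized trials
#'
#' Minimises the MSE (mm^2) between predicted and reference per-frame CoP
#' over overlapping windows, with Adam and a StepLR schedule. Feature
#' scalers (z-scores for WMA, angular and continuous static features) are
#' fitted on the training records only and stored with the model. The
#' output-layer bias is initialised at the training-set mean CoP.
#' Deterministic given `config$seed`.
#'
#' @param model a [build_model()] result (or `NULL` to build from `spec`).
#' @param records list of training `trial_record`s.
#' @param config a [train_config()].
#' @param spec used when `model` is `NULL`.
#' @param verbose print per-epoch loss.
#' @return list: `model` (trained), `history` (per-epoch mean loss), `lr`
#'   (per-epoch learning rate).
#' @export
train_model <- function(model, records, config, spec = NULL, verbose = FALSE) {
  if (is.null(model)) model <- build_model(spec, seed = config$seed)
  stopifnot(inherits(model, "cop_model"), inherits(config, "train_config"))
  use_ang <- model$spec$use_angular
  if (use_ang && is.null(records[[1]]$angular_features))
    abort_invalid("model requires angular features but records carry none")
  ds <- window_dataset(records, config$window_len, config$window_stride)
  scalers <- fit_scalers(records)
  model$scalers <- scalers
  # output bias at the training-mean CoP speeds convergence considerably
  ymean <- colMeans(do.call(rbind, lapply(records, `[[`, "truth_cop")))
  model$params$out_b <- as.numeric(ymean)
  n_win <- nrow(ds$index)
  lrs <- lr_schedule(config)
  history <- numeric(config$epochs)
  state <- adam_init(model$params)
  with_seed(derive_seed(config$seed, "train"), {
    for (e in seq_len(config$epochs)) {
      take <- if (!is.null(config$windows_per_epoch) && config$windows_per_epoch < n_win)
        sample.int(n_win, config$windows_per_epoch) else sample.int(n_win)
      losses <- numeric(0)
      for (i0 in seq(1L, length(take), by = config$batch_size)) {
        rows <- take[i0:min(i0 + config$batch_size - 1L, length(take))]
        batch <- make_batch(ds, rows, scalers, use_ang)
        fw <- forward_cop_model(model, batch)
        err <- fw$pred - batch$target
        loss <- mean(err^2)
        if (!is.finite(loss))
          stop(sprintf("NaN/Inf loss at epoch %d (lr=%.3g, batch mean target=%.2f): aborting",
                       e, lrs[e], mean(batch$target)))
        losses <- c(losses, loss)
        dPred <- 2 * err / length(err)
        gr <- backward_cop_model(model, batch, fw$cache, dPred)
        upd <- adam_step(model$params, gr, state, lrs[e])
        model$params <- upd$params; state <- upd$state
      }
      history[e] <- mean(losses)
      if (verbose) message(sprintf("epoch %d: loss %.3f (lr %.2g)", e, history[e], lrs[e]))
    }
  })
  list(model = model, history = history, lr = lrs)
}

#' Predict per-frame CoP for a synchronized trial
#'
#' Covers the trial with non-overlapping windows (a final window is slid
#' back to end exactly at the last frame); overlapping frames take the
#' later window's prediction.
#'
#' @param model a trained [train_model()] model (with scalers).
#' @param rec a `trial_record`.
#' @param window_len window length, frames.
#' @return `T x 2` matrix of (ML, AP) estimates, mm.
#' @export
predict_cop <- function(model, rec, window_len = 28L) {
  if (is.null(model$scalers)) abort_invalid("model has no fitted scalers; train it first")
  Tn <- record_length(rec)
  window_len <- min(as.integer(window_len), Tn)
  starts <- seq(1L, Tn - window_len + 1L, by = window_len)
  if (starts[length(starts)] + window_len - 1L < Tn)
    starts <- c(starts, Tn - window_len + 1L)
  ds <- list(records = list(rec),
             index = data.frame(record = 1L, start = starts),
             window_len = window_len)
  class(ds) <- "window_dataset"
  out <- matrix(NA_real_, Tn, 2L)
  # batch all windows at once
  batch <- make_batch(ds, seq_along(starts), model$scalers, model$spec$use_angular)
  fw <- forward_cop_model(model, batch)
  for (b in seq_along(starts)) {
    span <- starts[b]:(starts[b] + window_len - 1L)
    out[span, ] <- fw$pred[(b - 1L) * window_len + seq_len(window_len), ]
  }
  colnames(out) <- c("ml_mm", "ap_mm")
  out
}

#' Exhaustive grid search over training hyperparameters
#'
#' Evaluates every combination in `grid` (named lists of candidate values
#' for [train_config()] fields and/or `hidden_dim`/`n_layers` of the spec)
#' for each architecture, with an inner subject-held-out validation split,
#' and returns the argmin-validation-RMSE configuration per architecture
#' plus the full result table. The identical grid is applied to every
#' architecture.
#'
#' @param grid named list, e.g. `list(lr = c(1e-3, 3e-4), hidden_dim = c(32, 64))`.
#' @param records list of `trial_record`s.
#' @param specs named list of [cop_model_spec()]s.
#' @param val_subjects subject ids held out for validation (default: the
#'   last subject present).
#' @param config base [train_config()] overridden by grid entries.
#' @return list: `best` (per-architecture best settings), `table`
#'   (architecture x combination results).
#' @export
grid_search <- function(grid, records, specs, val_subjects = NULL,
                        config = train_config()) {
  if (!length(grid)) abort_invalid("grid must be non-empty")
  subj <- vapply(records, function(r) r$subject$subject_id, character(1))
  if (is.null(val_subjects)) val_subjects <- utils::tail(unique(subj), 1L)
  tr_rec <- records[!subj %in% val_subjects]
  va_rec <- records[subj %in% val_subjects]
  if (!length(tr_rec) || !length(va_rec))
    abort_invalid("validation split leaves an empty side")
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  rows <- list()
  best <- list()
  for (an in names(specs)) {
    best_rmse <- Inf
    for (ci in seq_len(nrow(combos))) {
      cmb <- as.list(combos[ci, , drop = FALSE])
      sp <- specs[[an]]
      for (f in intersect(names(cmb), c("hidden_dim", "n_layers", "encoder_dim")))
        sp[[f]] <- as.integer(cmb[[f]])
      cf <- config
      for (f in intersect(names(cmb), names(config))) cf[[f]] <- cmb[[f]]
      # a diverging combination (NaN loss abort) scores Inf rather than
      # killing the whole search
      rmse <- tryCatch({
        fit <- train_model(NULL, tr_rec, cf, spec = sp)
        mean(vapply(va_rec, function(r) {
          p <- predict_cop(fit$model, r, cf$window_len)
          sqrt(mean((p - r$truth_cop)^2))
        }, numeric(1)))
      }, error = function(e) Inf)
      rows[[length(rows) + 1L]] <- cbind(data.frame(architecture = an),
                                         combos[ci, , drop = FALSE],
                                         data.frame(val_rmse = rmse))
      if (rmse < best_rmse) {
        best_rmse <- rmse
        best[[an]] <- list(spec = sp, config = cf, val_rmse = rmse)
      }
    }
  }
  list(best = best, table = do.call(rbind, rows))
}
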
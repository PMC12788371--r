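#' Configuration of a full desk-scale experiment
#'
#' One configuration drives the whole pipeline: simulate a cohort, run
#' every trial through preprocessing and synchronization, train the chosen
#' architectures under the chosen input conditions with leave-one-subject-
#' out cross-validation, and evaluate. Desk-scale defaults (8 subjects,
#' 30 s trials with a 20 s analysis window, short training schedules) keep
#' a full run tractable on one CPU; `paper_scale = TRUE` restores the
#' 23-subject / 90 s / 80 s study design.
#'
#' @param n_subjects cohort size.
#' @param reps repetitions of each of the four protocols per subject.
#' @param duration_s,analysis_window_s trial length / analysed middle
#'   window, seconds.
#' @param noise a [noise_model()]; default [default_sensor_defects()].
#' @param models architectures to run (names of [model_zoo()]).
#' @param conditions input conditions: `"WA"` (with angular features),
#'   `"OT"` (tactile only).
#' @param train a [train_config()].
#' @param seed master seed; all stage seeds derive from it.
#' @param kp_noise_px pixel noise on simulated 2D keypoints.
#' @param output_dir where records, tables and figures are written
#'   (`NULL` = keep everything in memory only).
#' @param paper_scale use the full study design instead of desk defaults.
#' @export
experiment_config <- function(n_subjects = 8L, reps = 2L,
                              duration_s = 30, analysis_window_s = 20,
                              noise = NULL,
                              models = c("resnet_bilstm", "cnn_bilstm",
                                         "cnn_lstm", "bilstm"),
                              conditions = c("WA", "OT"),
                              train = NULL, seed = 1L, kp_noise_px = 0.3,
                              output_dir = NULL, paper_scale = FALSE) {
  if (paper_scale) { n_subjects <- 23L; duration_s <- 90; analysis_window_s <- 80 }
  models <- match.arg(models, several.ok = TRUE)
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (is.null(noise)) noise <- default_sensor_defects(seed)
  if (is.null(train))
    train <- train_config(lr = 1e-2, epochs = 10L, step_size = 4L, gamma = 0.5,
                          batch_size = 8L, window_len = 12L, window_stride = 12L,
                          windows_per_epoch = 96L, seed = seed)
  structure(list(n_subjects = as.integer(n_subjects), reps = as.integer(reps),
                 duration_s = duration_s, analysis_window_s = analysis_window_s,
                 noise = noise, models = models, conditions = conditions,
                 train = train, seed = as.integer(seed),
                 kp_noise_px = kp_noise_px, output_dir = output_dir),
            class = "experiment_config")
}

#' Enumerate the training jobs of an experiment
#'
#' Bookkeeping only (no computation): one job per LOOCV fold x architecture
#' x input condition.
#'
#' @param config an [experiment_config()].
#' @return data.frame with `fold`, `held_out_subject`, `model`, `condition`.
#' @export
experiment_plan <- function(config) {
  ids <- sprintf("S%02d", seq_len(config$n_subjects))
  folds <- loocv_split(ids)
  jobs <- expand.grid(fold = seq_along(folds), model = config$models,
                      condition = config$conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  jobs$held_out_subject <- ids[jobs$fold]
  jobs[, c("fold", "held_out_subject", "model", "condition")]
}

#' Simulate and assemble the full cohort of synchronized trial records
#'
#' @param config an [experiment_config()].
#' @param progress print progress lines.
#' @return list of `trial_record`s (n_subjects x 4 protocols x reps), with
#'   subject/protocol identity inside each record.
#' @export
simulate_cohort_records <- function(config, progress = FALSE) {
  cohort <- make_cohort(config$n_subjects, seed = derive_seed(config$seed, "cohort"))
  sched <- protocol_schedule(config$reps)
  cams <- default_stereo_rig()
  records <- vector("list", nrow(sched) * config$n_subjects)
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    for (j in seq_len(nrow(sched))) {
      k <- k + 1L
      pr <- protocol_spec(sched$protocol_id[j], duration_s = config$duration_s,
                          analysis_window_s = config$analysis_window_s)
      trial <- suppressWarnings(simulate_trial(
        cohort[s, ], pr, config$noise, seed = derive_seed(config$seed, "trial", s, j),
        cameras = cams, kp_noise_px = config$kp_noise_px))
      records[[k]] <- assemble_trial(trial, cameras = cams)
      if (progress) message(sprintf("simulated %s %s rep %d",
                                    cohort$subject_id[s], sched$protocol_id[j],
                                    sched$rep[j]))
    }
  }
  records
}

record_subject <- function(rec) rec$subject$subject_id

#' Run the full experiment: simulate, train, cross-validate, evaluate
#'
#' Reproduces the study's experimental design at the configured scale:
#' LOOCV over subjects, the chosen architectures under WA/OT input
#' conditions, per-direction and per-stratum metrics, the WMA baseline, the
#' summary tables, and (when all four architectures and both conditions are
#' present) the two-way repeated-measures ANOVA per direction. Re-running
#' with the same configuration reproduces the same report.
#'
#' @param config an [experiment_config()].
#' @param records optionally reuse pre-simulated records.
#' @param progress print progress lines.
#' @return `eval_report`: list with `fold_results`, `summary`,
#'   `directional_gap`, `anova` (or NULL), `wma_baseline`, `predictions`
#'   (representative subject), `config`.
#' @export
run_experiment <- function(config, records = NULL, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(records)) records <- simulate_cohort_records(config, progress)
    subj <- vapply(records, record_subject, character(1))
    ids <- unique(subj)
    folds <- loocv_split(ids)
    fold_rows <- list(); preds_keep <- NULL
    for (fi in seq_along(folds)) {
      fold <- folds[[fi]]
      tr_rec <- records[subj %in% fold$train]
      va_rec <- records[subj == fold$val]
      va_proto <- vapply(va_rec, function(r) r$settings$protocol_id, integer(1))
      va_truth <- lapply(va_rec, `[[`, "truth_cop")
      # WMA baseline once per fold
      stage <- "baseline"
      wma_pred <- lapply(va_rec, `[[`, "tactile_wma_cop")
      sm <- subject_metrics(va_truth, wma_pred, va_proto)
      sm$subject <- fold$val; sm$model <- "wma_baseline"; sm$condition <- "baseline"
      fold_rows[[length(fold_rows) + 1L]] <- sm
      for (mn in config$models) for (cn in config$conditions) {
        stage <- sprintf("train fold %s %s %s", fold$val, mn, cn)
        if (progress) message(stage)
        sp <- model_zoo(use_angular = (cn == "WA"))[[mn]]
        cf <- config$train
        cf$seed <- derive_seed(config$seed, "fit", fold$val, mn, cn)
        fit <- train_model(NULL, tr_rec, cf, spec = sp)
        pred <- lapply(va_rec, function(r) predict_cop(fit$model, r, cf$window_len))
        sm <- subject_metrics(va_truth, pred, va_proto)
        sm$subject <- fold$val; sm$model <- mn; sm$condition <- cn
        fold_rows[[length(fold_rows) + 1L]] <- sm
        if (fi == 1L && mn == config$models[1] && cn == config$conditions[1])
          preds_keep <- list(subject = fold$val, truth = va_truth, pred = pred,
                             protocol_ids = va_proto, model = mn, condition = cn)
      }
    }
    stage <- "summarize"
    fold_results <- do.call(rbind, fold_rows)
    summ <- stratify_and_summarize(fold_results)
    anova_tabs <- NULL
    if (length(config$models) == 4L && length(config$conditions) == 2L) {
      anova_tabs <- lapply(c(ml = "ml", ap = "ap"), function(d) {
        cells <- fold_results[fold_results$stratum == "overall" &
                                fold_results$direction == d &
                                fold_results$model != "wma_baseline", ]
        rm_anova_2way(data.frame(subject = cells$subject, model = cells$model,
                                 condition = cells$condition, value = cells$rmse_mm))
      })
    }
    report <- structure(list(fold_results = fold_results,
                             summary = summ$summary,
                             directional_gap = summ$directional_gap,
                             anova = anova_tabs,
                             predictions = preds_keep,
                             config = config),
                        class = "eval_report")
    if (!is.null(config$output_dir)) write_report(report, config$output_dir)
    report
  }, error = function(e) {
    stop(sprintf("experiment failed at stage [%s]: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  res
}

#' @export
print.eval_report <- function(x, ...) {
  ov <- x$summary[x$summary$stratum == "overall", ]
  cat("<eval_report> overall RMSE (mm), mean (SD) across subjects:\n")
  for (r in seq_len(nrow(ov)))
    cat(sprintf("  %-14s %-8s %-3s %6.2f (%.2f)\n", ov$model[r], ov$condition[r],
                toupper(ov$direction[r]), ov$rmse_mm_mean[r], ov$rmse_mm_sd[r]))
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$fold_results, file.path(dir, "fold_results.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(report$directional_gap, file.path(dir, "directional_gap.csv"),
                   row.names = FALSE)
  if (!is.null(report$anova)) {
    utils::write.csv(report$anova$ml, file.path(dir, "anova_ml.csv"), row.names = FALSE)
    utils::write.csv(report$anova$ap, file.path(dir, "anova_ap.csv"), row.names = FALSE)
  }
  manifest <- list(seed = report$config$seed,
                   n_subjects = report$config$n_subjects,
                   models = report$config$models,
                   conditions = report$config$conditions,
                   package_version = as.character(utils::packageVersion("copmat")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  figs <- make_report(report)
  for (nm in names(figs))
    ggplot2::ggsave(file.path(dir, paste0(nm, ".png")), figs[[nm]],
                    width = 8, height = 5, dpi = 110)
  invisible(dir)
}

#' Figures for an evaluation report
#'
#' Stabilogram overlays (ground truth vs estimate per protocol for the
#' stored representative subject), RMSE summaries by model and condition
#' (split into static and dynamic strata), and the absolute-error versus
#' CoP-position scatter.
#'
#' @param report an `eval_report` from [run_experiment()].
#' @return named list of ggplot objects.
#' @export
make_report <- function(report) {
  if (is.null(report$fold_results) || !nrow(report$fold_results))
    abort_invalid("empty results")
  figs <- list()
  fr <- report$fold_results
  ov <- fr[fr$stratum %in% c("static", "dynamic") & fr$model != "wma_baseline", ]
  if (nrow(ov)) {
    figs$rmse_by_model <- ggplot2::ggplot(
      ov, ggplot2::aes(x = model, y = rmse_mm, fill = condition)) +
      ggplot2::geom_boxplot(outlier.size = 0.6) +
      ggplot2::facet_grid(toupper(direction) ~ stratum) +
      ggplot2::labs(x = NULL, y = "RMSE (mm)", fill = "input") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  }
  pk <- report$predictions
  if (!is.null(pk)) {
    proto_names <- c("one_leg", "tandem", "squat", "walk_in_place")
    stab <- do.call(rbind, lapply(seq_along(pk$truth), function(i) {
      rbind(data.frame(protocol = proto_names[pk$protocol_ids[i]], kind = "truth",
                       ml = pk$truth[[i]][, 1], ap = pk$truth[[i]][, 2]),
            data.frame(protocol = proto_names[pk$protocol_ids[i]], kind = "estimate",
                       ml = pk$pred[[i]][, 1], ap = pk$pred[[i]][, 2]))
    }))
    figs$stabilograms <- ggplot2::ggplot(
      stab, ggplot2::aes(x = ml, y = ap, colour = kind)) +
      ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
      ggplot2::facet_wrap(~ protocol, scales = "free") +
      ggplot2::labs(x = "CoP ML (mm)", y = "CoP AP (mm)",
                    title = sprintf("Stabilograms, subject %s (%s, %s)",
                                    pk$subject, pk$model, pk$condition)) +
      ggplot2::theme_bw()
    errs <- do.call(rbind, lapply(seq_along(pk$truth), function(i)
      data.frame(dynamic = pk$protocol_ids[i] >= 3,
                 ml = pk$truth[[i]][, 1], ap = pk$truth[[i]][, 2],
                 err_ml = abs(pk$pred[[i]][, 1] - pk$truth[[i]][, 1]),
                 err_ap = abs(pk$pred[[i]][, 2] - pk$truth[[i]][, 2]))))
    figs$error_vs_position <- ggplot2::ggplot(
      errs, ggplot2::aes(x = ml, y = err_ml,
                         colour = ifelse(dynamic, "dynamic", "static"))) +
      ggplot2::geom_point(size = 0.4, alpha = 0.5) +
      ggplot2::labs(x = "ground-truth CoP ML (mm)", y = "absolute ML error (mm)",
                    colour = "stratum") +
      ggplot2::theme_bw()
  }
  figs
}

utils::globalVariables(c("model", "rmse_mm", "condition", "direction", "ml",
                         "ap", "kind", "err_ml", "dynamic", "protocol"))

#' Desk-scale model-ordering benchmark
#'
#' Runs the core LOOCV comparison on one simulated cohort: the chosen
#' (architecture, input condition) pairs are trained per fold with an
#' identical training budget and scored on the held-out subject, alongside
#' the training-free WMA baseline. Used to check that the learned models
#' recover the expected performance ordering (spatial encoders beat the
#' flattened baseline, which beats raw WMA under a nonlinear sensor).
#'
#' @param seed master seed for cohort, sensor defects and training.
#' @param n_subjects cohort size.
#' @param pairs list of `c(model, condition)` pairs to train.
#' @param config optional [experiment_config()] override.
#' @param records optionally reuse pre-simulated records.
#' @param progress print progress lines.
#' @return data.frame: `model`, `condition`, `direction`, `rmse_mm` (mean
#'   across validation subjects of the per-subject overall RMSE).
#' @export
benchmark_models <- function(seed, n_subjects = 8L,
                             pairs = list(c("resnet_bilstm", "WA"),
                                          c("resnet_bilstm", "OT"),
                                          c("bilstm", "WA")),
                             config = NULL, records = NULL, progress = FALSE) {
  if (is.null(config)) config <- experiment_config(n_subjects = n_subjects, seed = seed)
  if (is.null(records)) records <- simulate_cohort_records(config, progress)
  subj <- vapply(records, record_subject, character(1))
  folds <- loocv_split(unique(subj))
  acc <- list()
  add_row <- function(model, condition, direction, rmse)
    acc[[length(acc) + 1L]] <<- data.frame(model = model, condition = condition,
                                           direction = direction, rmse_mm = rmse,
                                           stringsAsFactors = FALSE)
  per_fold <- list()
  for (fold in folds) {
    tr_rec <- records[subj %in% fold$train]
    va_rec <- records[subj == fold$val]
    truth <- do.call(rbind, lapply(va_rec, `[[`, "truth_cop"))
    wma <- do.call(rbind, lapply(va_rec, `[[`, "tactile_wma_cop"))
    per_fold[[length(per_fold) + 1L]] <-
      c(list(wma_baseline.baseline = sqrt(colMeans((wma - truth)^2))),
        stats::setNames(lapply(pairs, function(pr) {
          if (progress) message(sprintf("fold %s: %s %s", fold$val, pr[1], pr[2]))
          sp <- model_zoo(use_angular = (pr[2] == "WA"))[[pr[1]]]
          cf <- config$train
          cf$seed <- derive_seed(config$seed, "fit", fold$val, pr[1], pr[2])
          fit <- train_model(NULL, tr_rec, cf, spec = sp)
          pred <- do.call(rbind, lapply(va_rec, function(r)
            predict_cop(fit$model, r, cf$window_len)))
          sqrt(colMeans((pred - truth)^2))
        }), vapply(pairs, paste, character(1), collapse = ".")))
  }
  keys <- names(per_fold[[1]])
  for (k in keys) {
    mat <- do.call(rbind, lapply(per_fold, `[[`, k))
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    add_row(parts[1], parts[2], "ml", mean(mat[, 1]))
    add_row(parts[1], parts[2], "ap", mean(mat[, 2]))
  }
  do.call(rbind, acc)
}
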
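#' Leave-one-subject-out folds
#'
#' Each subject serves once as the validation set while the remaining
#' subjects form the training set.
#'
#' @param subject_ids character vector of unique subject ids (>= 2).
#' @return list of folds, each `list(val = <id>, train = <ids>)`.
#' @export
loocv_split <- function(subject_ids) {
  ids <- as.character(subject_ids)
  if (anyDuplicated(ids)) abort_invalid("duplicate subject ids")
  if (length(ids) < 2L) abort_invalid("need >= 2 subjects for LOOCV")
  lapply(seq_along(ids), function(i) list(val = ids[i], train = ids[-i]))
}

#' CoP estimation error metrics
#'
#' RMSE (`sqrt(mean((y - y_hat)^2))`, mm), NRMSE (RMSE divided by the
#' ground-truth range `y_max - y_min`, in percent), and the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot`.
#'
#' For a constant ground-truth vector the range and total sum of squares
#' vanish: NRMSE and R^2 are then undefined and returned as `NA` with the
#' reason in the `undefined` field. `R^2` can be negative (a predictor
#' worse than the ground-truth mean).
#'
#' @param y ground truth values, mm.
#' @param y_hat estimates, mm.
#' @return list with `rmse_mm`, `nrmse_pct`, `r2`, `n`, `undefined`.
#' @export
compute_metrics <- function(y, y_hat) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat)) abort_invalid("y and y_hat lengths differ")
  n <- length(y)
  if (n < 2L) abort_invalid("need n >= 2")
  rmse <- sqrt(mean((y - y_hat)^2))
  rng <- max(y) - min(y)
  sstot <- sum((y - mean(y))^2)
  undefined <- character(0)
  nrmse <- if (rng > 0) rmse / rng * 100 else { undefined <- c(undefined, "nrmse"); NA_real_ }
  r2 <- if (sstot > 0) 1 - sum((y - y_hat)^2) / sstot
  else { undefined <- c(undefined, "r2"); NA_real_ }
  list(rmse_mm = rmse, nrmse_pct = nrmse, r2 = r2, n = n, undefined = undefined)
}

#' Per-direction, per-stratum metrics of one validation subject
#'
#' Concatenates the subject's validation trials within each stratum
#' (overall, static, dynamic, and each protocol) before computing metrics,
#' per direction.
#'
#' @param truth,pred lists of `T x 2` matrices (one per trial), mm.
#' @param protocol_ids integer protocol code per trial (1..4).
#' @return data.frame with `stratum`, `direction`, `rmse_mm`, `nrmse_pct`,
#'   `r2`, `n`.
#' @export
subject_metrics <- function(truth, pred, protocol_ids) {
  stopifnot(length(truth) == length(pred), length(truth) == length(protocol_ids))
  strata <- list(overall = 1:4, static = 1:2, dynamic = 3:4,
                 one_leg = 1L, tandem = 2L, squat = 3L, walk_in_place = 4L)
  out <- list()
  for (sn in names(strata)) {
    keep <- which(protocol_ids %in% strata[[sn]])
    if (!length(keep)) next
    yt <- do.call(rbind, truth[keep]); yp <- do.call(rbind, pred[keep])
    for (d in 1:2) {
      m <- compute_metrics(yt[, d], yp[, d])
      out[[length(out) + 1L]] <- data.frame(
        stratum = sn, direction = c("ml", "ap")[d],
        rmse_mm = m$rmse_mm, nrmse_pct = m$nrmse_pct, r2 = m$r2, n = m$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Summarize per-fold results across subjects
#'
#' Mean (SD) of each metric across validation subjects, per model, input
#' condition, stratum and direction, plus the directional gap
#' (ML metric minus AP metric) per model/condition/stratum.
#'
#' @param fold_results data.frame with columns `subject`, `model`,
#'   `condition`, `stratum`, `direction`, `rmse_mm`, `nrmse_pct`, `r2`.
#' @return list: `summary` (mean/SD table), `directional_gap`.
#' @export
stratify_and_summarize <- function(fold_results) {
  req <- c("subject", "model", "condition", "stratum", "direction", "rmse_mm")
  if (!all(req %in% names(fold_results)))
    abort_invalid(paste("fold_results must carry columns:", paste(req, collapse = ", ")))
  key <- c("model", "condition", "stratum", "direction")
  agg <- function(metric) {
    mn <- stats::aggregate(fold_results[[metric]],
                           fold_results[key], function(v) mean(v, na.rm = TRUE))
    sdv <- stats::aggregate(fold_results[[metric]],
                            fold_results[key], function(v) stats::sd(v, na.rm = TRUE))
    names(mn)[ncol(mn)] <- paste0(metric, "_mean")
    names(sdv)[ncol(sdv)] <- paste0(metric, "_sd")
    merge(mn, sdv, by = key)
  }
  s <- Reduce(function(a, b) merge(a, b, by = key),
              lapply(intersect(c("rmse_mm", "nrmse_pct", "r2"), names(fold_results)), agg))
  ml <- s[s$direction == "ml", ]
  ap <- s[s$direction == "ap", ]
  gap <- merge(ml, ap, by = c("model", "condition", "stratum"),
               suffixes = c("_ml", "_ap"))
  gap$rmse_gap_mm <- gap$rmse_mm_mean_ml - gap$rmse_mm_mean_ap
  if ("nrmse_pct_mean_ml" %in% names(gap))
    gap$nrmse_gap_pct <- gap$nrmse_pct_mean_ml - gap$nrmse_pct_mean_ap
  list(summary = s,
       directional_gap = gap[, c("model", "condition", "stratum", "rmse_gap_mm",
                                 intersect("nrmse_gap_pct", names(gap)))])
}

# orthonormal contrast basis (k x (k-1)) with columns orthogonal to 1
orth_contrasts <- function(k) {
  qr.Q(qr(cbind(rep(1, k), stats::contr.helmert(k))))[, -1, drop = FALSE]
}

#' Two-way repeated-measures ANOVA (Model x Input Condition)
#'
#' Within-subject sums-of-squares decomposition with the subject as the
#' blocking factor: each effect is tested against its own effect-by-subject
#' interaction (`F = MS_effect / MS_(effect x subject)`). Reported alongside
#' are Greenhouse-Geisser epsilons (from the covariance of the
#' orthonormally contrasted cell matrix) and the corrected p-values.
#'
#' @param cells data.frame with columns `subject`, `model`, `condition`,
#'   `value` (e.g. per-subject RMSE in one direction). The design must be
#'   complete and balanced: every subject x model x condition cell exactly
#'   once; missing cells are an error (no imputation).
#' @return data.frame with one row per effect (`model`, `condition`,
#'   `model:condition`): `df1`, `df2`, `ss`, `ms`, `F`, `p`, `gg_epsilon`,
#'   `p_gg`.
#' @export
rm_anova_2way <- function(cells) {
  req <- c("subject", "model", "condition", "value")
  if (!all(req %in% names(cells))) abort_invalid("cells needs subject/model/condition/value")
  cells$subject <- as.character(cells$subject)
  cells$model <- as.character(cells$model)
  cells$condition <- as.character(cells$condition)
  subs <- sort(unique(cells$subject)); mods <- sort(unique(cells$model))
  cnds <- sort(unique(cells$condition))
  n <- length(subs); a <- length(mods); b <- length(cnds)
  if (n < 3L) abort_invalid("need >= 3 subjects")
  if (nrow(cells) != n * a * b ||
      any(table(cells$subject, cells$model, cells$condition) != 1L))
    abort_invalid("design must be complete and balanced (one value per subject x model x condition)")
  Y <- array(NA_real_, dim = c(n, a, b))
  for (r in seq_len(nrow(cells)))
    Y[match(cells$subject[r], subs), match(cells$model[r], mods),
      match(cells$condition[r], cnds)] <- cells$value[r]
  g <- mean(Y)
  ys <- apply(Y, 1, mean); ym <- apply(Y, 2, mean); yc <- apply(Y, 3, mean)
  ysm <- apply(Y, c(1, 2), mean); ysc <- apply(Y, c(1, 3), mean)
  ymc <- apply(Y, c(2, 3), mean)
  ss_m <- n * b * sum((ym - g)^2)
  ss_c <- n * a * sum((yc - g)^2)
  ss_mc <- n * sum((ymc - outer(ym, yc, `+`) + g)^2)
  ss_subj <- a * b * sum((ys - g)^2)
  ss_ms <- b * sum((ysm - outer(ys, ym, `+`) + g)^2)
  ss_cs <- a * sum((ysc - outer(ys, yc, `+`) + g)^2)
  ss_tot <- sum((Y - g)^2)
  ss_mcs <- ss_tot - ss_m - ss_c - ss_mc - ss_subj - ss_ms - ss_cs
  eff <- data.frame(
    effect = c("model", "condition", "model:condition"),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = c((a - 1) * (n - 1), (b - 1) * (n - 1), (a - 1) * (b - 1) * (n - 1)),
    ss = c(ss_m, ss_c, ss_mc),
    ss_err = c(ss_ms, ss_cs, ss_mcs),
    stringsAsFactors = FALSE)
  eff$ms <- eff$ss / eff$df1
  eff$ms_err <- eff$ss_err / eff$df2
  eff$F <- eff$ms / eff$ms_err
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  # Greenhouse-Geisser epsilon per effect from the contrasted cell covariance
  cellmat <- matrix(Y, n, a * b)  # columns ordered (model fastest, condition slow)
  Qa <- orth_contrasts(a); Qb <- orth_contrasts(b)
  ones_a <- matrix(1 / a, a, 1); ones_b <- matrix(1 / b, b, 1)
  Cs <- list(model = kronecker(t(ones_b), t(Qa)),
             condition = kronecker(t(Qb), t(ones_a)),
             `model:condition` = kronecker(t(Qb), t(Qa)))
  Sig <- stats::cov(cellmat)
  eff$gg_epsilon <- vapply(Cs, function(C) {
    S <- C %*% Sig %*% t(C)
    q <- nrow(S)
    (sum(diag(S))^2) / (q * sum(S^2))
  }, numeric(1))
  eff$p_gg <- stats::pf(eff$F, eff$df1 * eff$gg_epsilon, eff$df2 * eff$gg_epsilon,
                        lower.tail = FALSE)
  eff
}
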
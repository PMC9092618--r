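# Fit, internal and external validation statistics, with the acceptance
# thresholds used for the odor-threshold model: 0.5 for Q2, rm2-family,
# R2pred and Q2F2; 0.750 for CCC; 0.2 cap for delta-rm2.

#' Classical fit statistics of a regression
#'
#' @param obs observed training responses.
#' @param fitted fitted values.
#' @param p number of predictors (for adjusted R2 and s).
#' @return list with `r2`, `r2_adj`, `s`, `f_ratio`.
#' @export
fit_stats <- function(obs, fitted, p) {
  n <- length(obs)
  stopifnot(length(fitted) == n)
  if (n <= p + 1) stopf("need n > p + 1")
  sse <- sum((obs - fitted)^2)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stopf("zero-variance response")
  r2 <- 1 - sse / sst
  list(r2 = r2,
       r2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
       s = sqrt(sse / (n - p - 1)),
       f_ratio = (r2 / p) / ((1 - r2) / (n - p - 1)))
}

#' External predictivity metrics
#'
#' R2pred (a.k.a. Q2F1) normalizes the test SSE by deviations from the
#' training mean; Q2F2 by deviations from the test mean; CCC is Lin's
#' concordance correlation coefficient (n-denominator moments), penalizing
#' both imprecision and location/scale shift.
#'
#' @param obs_test,pred_test observed and predicted test responses.
#' @param mean_y_train training-set response mean.
#' @return list with `r2_pred`, `q2_f2`, `ccc`, `rmsep`.
#' @export
external_metrics <- function(obs_test, pred_test, mean_y_train) {
  n <- length(obs_test)
  stopifnot(length(pred_test) == n, n >= 3)
  sse <- sum((obs_test - pred_test)^2)
  d_train <- sum((obs_test - mean_y_train)^2)
  d_test <- sum((obs_test - mean(obs_test))^2)
  if (d_train == 0 || d_test == 0) stopf("zero-variance denominator")
  sx <- mom_var(obs_test); sy <- mom_var(pred_test)
  sxy <- mom_cov(obs_test, pred_test)
  ccc <- 2 * sxy / (sx + sy + (mean(obs_test) - mean(pred_test))^2)
  list(r2_pred = 1 - sse / d_train,
       q2_f2 = 1 - sse / d_test,
       ccc = ccc,
       rmsep = sqrt(sse / n))
}

#' rm2 metrics and origin-forced regression statistics
#'
#' Following the rm2 family: r2 is the squared Pearson correlation; r0_2 is
#' the determination coefficient of the origin-forced regression of
#' predictions on observations (pred_hat = k * pred, k = sum(obs*pred)/
#' sum(pred^2), evaluated against obs) and r0p_2 the axes-swapped analogue
#' with k' = sum(obs*pred)/sum(obs^2); rm2 = r2*(1 - sqrt(|r2 - r0_2|)),
#' rm2' analogously. By default both vectors are min-max scaled to [0,1]
#' first (the scaled rm2 convention); set `scaled = FALSE` for raw-scale
#' values.
#'
#' @param obs,pred observed and predicted responses.
#' @param scaled min-max scale both vectors to [0,1] first (default TRUE).
#' @return list with `rm2`, `rm2_prime`, `rm2_avg`, `delta_rm2`, `r2`,
#'   `r0_2`, `r0p_2`, `k`, `k_prime`.
#' @export
rm2_metrics <- function(obs, pred, scaled = TRUE) {
  stopifnot(length(obs) == length(pred))
  if (diff(range(obs)) == 0 || diff(range(pred)) == 0)
    stopf("constant vector")
  if (scaled) {
    obs <- (obs - min(obs)) / diff(range(obs))
    pred <- (pred - min(pred)) / diff(range(pred))
  }
  r2 <- cor(obs, pred)^2
  sst_obs <- sum((obs - mean(obs))^2)
  sst_pred <- sum((pred - mean(pred))^2)
  k <- sum(obs * pred) / sum(pred^2)
  kp <- sum(obs * pred) / sum(obs^2)
  r0_2 <- 1 - sum((obs - k * pred)^2) / sst_obs
  r0p_2 <- 1 - sum((pred - kp * obs)^2) / sst_pred
  rm2 <- r2 * (1 - sqrt(abs(r2 - r0_2)))
  rm2p <- r2 * (1 - sqrt(abs(r2 - r0p_2)))
  list(rm2 = rm2, rm2_prime = rm2p, rm2_avg = mean(c(rm2, rm2p)),
       delta_rm2 = abs(rm2 - rm2p), r2 = r2, r0_2 = r0_2, r0p_2 = r0p_2,
       k = k, k_prime = kp)
}

#' Golbraikh-Tropsha external acceptability criteria
#'
#' Checks, on the raw (unscaled) test vectors: r2 > 0.6;
#' (r2 - r0_2)/r2 < 0.1 or (r2 - r0'_2)/r2 < 0.1; and 0.85 < k < 1.15 or
#' 0.85 < k' < 1.15, where k and k' are the origin-forced regression slopes.
#'
#' @param obs,pred observed and predicted test responses.
#' @return object of class `gt_verdict`: list of per-criterion values and
#'   verdicts plus overall `passed`.
#' @export
golbraikh_tropsha <- function(obs, pred) {
  m <- rm2_metrics(obs, pred, scaled = FALSE)
  ratio0 <- (m$r2 - m$r0_2) / m$r2
  ratio0p <- (m$r2 - m$r0p_2) / m$r2
  crit <- list(
    r2 = list(value = m$r2, passed = m$r2 > 0.6, rule = "r2 > 0.6"),
    ratio_r0 = list(value = ratio0, passed = ratio0 < 0.1,
                    rule = "(r2 - r0_2)/r2 < 0.1"),
    ratio_r0_prime = list(value = ratio0p, passed = ratio0p < 0.1,
                          rule = "(r2 - r0'_2)/r2 < 0.1"),
    k = list(value = m$k, passed = m$k > 0.85 && m$k < 1.15,
             rule = "0.85 < k < 1.15"),
    k_prime = list(value = m$k_prime,
                   passed = m$k_prime > 0.85 && m$k_prime < 1.15,
                   rule = "0.85 < k' < 1.15"))
  passed <- crit$r2$passed &&
    (crit$ratio_r0$passed || crit$ratio_r0_prime$passed) &&
    (crit$k$passed || crit$k_prime$passed)
  structure(list(criteria = crit, passed = passed), class = "gt_verdict")
}

#' @export
print.gt_verdict <- function(x, ...) {
  cat("Golbraikh-Tropsha criteria:\n")
  for (nm in names(x$criteria)) {
    cr <- x$criteria[[nm]]
    cat(sprintf("  %-16s %10.5f  %s  [%s]\n", nm, cr$value,
                if (cr$passed) "Passed" else "Failed", cr$rule))
  }
  cat(sprintf("Overall: %s\n", if (x$passed) "Passed" else "Failed"))
  invisible(x)
}

# vectorized classification shared with the compiled enumeration kernel
mae_class_from_stats <- function(mae, sd_err, rng) {
  good <- mae <= 0.1 * rng & mae + 3 * sd_err <= 0.2 * rng
  bad <- mae > 0.15 * rng | mae + 3 * sd_err > 0.25 * rng
  ifelse(good, "good", ifelse(bad, "bad", "moderate"))
}

#' MAE-based prediction-quality criteria
#'
#' The 5% largest absolute errors (count rounded half up) are dropped; on the
#' remainder, with MAE the mean and SD the standard deviation of the absolute
#' errors and `range` the training response range: predictions are `good`
#' when MAE <= 0.1*range and MAE + 3*SD <= 0.2*range, `bad` when
#' MAE > 0.15*range or MAE + 3*SD > 0.25*range, and `moderate` otherwise.
#'
#' @param abs_errors vector of absolute prediction errors (>= 5 values).
#' @param training_range range (max - min) of the training response.
#' @param trim_frac fraction of largest errors dropped (default 0.05).
#' @return list with `class` ("good"/"moderate"/"bad"), `mae`, `sd`,
#'   `n_dropped`.
#' @export
mae_criteria <- function(abs_errors, training_range, trim_frac = 0.05) {
  if (length(abs_errors) < 5) stopf("need at least 5 errors")
  if (training_range <= 0) stopf("training response range must be positive")
  stopifnot(all(abs_errors >= 0))
  n_drop <- floor(trim_frac * length(abs_errors) + 0.5)
  kept <- sort(abs_errors)[seq_len(length(abs_errors) - n_drop)]
  m <- mean(kept); s <- if (length(kept) > 1) sd(kept) else 0
  list(class = mae_class_from_stats(m, s, training_range),
       mae = m, sd = s, n_dropped = n_drop)
}

#' Full validation report for a train/test model
#'
#' Aggregates fit statistics, LOO-based internal validation, external
#' predictivity, rm2 metrics on both sets, the Golbraikh-Tropsha checklist
#' and the MAE-based classes, with pass/fail verdicts at the standard
#' thresholds (0.5 for Q2 / rm2-family / R2pred / Q2F2, 0.750 for CCC, 0.2
#' cap for delta-rm2).
#'
#' @param obs_train,fitted_train training observations and fitted values.
#' @param loo_pred leave-one-out predictions for the training compounds.
#' @param obs_test,pred_test test observations and predictions.
#' @param p number of model descriptors.
#' @return object of class `validation_report` (nested list; see fields).
#' @export
validation_report <- function(obs_train, fitted_train, loo_pred,
                              obs_test, pred_test, p) {
  fs <- fit_stats(obs_train, fitted_train, p)
  q2 <- 1 - sum((obs_train - loo_pred)^2) /
    sum((obs_train - mean(obs_train))^2)
  rm_loo <- rm2_metrics(obs_train, loo_pred)
  ext <- external_metrics(obs_test, pred_test, mean(obs_train))
  rm_test <- rm2_metrics(obs_test, pred_test)
  gt <- golbraikh_tropsha(obs_test, pred_test)
  rng <- diff(range(obs_train))
  mae_tr <- mae_criteria(abs(obs_train - loo_pred), rng)
  mae_te <- mae_criteria(abs(obs_test - pred_test), rng)
  verdicts <- list(
    q2 = q2 > 0.5, rm2_loo = rm_loo$rm2_avg > 0.5,
    delta_rm2_loo = rm_loo$delta_rm2 < 0.2,
    r2_pred = ext$r2_pred > 0.5, q2_f2 = ext$q2_f2 > 0.5,
    ccc = ext$ccc > 0.750, rm2_test = rm_test$rm2_avg > 0.5,
    delta_rm2_test = rm_test$delta_rm2 < 0.2,
    golbraikh_tropsha = gt$passed)
  structure(list(fit = fs, q2_loo = q2, rm2_loo = rm_loo,
                 external = ext, rm2_test = rm_test, gt = gt,
                 mae_train = mae_tr, mae_test = mae_te,
                 verdicts = verdicts, all_passed = all(unlist(verdicts))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "R2 %.3f | Ra2 %.3f | s %.3f | Q2(LOO) %.3f | rm2(LOO) %.3f | drm2(LOO) %.3f\n",
    x$fit$r2, x$fit$r2_adj, x$fit$s, x$q2_loo, x$rm2_loo$rm2_avg,
    x$rm2_loo$delta_rm2))
  cat(sprintf(
    "R2pred %.3f | Q2F2 %.3f | CCC %.3f | rm2(test) %.3f | drm2(test) %.3f\n",
    x$external$r2_pred, x$external$q2_f2, x$external$ccc,
    x$rm2_test$rm2_avg, x$rm2_test$delta_rm2))
  cat(sprintf("MAE class: training %s, test %s | GT: %s | overall: %s\n",
              x$mae_train$class, x$mae_test$class,
              if (x$gt$passed) "Passed" else "Failed",
              if (x$all_passed) "all thresholds met" else "threshold(s) missed"))
  invisible(x)
}

#' Serialize a validation report
#' @param x a `validation_report`. @param json_path,csv_path output paths
#'   (NULL to skip either).
#' @export
write_validation_report <- function(x, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(x), json_path, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  if (!is.null(csv_path)) {
    row <- data.frame(
      r2 = x$fit$r2, r2_adj = x$fit$r2_adj, q2 = x$q2_loo,
      s = x$fit$s, rm2_loo = x$rm2_loo$rm2_avg,
      delta_rm2_loo = x$rm2_loo$delta_rm2,
      mae_class_train = x$mae_train$class,
      r2_pred = x$external$r2_pred, q2_f2 = x$external$q2_f2,
      rm2_test = x$rm2_test$rm2_avg,
      delta_rm2_test = x$rm2_test$delta_rm2, ccc = x$external$ccc,
      mae_class_test = x$mae_test$class)
    write.csv(row, csv_path, row.names = FALSE)
  }
  invisible(x)
}
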
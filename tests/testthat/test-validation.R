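test_that("external metrics match hand-evaluated cases", {
  # perfect prediction
  ex <- external_metrics(c(1, 2, 3), c(1, 2, 3), mean_y_train = 1.5)
  expect_equal(ex$r2_pred, 1); expect_equal(ex$q2_f2, 1)
  expect_equal(ex$ccc, 1); expect_equal(ex$rmsep, 0)
  # Q2F2 hand case: obs (0,1,2), pred (0,1,1) -> 1 - 1/2 = 0.5
  expect_equal(external_metrics(c(0, 1, 2), c(0, 1, 1), 1)$q2_f2, 0.5)
  # CCC hand case: obs (1,2,3), pred (1,2,4) -> 6/7
  expect_equal(external_metrics(c(1, 2, 3), c(1, 2, 4), 2)$ccc, 6 / 7)
  expect_error(external_metrics(c(1, 1, 1), c(1, 2, 3), 1), "zero-variance")
})

test_that("CCC is bounded by |r| and equals r when moments match", {
  set.seed(31)
  for (i in 1:20) {
    obs <- rnorm(15); pred <- 0.6 * obs + rnorm(15, 0.3, 0.7)
    ccc <- external_metrics(obs, pred, mean(obs))$ccc
    expect_lte(abs(ccc), abs(cor(obs, pred)) + 1e-12)
  }
  # location/scale-matched pair: CCC = r
  obs <- rnorm(40)
  pred <- sample(obs)   # same moments exactly
  expect_equal(external_metrics(obs, pred, 0)$ccc, cor(obs, pred),
               tolerance = 1e-12)
})

test_that("rm2 family reproduces hand cases and its inequalities", {
  r <- rm2_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$rm2, 1); expect_equal(r$rm2_prime, 1)
  expect_equal(r$delta_rm2, 0); expect_equal(r$k, 1); expect_equal(r$k_prime, 1)
  # k/k' hand case on raw scale: obs (1,2), pred (2,4)
  r2 <- rm2_metrics(c(1, 2), c(2, 4), scaled = FALSE)
  expect_equal(r2$k, 0.5); expect_equal(r2$k_prime, 2)
  # centered vectors make the origin-forced fit equal the free fit: rm2 = r2
  set.seed(32)
  o <- rnorm(25); o <- o - mean(o)
  p <- 0.8 * o + rnorm(25, 0, 0.4); p <- p - mean(p)
  rc <- rm2_metrics(o, p, scaled = FALSE)
  expect_equal(rc$r0_2, rc$r2, tolerance = 1e-10)
  # sqrt(|r2 - r0_2|) amplifies machine-epsilon differences to ~1e-8
  expect_equal(rc$rm2, rc$r2, tolerance = 1e-6)
  # general inequalities
  for (i in 1:20) {
    oo <- rnorm(12); pp <- 0.7 * oo + rnorm(12, 0.2, 0.5)
    rr <- rm2_metrics(oo, pp)
    expect_lte(rr$rm2, rr$r2 + 1e-12)
    expect_gte(rr$delta_rm2, 0)
  }
  expect_error(rm2_metrics(rep(1, 5), rnorm(5)), "constant")
})

test_that("Golbraikh-Tropsha checklist passes/fails the right constructions", {
  # identity passes trivially
  gt <- golbraikh_tropsha(1:10, 1:10)
  expect_true(gt$passed)
  expect_equal(gt$criteria$r2$value, 1)
  expect_equal(gt$criteria$k$value, 1)
  # anti-correlated predictions fail through the slope band
  obs <- seq(1, 5, length.out = 12)
  gt2 <- golbraikh_tropsha(obs, -obs + 6)
  expect_false(gt2$criteria$k$passed && gt2$criteria$k_prime$passed)
  expect_false(gt2$passed)
})

test_that("the reference external pair reproduces the published checklist values", {
  pair <- gt_reference_pair()
  gt <- golbraikh_tropsha(pair$obs, pair$pred)
  expect_equal(round(gt$criteria$r2$value, 3), 0.923)
  expect_equal(round(gt$criteria$ratio_r0$value, 5), 0.00062)
  expect_equal(round(gt$criteria$ratio_r0_prime$value, 5), 0.00227)
  expect_equal(round(gt$criteria$k$value, 4), 1.0015)
  expect_equal(round(gt$criteria$k_prime$value, 3), 0.982)
  expect_true(all(vapply(gt$criteria, `[[`, logical(1), "passed")))
  expect_true(gt$passed)
})

test_that("MAE-based classes hit the good/moderate/bad bands", {
  expect_equal(mae_criteria(rep(0, 20), 7.9)$class, "good")
  expect_equal(mae_criteria(rep(7.9, 20), 7.9)$class, "bad")
  # construct a trimmed error vector with MAE = 0.12*range and
  # MAE + 3*SD = 0.22*range -> moderate
  R <- 5
  z <- drop(scale(1:19))                 # mean 0, sd 1 exactly
  kept <- 0.12 * R + (0.10 * R / 3) * z
  errs <- c(kept, 10 * R)                # 20th value is trimmed away
  mc <- mae_criteria(errs, R)
  expect_equal(mc$class, "moderate")
  expect_equal(mc$mae, 0.12 * R, tolerance = 1e-10)
  expect_equal(mc$mae + 3 * mc$sd, 0.22 * R, tolerance = 1e-10)
  expect_equal(mc$n_dropped, 1)
  expect_error(mae_criteria(rep(0.1, 3), 1), "at least 5")
  expect_error(mae_criteria(rep(0.1, 10), 0), "positive")
})

test_that("fit statistics match an independent oracle", {
  fs <- fit_stats(1:10, 1:10, p = 1)
  expect_equal(fs$r2, 1); expect_equal(fs$r2_adj, 1); expect_equal(fs$s, 0)
  obs <- c(2, 4, 6, 8)
  expect_equal(fit_stats(obs, rep(mean(obs), 4), p = 1)$r2, 0)
  set.seed(33)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  fit <- lm(y ~ X)
  sm <- summary(fit)
  fs2 <- fit_stats(y, fitted(fit), p = 3)
  expect_equal(fs2$r2, sm$r.squared, tolerance = 1e-8)
  expect_equal(fs2$r2_adj, sm$adj.r.squared, tolerance = 1e-8)
  expect_equal(fs2$s, sm$sigma, tolerance = 1e-8)
  expect_equal(fs2$f_ratio, unname(sm$fstatistic[1]), tolerance = 1e-8)
})

test_that("the aggregated report applies every threshold verdict", {
  set.seed(34)
  X <- matrix(rnorm(60 * 5), 60, dimnames = list(NULL, paste0("d", 1:5)))
  y <- drop(X %*% c(2, -1, 1, 0.5, 0)) + rnorm(60, 0, 0.5)
  tr <- 1:45; te <- 46:60
  m <- fit_nipals(X[tr, ], y[tr], A = 3)
  loo <- vapply(seq_along(tr), function(i) {
    mi <- fit_nipals(X[tr[-i], ], y[tr[-i]], A = 3)
    predict(mi, X[tr[i], , drop = FALSE])
  }, numeric(1))
  rep <- validation_report(y[tr], m$fitted, loo, y[te],
                           predict(m, X[te, ]), p = 5)
  expect_true(rep$verdicts$q2)
  expect_true(rep$verdicts$ccc)
  expect_true(rep$all_passed)
  # both-equal-1 iff test SSE is zero
  expect_false(rep$external$r2_pred == 1 || rep$external$q2_f2 == 1)
  perfect <- external_metrics(y[te], y[te], mean(y[tr]))
  expect_equal(perfect$r2_pred, 1); expect_equal(perfect$q2_f2, 1)
  # serialization round trip
  tmp <- withr::local_tempdir()
  write_validation_report(rep, json_path = file.path(tmp, "v.json"),
                          csv_path = file.path(tmp, "v.csv"))
  expect_true(file.exists(file.path(tmp, "v.json")))
  row <- read.csv(file.path(tmp, "v.csv"))
  expect_equal(row$q2, rep$q2_loo, tolerance = 1e-12)
})
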
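test_that("NIPALS reproduces simple and full-rank solutions", {
  # single column, exact proportionality
  x <- matrix(seq(-3, 3, length.out = 12), dimnames = list(NULL, "x"))
  m1 <- fit_nipals(x, 2 * drop(x), A = 1)
  expect_equal(unname(m1$b), c(0, 2), tolerance = 1e-10)
  # A = rank(X): PLS predictions equal OLS
  set.seed(10)
  X <- matrix(rnorm(40 * 6), 40, dimnames = list(NULL, paste0("d", 1:6)))
  y <- rnorm(40)
  m <- fit_nipals(X, y, A = 6)
  ols <- lm(y ~ X)
  expect_equal(unname(m$fitted), unname(fitted(ols)), tolerance = 1e-8)
  # score orthogonality
  G <- crossprod(m$T)
  expect_true(all(abs(G[upper.tri(G)]) < 1e-8))
  expect_error(fit_nipals(X, y, A = 7), "rank")
})

test_that("coefficient form and projection form agree on new data", {
  set.seed(15)
  X <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("d", 1:5)))
  y <- drop(X %*% c(1, -2, 0.5, 0, 1)) + rnorm(30, 0, 0.3)
  m <- fit_nipals(X, y, A = 3)
  Xn <- matrix(rnorm(10 * 5), 10, dimnames = list(NULL, paste0("d", 1:5)))
  expect_equal(predict(m, Xn, form = "b"), predict(m, Xn, form = "wpq"),
               tolerance = 1e-10)
  expect_equal(unname(predict(m, X)), unname(m$fitted), tolerance = 1e-10)
})

test_that("LOO Q2 matches a naive refit loop and behaves at the extremes", {
  set.seed(16)
  X <- matrix(rnorm(20 * 4), 20, dimnames = list(NULL, paste0("d", 1:4)))
  y <- drop(X %*% c(1, 1, -1, 0.5)) + rnorm(20, 0, 0.5)
  q2 <- loo_q2(X, y, A = 2)
  # independent oracle: explicit n-refit loop
  press <- 0
  for (i in seq_len(20)) {
    mi <- fit_nipals(X[-i, ], y[-i], A = 2)
    press <- press + (y[i] - predict(mi, X[i, , drop = FALSE]))^2
  }
  expect_equal(q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-12)
  # noise-free linear response is almost perfectly cross-validated
  y_exact <- drop(X %*% c(2, -1, 1, 0.5))
  expect_gt(loo_q2(X, y_exact, A = 4), 0.99)
  # pure-noise responses cross-validate at or below zero (sampling slack)
  q2n <- vapply(1:10, function(s) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(40 * 5), 40, dimnames = list(NULL, paste0("d", 1:5)))
    loo_q2(Xn, rnorm(40), A = 2)
  }, numeric(1))
  expect_true(all(q2n < 0.2))
  expect_lt(median(q2n), 0)
})

test_that("latent-variable count is chosen by LOO Q2, ties to the smaller A", {
  set.seed(17)
  # one planted factor: all information in a single direction
  t1 <- rnorm(50)
  X <- outer(t1, c(1, -1, 0.5, 2)) +
    matrix(rnorm(200, 0, 0.05), 50, 4)
  colnames(X) <- paste0("d", 1:4)
  y <- 2 * t1 + rnorm(50, 0, 0.2)
  sel <- select_lv(X, y, A_max = 4)
  expect_equal(sel$A, 1)
  expect_length(sel$q2, 4)
  expect_equal(select_lv(X, y, A_max = 1)$A, 1)
})

test_that("VIP satisfies its normalization identities", {
  set.seed(18)
  X <- matrix(rnorm(30 * 6), 30, dimnames = list(NULL, paste0("d", 1:6)))
  y <- drop(X %*% c(2, 2, 0, 0, 1, -1)) + rnorm(30, 0.2)
  m <- fit_nipals(X, y, A = 3)
  v <- vip(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)     # sum VIP^2 = J
  expect_true(all(v >= 0))
  # symmetric two-descriptor model: equal weights -> VIP = (1, 1)
  z <- rnorm(25)
  Xs <- cbind(a = z + rnorm(25, 0, 1e-8), b = z + rnorm(25, 0, 1e-8))
  ys <- z
  ms <- fit_nipals(Xs, ys, A = 1)
  expect_equal(unname(vip(ms)), c(1, 1), tolerance = 1e-3)
})

test_that("DModX is zero for perfectly reconstructed rows and calibrated on MVN data", {
  set.seed(19)
  X <- matrix(rnorm(50 * 6), 50, dimnames = list(NULL, paste0("d", 1:6)))
  y <- drop(X %*% c(1, -1, 1, 0, 0.5, 0)) + rnorm(50, 0, 0.4)
  m <- fit_nipals(X, y, A = 2)
  # a new row lying exactly on the model plane has DModX 0
  xs_new <- (m$T[3, , drop = FALSE] %*% t(m$P))
  x_new <- sweep(sweep(xs_new, 2, m$x_scaling$scale, `*`), 2,
                 m$x_scaling$center, `+`)
  colnames(x_new) <- colnames(X)
  dm0 <- dmodx(m, x_new)
  expect_equal(dm0$dmodx, 0, tolerance = 1e-8)
  expect_true(dm0$in_domain)
  # weighted mean of training DModX^2 is ~1 by construction of s0
  dm <- dmodx(m)
  expect_equal(mean(dm$dmodx^2), 1, tolerance = 0.1)
  expect_error(dmodx(fit_nipals(X[, 1:2], y, A = 2)), "K = A")
})

test_that("Hotelling T2 is zero at the origin and its limit grows with A", {
  set.seed(20)
  X <- matrix(rnorm(60 * 5), 60, dimnames = list(NULL, paste0("d", 1:5)))
  y <- drop(X %*% c(1, 1, -1, 0.5, 0)) + rnorm(60, 0, 0.4)
  m <- fit_nipals(X, y, A = 3)
  center_row <- matrix(m$x_scaling$center, 1,
                       dimnames = list(NULL, colnames(X)))
  ht0 <- hotelling_t2(m, center_row)
  expect_equal(unname(ht0$t2), 0, tolerance = 1e-10)
  lims <- vapply(1:4, function(a)
    hotelling_t2(fit_nipals(X, y, a))$limit, numeric(1))
  expect_true(all(diff(lims) > 0))
  # about 5% of multivariate-normal training rows exceed the 95% limit
  ht <- hotelling_t2(m)
  expect_lte(mean(ht$t2 > ht$limit), 0.10)
})

test_that("PCA factor scores separate planted groups and varimax preserves variance", {
  # two perfectly correlated variables: first factor carries all shared variance
  z <- rnorm(20)
  r <- pca_factor_scores(cbind(a = z, b = 2 * z), n_factors = 2,
                         rotate = FALSE)
  expect_equal(r$explained[1], 1, tolerance = 1e-10)
  # varimax rotation preserves total retained variance
  set.seed(22)
  X <- matrix(rnorm(40 * 5), 40, dimnames = list(NULL, paste0("d", 1:5)))
  X[, 2] <- X[, 1] + rnorm(40, 0, 0.4)
  X[, 4] <- X[, 3] + rnorm(40, 0, 0.4)
  un <- pca_factor_scores(X, 2, rotate = FALSE)
  ro <- pca_factor_scores(X, 2, rotate = TRUE)
  expect_equal(sum(ro$explained), sum(un$explained), tolerance = 1e-8)
  # two planted clusters separated along the dominant factor
  g <- rep(c(-3, 3), each = 15)
  Xc <- cbind(d1 = g + rnorm(30, 0, 0.5), d2 = -g + rnorm(30, 0, 0.5),
              d3 = rnorm(30), d4 = g + rnorm(30, 0, 0.5))
  rc <- pca_factor_scores(Xc, 2)
  lead <- which.max(rc$explained)
  split_sign <- sign(rc$scores[, lead])
  expect_true(abs(sum(split_sign[1:15])) == 15 &&
              abs(sum(split_sign[16:30])) == 15)
  expect_error(pca_factor_scores(Xc, 5), "n_factors")
})

test_that("Y-randomization separates a real model from chance correlation", {
  set.seed(23)
  X <- matrix(rnorm(60 * 6), 60, dimnames = list(NULL, paste0("d", 1:6)))
  sig <- drop(X %*% c(1.5, -1, 1, 0.5, -0.5, 0.8))
  y <- sig + rnorm(60, 0, sd(sig) * 0.42)
  yr <- y_randomization(X, y, A = 3, n_perm = 25, seed = 1)
  expect_true(yr$passed)
  expect_lt(yr$r2_intercept, 0.4)
  expect_lt(yr$q2_intercept, 0.05)
  expect_equal(nrow(yr$permutations), 25)
  # chance-correlation regime: overfitted noise keeps R2 under permutation
  set.seed(101)
  Xn <- matrix(rnorm(20 * 10), 20, dimnames = list(NULL, paste0("d", 1:10)))
  yn <- rnorm(20)
  yrn <- y_randomization(Xn, yn, A = 3, n_perm = 25, seed = 1)
  expect_false(yrn$passed)
  expect_error(y_randomization(X, y, 3, n_perm = 0), "n_perm")
  expect_error(y_randomization(X[1:4, ], y[1:4], 1, 10), "few")
})
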
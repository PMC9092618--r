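# NIPALS partial least squares (single response) with leave-one-out
# latent-variable selection and the diagnostics used around the final model:
# VIP, DModX applicability domain, Hotelling T-squared, Y-randomization and
# PCA/varimax factor scores.

#' Fit a PLS model by NIPALS
#'
#' X is autoscaled (unit variance) and y centered and scaled internally; the
#' scaling parameters are stored in the model. Per component the X-weight
#' w is proportional to X'y (normalized), scores t = Xw, X-loading
#' p = X't/(t't), y-loading q = y't/(t't), followed by deflation of X and y.
#' Back-transformed regression coefficients on the original descriptor scale
#' (slopes + intercept) are assembled via W(P'W)^-1 q.
#'
#' @param X numeric matrix (final model descriptor columns; spline terms
#'   already evaluated).
#' @param y response vector (log(OT)).
#' @param A number of latent variables.
#' @return object of class `pls_model` with elements `A`, `W`, `P`, `T`, `q`,
#'   `b` (named vector: `(Intercept)` then slopes on the original scale),
#'   `x_scaling`, `y_scaling`, `E` (training X-residual matrix after A
#'   components), `s0` (pooled residual SD), `fitted`, `ssy_f` (explained
#'   y-variance per component, scaled units).
#' @export
fit_nipals <- function(X, y, A) {
  stopifnot(is.matrix(X), nrow(X) == length(y), A >= 1)
  n <- nrow(X); K <- ncol(X)
  sc <- autoscale(X)
  ym <- mean(y); ysd <- sd(y)
  if (ysd == 0) stopf("response has zero variance")
  rank_x <- qr(sc$Xs)$rank
  if (A > rank_x) stopf("A = %d exceeds rank(X) = %d", A, rank_x)

  Xd <- sc$Xs; yd <- (y - ym) / ysd
  W <- P <- matrix(0, K, A, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, n, A)
  q <- numeric(A); ssy_f <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stopf("degenerate component %d: X'y vanished", a)
    w <- w / nw
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    p_a <- drop(crossprod(Xd, tt)) / tt2
    q_a <- sum(yd * tt) / tt2
    Xd <- Xd - tcrossprod(tt, p_a)
    yd <- yd - q_a * tt
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- tt; q[a] <- q_a
    ssy_f[a] <- q_a^2 * tt2
  }
  R_mat <- W %*% solve(crossprod(P, W))
  b_scaled <- drop(R_mat %*% q)
  slopes <- ysd * b_scaled / sc$scale
  b <- c(`(Intercept)` = ym - sum(slopes * sc$center), slopes)
  E <- Xd
  s0 <- if (K > A && n > A + 1)
    sqrt(sum(E^2) / ((n - A - 1) * (K - A))) else NA_real_
  fitted <- drop(cbind(1, X) %*% b)
  structure(list(A = A, W = W, P = P, T = Tm, q = q, R = R_mat,
                 b = b, b_scaled = b_scaled,
                 x_scaling = sc[c("center", "scale")],
                 y_scaling = list(center = ym, scale = ysd),
                 E = E, s0 = s0, fitted = fitted, ssy_f = ssy_f,
                 n = n, K = K),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d latent variables, %d descriptors, n = %d\n",
              x$A, x$K, x$n))
  cat("Coefficients (original scale):\n")
  print(signif(x$b, 5))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata numeric matrix with the model's descriptor columns.
#' @param form `"b"` (back-transformed coefficients, default) or `"wpq"`
#'   (projection through weights/loadings); the two agree to numerical
#'   precision.
#' @param ... unused.
#' @export
predict.pls_model <- function(object, newdata, form = c("b", "wpq"), ...) {
  form <- match.arg(form)
  stopifnot(is.matrix(newdata), ncol(newdata) == object$K)
  if (form == "b") return(drop(cbind(1, newdata) %*% object$b))
  Xs <- apply_scaling(newdata, object$x_scaling)
  Tn <- Xs %*% object$R
  drop(Tn %*% object$q) * object$y_scaling$scale + object$y_scaling$center
}

#' Project new rows onto the model's score space
#' @noRd
pls_scores <- function(model, newdata = NULL) {
  if (is.null(newdata)) return(model$T)
  apply_scaling(newdata, model$x_scaling) %*% model$R
}

#' Leave-one-out cross-validated Q2
#'
#' For each compound i the whole model is honestly refitted without i —
#' including recomputation of all scaling parameters on the remaining n-1
#' rows — and i is predicted from that fold.
#' Q2 = 1 - PRESS / sum((y - mean(y))^2).
#'
#' @param X descriptor matrix. @param y response. @param A latent variables.
#' @export
loo_q2 <- function(X, y, A) {
  stopifnot(nrow(X) >= 3)
  if (sd(y) == 0) stopf("response has zero variance")
  press <- 0
  for (i in seq_len(nrow(X))) {
    m <- fit_nipals(X[-i, , drop = FALSE], y[-i], A)
    press <- press + (y[i] - predict(m, X[i, , drop = FALSE]))^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Choose the number of latent variables by LOO cross-validation
#'
#' Returns the A in 1..A_max maximizing [loo_q2()]; exact ties go to the
#' smaller A.
#' @param X descriptor matrix. @param y response.
#' @param A_max maximum latent variables to consider (capped at rank(X)).
#' @return list with `A` and the vector `q2` (one value per candidate A).
#' @export
select_lv <- function(X, y, A_max = min(ncol(X), nrow(X) - 2L)) {
  rank_x <- qr(scale(X))$rank
  A_max <- min(A_max, rank_x)
  q2 <- vapply(seq_len(A_max), function(a) loo_q2(X, y, a), numeric(1))
  list(A = which.max(q2), q2 = q2)
}

#' Variable importance in projection (VIP)
#'
#' VIP_j = sqrt( J * sum_f SSY_f * w_jf^2 / SSY_total ), with w_f the
#' unit-norm PLS weight vectors and SSY_f the y-variance explained by
#' component f. The mean squared VIP equals 1 by construction.
#'
#' @param model a `pls_model`.
#' @return named numeric vector of VIP scores, one per descriptor.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ssy <- model$ssy_f
  if (sum(ssy) <= 0) stopf("model explains no y-variance")
  J <- model$K
  w2 <- sweep(model$W^2, 2, ssy, `*`)
  stats::setNames(sqrt(J * rowSums(w2) / sum(ssy)), rownames(model$W))
}

#' DModX applicability domain
#'
#' Distance to the model in X-space: per row, the residual e after projection
#' onto the A components gives s_i = sqrt(sum(e^2)/(K-A)) and
#' DModX_i = s_i / s0, with the pooled training residual SD
#' s0 = sqrt(sum(E^2)/((N-A-1)(K-A))). The critical limit is
#' d_crit = sqrt(F(1-alpha; K-A, (N-A-1)(K-A))); rows with DModX <= d_crit
#' are inside the domain.
#'
#' @param model a `pls_model` with K > A.
#' @param newdata optional matrix of new rows (default: training rows).
#' @param alpha significance level (default 0.01, i.e. 99% confidence).
#' @return data.frame `dmodx,in_domain` with attribute `"d_crit"`.
#' @export
dmodx <- function(model, newdata = NULL, alpha = 0.01) {
  stopifnot(inherits(model, "pls_model"))
  if (model$K <= model$A) stopf("no residual X-space: K = A")
  if (!is.finite(model$s0) || model$s0 <= 0)
    stopf("pooled residual SD s0 is not positive")
  E <- if (is.null(newdata)) model$E else {
    Xs <- apply_scaling(newdata, model$x_scaling)
    Xs - (Xs %*% model$R) %*% t(model$P)
  }
  s_i <- sqrt(rowSums(E^2) / (model$K - model$A))
  dm <- s_i / model$s0
  d_crit <- dmodx_crit(model$n, model$K, model$A, alpha)
  out <- data.frame(dmodx = dm, in_domain = dm <= d_crit)
  if (!is.null(newdata) && !is.null(rownames(newdata)))
    rownames(out) <- rownames(newdata)
  attr(out, "d_crit") <- d_crit
  out
}

#' Critical DModX value
#' @param N training rows, @param K descriptors, @param A latent variables,
#' @param alpha significance level.
#' @export
dmodx_crit <- function(N, K, A, alpha = 0.01) {
  stopifnot(K > A, N > A + 1)
  sqrt(qf(1 - alpha, K - A, (N - A - 1) * (K - A)))
}

#' Hotelling T-squared in score space
#'
#' T2_i = sum_a t_ia^2 / var(t_a) with the variance taken over the training
#' scores; the limit at level `alpha` is
#' A(N^2-1)/(N(N-A)) * F(1-alpha; A, N-A). The T2 ellipse drawn on score
#' plots is this limit for A = 2.
#'
#' @param model a `pls_model`.
#' @param newdata optional matrix of new rows (default: training rows).
#' @param alpha significance level (default 0.05).
#' @return list with `t2` (per row) and `limit`.
#' @export
hotelling_t2 <- function(model, newdata = NULL, alpha = 0.05) {
  Tm <- pls_scores(model, newdata)
  v <- apply(model$T, 2, var)
  if (any(v <= 0)) stopf("zero-variance score column")
  t2 <- rowSums(sweep(Tm^2, 2, v, `/`))
  N <- model$n; A <- model$A
  limit <- A * (N^2 - 1) / (N * (N - A)) * qf(1 - alpha, A, N - A)
  list(t2 = t2, limit = limit)
}

#' Combined applicability-domain report
#'
#' @inheritParams dmodx
#' @param alpha_dmodx,alpha_t2 significance levels for the two diagnostics.
#' @return data.frame `id,dmodx,in_domain,t2` with attributes `"d_crit"` and
#'   `"t2_limit"`.
#' @export
ad_report <- function(model, newdata = NULL, alpha_dmodx = 0.01,
                      alpha_t2 = 0.05) {
  dm <- dmodx(model, newdata, alpha_dmodx)
  ht <- hotelling_t2(model, newdata, alpha_t2)
  out <- data.frame(id = rownames(dm) %||% seq_len(nrow(dm)),
                    dmodx = dm$dmodx, in_domain = dm$in_domain, t2 = ht$t2)
  attr(out, "d_crit") <- attr(dm, "d_crit")
  attr(out, "t2_limit") <- ht$limit
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Y-randomization (response permutation) test
#'
#' The response is randomly permuted `n_perm` times with the X-matrix intact;
#' each permutation is refitted at A latent variables and its training R2 and
#' LOO Q2 recorded together with |cor(y, y_perm)|. Straight lines of R2 and
#' Q2 against |cor| — including the unpermuted model's point at cor = 1 —
#' give the intercepts R2int and Q2int; the model passes when R2int < 0.4 and
#' Q2int < 0.05.
#'
#' @param X descriptor matrix. @param y response. @param A latent variables.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @return object of class `y_randomization`: list with `permutations`
#'   (data.frame `corr,r2,q2`), `r2_intercept`, `q2_intercept`, `passed`.
#' @export
y_randomization <- function(X, y, A, n_perm = 100L, seed = 1L) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (length(y) < 5) stopf("too few compounds for permutation diversity")
  base <- fit_nipals(X, y, A)
  r2_0 <- 1 - sum((y - base$fitted)^2) / sum((y - mean(y))^2)
  q2_0 <- loo_q2(X, y, A)
  perms <- with_seed(seed, replicate(n_perm, sample(length(y))))
  rows <- lapply(seq_len(n_perm), function(j) {
    yp <- y[perms[, j]]
    m <- fit_nipals(X, yp, A)
    data.frame(corr = abs(cor(y, yp)),
               r2 = 1 - sum((yp - m$fitted)^2) / sum((yp - mean(yp))^2),
               q2 = loo_q2(X, yp, A))
  })
  df <- do.call(rbind, rows)
  all_pts <- rbind(df, data.frame(corr = 1, r2 = r2_0, q2 = q2_0))
  r2_int <- unname(coef(lm(r2 ~ corr, all_pts))[1])
  q2_int <- unname(coef(lm(q2 ~ corr, all_pts))[1])
  structure(list(permutations = df, r2_model = r2_0, q2_model = q2_0,
                 r2_intercept = r2_int, q2_intercept = q2_int,
                 passed = r2_int < 0.4 && q2_int < 0.05,
                 n_permutations = n_perm),
            class = "y_randomization")
}

#' @export
print.y_randomization <- function(x, ...) {
  cat(sprintf(
    "Y-randomization (%d permutations): R2int = %.3f, Q2int = %.3f -> %s\n",
    x$n_permutations, x$r2_intercept, x$q2_intercept,
    if (x$passed) "PASS (R2int < 0.4, Q2int < 0.05)" else "FAIL"))
  invisible(x)
}

#' PCA factor scores with optional varimax rotation
#'
#' Principal-component extraction from the correlation matrix of the input
#' (columns standardized), retaining `n_factors` factors; loadings are
#' optionally varimax-rotated (Kaiser-normalized) and the standardized
#' component scores are rotated with the same orthogonal matrix, so the total
#' explained variance of the retained factors is preserved.
#'
#' @param X numeric matrix (e.g. the final model's descriptor columns for
#'   selected compounds).
#' @param n_factors number of factors to retain (default 2).
#' @param rotate apply varimax rotation (default TRUE).
#' @return list with `scores` (n x n_factors), `loadings` (p x n_factors),
#'   `explained` (fraction of total variance per retained factor).
#' @export
pca_factor_scores <- function(X, n_factors = 2L, rotate = TRUE) {
  stopifnot(is.matrix(X), nrow(X) >= 3)
  if (n_factors > ncol(X)) stopf("n_factors exceeds number of variables")
  Z <- scale(X)
  if (any(!is.finite(Z))) stopf("constant column(s) cannot be standardized")
  R <- cor(X)
  eg <- eigen(R, symmetric = TRUE)
  lam <- eg$values[seq_len(n_factors)]
  V <- eg$vectors[, seq_len(n_factors), drop = FALSE]
  ok <- lam > 1e-10
  L <- sweep(V, 2, sqrt(pmax(lam, 0)), `*`)        # loadings
  U <- matrix(0, nrow(X), n_factors)
  U[, ok] <- sweep(Z %*% V[, ok, drop = FALSE], 2, sqrt(lam[ok]), `/`)
  if (rotate && sum(ok) > 1L) {
    vm <- varimax(L[, ok, drop = FALSE])
    L[, ok] <- L[, ok, drop = FALSE] %*% vm$rotmat
    U[, ok] <- U[, ok, drop = FALSE] %*% vm$rotmat
  }
  rownames(L) <- colnames(X)
  rownames(U) <- rownames(X)
  list(scores = U, loadings = L, explained = colSums(L^2) / ncol(X))
}
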
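# Exhaustive best-subset multiple linear regression over the GFA-reduced
# descriptor pool, ranked by MAE-based criteria on a validation set.

#' Ordinary least-squares fit with standard summary statistics
#'
#' @param X numeric matrix of predictors (no intercept column).
#' @param y response vector.
#' @return list with `coefficients` (intercept first), `fitted`, `residuals`,
#'   `r2`, `r2_adj`, `s` (standard error of estimate, n-p-1 denominator) and
#'   `f_ratio`.
#' @export
fit_mlr <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stopf("need n > p + 1 (n = %d, p = %d)", n, p)
  Z <- cbind(`(Intercept)` = 1, X)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qz, y)
  fitted <- drop(Z %*% beta)
  res <- y - fitted
  sse <- sum(res^2); sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  list(coefficients = beta, fitted = fitted, residuals = res,
       r2 = r2, r2_adj = r2_adj, s = sqrt(sse / (n - p - 1)),
       f_ratio = (r2 / p) / ((1 - r2) / (n - p - 1)))
}

#' Enumerate all size-k descriptor subsets, ranked by validation MAE criteria
#'
#' Every C(p, size) subset of the pool is fitted by OLS on the training rows;
#' each is then scored on the validation rows by the trimmed MAE-based
#' criteria (see [mae_criteria()]) and ranked by MAE class
#' (good < moderate < bad), then ascending MAE, ties broken by lexicographic
#' descriptor names. The compiled kernel makes the full C(32,6) = 906,192
#' enumeration practical on one CPU; pools beyond `cap` fits are refused.
#'
#' @param X_train,y_train training rows of the pooled descriptor columns
#'   (GFA spline terms enter as fixed transformed columns) and response.
#' @param X_valid,y_valid validation rows used for MAE ranking.
#' @param size subset size (default 6).
#' @param cap maximum number of fits (default 2e6).
#' @param trim_frac fraction of largest absolute errors dropped before the
#'   MAE (default 0.05, round half up).
#' @return object of class `subset_ranking`: data.frame with columns `rank`,
#'   `descriptors` (`;`-joined), `r2_train`, `mae_valid`, `mae_class`, plus
#'   attribute `"models"` holding the top fitted models.
#' @export
enumerate_best_subsets <- function(X_train, y_train, X_valid, y_valid,
                                   size = 6L, cap = 2e6, trim_frac = 0.05,
                                   keep_models = 10L) {
  stopifnot(is.matrix(X_train), is.matrix(X_valid),
            ncol(X_train) == ncol(X_valid))
  p <- ncol(X_train)
  if (p < size) stopf("pool (%d columns) smaller than subset size %d", p, size)
  ncomb <- choose(p, size)
  if (ncomb > cap)
    stopf("C(%d, %d) = %.0f exceeds the enumeration cap (%g); reduce the pool or raise `cap`",
          p, size, ncomb, cap)
  nms <- colnames(X_train)
  res <- .enum_subsets_cpp(X_train, y_train, X_valid, y_valid,
                           as.integer(size), trim_frac)
  rng <- diff(range(y_train))
  cls <- mae_class_from_stats(res$mae, res$sd_trim, rng)
  desc <- apply(res$combos, 2, function(ix)
    paste(nms[ix], collapse = ";"))
  clsrank <- match(cls, c("good", "moderate", "bad"))
  ord <- order(clsrank, res$mae)
  # deterministic tie-break on exact (class, MAE) ties: lexicographic names
  key <- paste(clsrank[ord], res$mae[ord])
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    tie <- vapply(which(dup), function(i)
      paste(sort(nms[res$combos[, ord[i]]]), collapse = ";"), "")
    ord[dup] <- ord[dup][order(key[dup], tie)]
  }
  df <- data.frame(rank = seq_along(ord),
                   descriptors = desc[ord],
                   r2_train = res$r2[ord],
                   mae_valid = res$mae[ord],
                   mae_class = cls[ord],
                   stringsAsFactors = FALSE)
  top <- head(ord, keep_models)
  models <- lapply(top, function(c0) {
    ix <- res$combos[, c0]
    fit <- fit_mlr(X_train[, ix, drop = FALSE], y_train)
    list(descriptors = nms[ix], coefficients = fit$coefficients,
         r2 = fit$r2, r2_adj = fit$r2_adj, s = fit$s)
  })
  structure(df, models = models, class = c("subset_ranking", "data.frame"))
}

#' Union descriptor pool of the top best-subset models
#'
#' @param ranking a `subset_ranking` from [enumerate_best_subsets()].
#' @param m number of top models to pool (default 5).
#' @return character vector of descriptor (column) names, insertion-ordered
#'   by model rank.
#' @export
final_pool <- function(ranking, m = 5L) {
  stopifnot(inherits(ranking, "subset_ranking"))
  if (nrow(ranking) == 0L) stopf("empty model ranking")
  m <- min(m, nrow(ranking))
  unique(unlist(strsplit(ranking$descriptors[seq_len(m)], ";", fixed = TRUE)))
}

#' @export
print.subset_ranking <- function(x, n = 5L, ...) {
  cat(sprintf("Best-subset ranking: %d models enumerated\n", nrow(x)))
  print.data.frame(head(x, n))
  invisible(x)
}
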
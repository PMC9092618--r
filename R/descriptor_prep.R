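#' Read a descriptor matrix CSV
#'
#' First column `id`, remaining columns numeric molecular descriptors; blank
#' cells are missing values. Any numeric descriptor source is accepted.
#'
#' @param path CSV file path.
#' @return numeric matrix with compound ids as rownames.
#' @export
read_descriptors <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "id") stopf("descriptor CSV must start with an 'id' column")
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- as.character(df$id)
  X
}

#' Pre-filter a raw descriptor pool
#'
#' Removes, in order: (1) columns containing any missing value;
#' (2) constant and near-constant columns (SD < `sd_min`);
#' (3) one member of every highly collinear pair (|Pearson r| >= `r_max`) —
#' the later column in file order is dropped, so the first-listed
#' representative of a correlated group survives.
#'
#' @param X numeric matrix, rows = compounds.
#' @param sd_min minimum column standard deviation (n-1 denominator),
#'   default 1e-4.
#' @param r_max pairwise absolute-correlation ceiling, default 0.95.
#' @return the filtered matrix, with attribute `"removed"`: a data.frame
#'   `name,reason` logging every removal.
#' @export
prefilter <- function(X, sd_min = 1e-4, r_max = 0.95) {
  if (!is.matrix(X) || ncol(X) == 0L || nrow(X) == 0L)
    stopf("empty descriptor matrix")
  if (nrow(X) < 3L) stopf("need at least 3 compounds to filter descriptors")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  removed <- data.frame(name = character(), reason = character(),
                        stringsAsFactors = FALSE)
  log_rm <- function(nms, reason) {
    if (length(nms))
      removed <<- rbind(removed, data.frame(name = nms, reason = reason,
                                            stringsAsFactors = FALSE))
  }

  has_na <- colSums(is.na(X)) > 0
  log_rm(colnames(X)[has_na], "missing values")
  X <- X[, !has_na, drop = FALSE]

  if (ncol(X)) {
    sds <- apply(X, 2, sd)
    low <- sds < sd_min
    log_rm(colnames(X)[low], sprintf("SD < %g", sd_min))
    X <- X[, !low, drop = FALSE]
  }

  if (ncol(X) > 1L) {
    R <- abs(suppressWarnings(cor(X)))
    drop <- logical(ncol(X))
    for (j in seq_len(ncol(X) - 1L)) {
      if (drop[j]) next
      hits <- which(R[j, ] >= r_max & seq_len(ncol(X)) > j & !drop)
      drop[hits] <- TRUE
    }
    log_rm(colnames(X)[drop], sprintf("|r| >= %g with earlier column", r_max))
    X <- X[, !drop, drop = FALSE]
  }

  if (ncol(X) == 0L) warning("all descriptor columns were removed")
  attr(X, "removed") <- removed
  X
}

#' Truncated linear spline basis value
#'
#' Evaluates the chevron spline term `<knot - x>` = max(0, knot - x); negative
#' values of the spline argument are truncated to zero, so the descriptor's
#' effect switches off once x exceeds the knot.
#'
#' @param x numeric vector of descriptor values.
#' @param knot finite numeric knot.
#' @return max(0, knot - x), elementwise.
#' @examples
#' spline_value(28.127, 128.127)  # 100
#' spline_value(200,    128.127)  # 0
#' @export
spline_value <- function(x, knot) {
  stopifnot(is.finite(knot), all(is.finite(x)))
  pmax(0, knot - x)
}

#' Autoscale a descriptor matrix
#'
#' Centers each column to mean 0 and scales to unit standard deviation
#' (n-1 denominator). The scaling parameters are kept so new compounds can be
#' projected onto the same scale.
#'
#' @param X prefiltered numeric matrix (no missing values, no constant
#'   columns).
#' @return list with `Xs` (scaled matrix), `center`, `scale`.
#' @export
autoscale <- function(X) {
  stopifnot(is.matrix(X))
  if (anyNA(X)) stopf("autoscale requires a complete (prefiltered) matrix")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0)) stopf("zero-SD column(s): %s — run prefilter first",
                           paste(colnames(X)[scl == 0], collapse = ", "))
  list(Xs = scale(X, center = ctr, scale = scl)[, , drop = FALSE],
       center = ctr, scale = scl)
}

#' Apply stored autoscaling parameters to new rows
#'
#' @param X numeric matrix with the same columns as the training matrix.
#' @param scaling the `center`/`scale` list from [autoscale()].
#' @export
apply_scaling <- function(X, scaling) {
  stopifnot(is.matrix(X))
  if (length(scaling$center) != ncol(X)) stopf("column count mismatch")
  scale(X, center = scaling$center, scale = scaling$scale)[, , drop = FALSE]
}

#' Undo autoscaling
#' @noRd
invert_scaling <- function(Xs, scaling) {
  sweep(sweep(Xs, 2, scaling$scale, `*`), 2, scaling$center, `+`)
}
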
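#' k-medoid (PAM) clustering of descriptor space
#'
#' Deterministic partitioning-around-medoids: BUILD (greedy cost-minimizing
#' medoid addition) followed by steepest-descent SWAP passes until no swap
#' lowers the total Euclidean distance of points to their medoids. Exact ties
#' between candidate medoids are broken by row order, so the result is fully
#' reproducible; `seed` is accepted for interface symmetry but only matters
#' when ties are broken randomly (`tie_break = "random"`).
#'
#' @param Xs autoscaled numeric matrix (rows = compounds).
#' @param k number of clusters (default 6, the number used for rational
#'   dataset division of the 85-odorant set).
#' @param seed optional integer seed (tie-breaking only).
#' @param tie_break `"first"` (default, deterministic) or `"random"`.
#' @return object of class `kmedoid_clustering`: list with `medoid_ids`,
#'   `labels` (named integer vector), `total_cost`, `cost_trace` (total cost
#'   after BUILD and after each SWAP pass), `distances` (distance of each
#'   point to its medoid).
#' @export
kmedoid <- function(Xs, k = 6L, seed = NULL, tie_break = c("first", "random")) {
  tie_break <- match.arg(tie_break)
  stopifnot(is.matrix(Xs))
  n <- nrow(Xs)
  if (anyNA(Xs)) stopf("kmedoid requires complete data")
  if (k <= 0) stopf("k must be positive")
  if (k > n) stopf("k (%d) exceeds number of compounds (%d)", k, n)
  ids <- rownames(Xs); if (is.null(ids)) ids <- as.character(seq_len(n))

  D <- as.matrix(dist(Xs))
  pick <- function(cand, score) {
    best <- which(score == min(score))
    if (length(best) > 1L && tie_break == "random")
      cand[with_seed(seed, sample(best, 1L))] else cand[best[1L]]
  }

  # BUILD: start with the 1-medoid minimizer, then greedily add
  med <- integer(0)
  costs <- colSums(D)
  med <- pick(seq_len(n), costs)
  dnear <- D[, med]
  while (length(med) < k) {
    cand <- setdiff(seq_len(n), med)
    gain <- vapply(cand, function(j) sum(pmin(dnear, D[, j])), numeric(1))
    med <- c(med, pick(cand, gain))
    dnear <- pmin(dnear, D[, med[length(med)]])
  }

  total_cost <- function(med) sum(apply(D[, med, drop = FALSE], 1, min))
  trace <- total_cost(med)

  # SWAP: steepest descent over all (medoid, non-medoid) exchanges
  repeat {
    cur <- trace[length(trace)]
    best_cost <- cur; best_swap <- NULL
    nonmed <- setdiff(seq_len(n), med)
    for (mi in seq_along(med)) {
      for (h in nonmed) {
        trial <- med; trial[mi] <- h
        cc <- total_cost(trial)
        if (cc < best_cost - 1e-12) { best_cost <- cc; best_swap <- c(mi, h) }
      }
    }
    if (is.null(best_swap)) break
    med[best_swap[1]] <- best_swap[2]
    trace <- c(trace, best_cost)
  }

  lab <- apply(D[, med, drop = FALSE], 1, which.min)
  dist_to_med <- D[cbind(seq_len(n), med[lab])]
  structure(list(
    medoid_ids = ids[med],
    labels = stats::setNames(as.integer(lab), ids),
    total_cost = trace[length(trace)],
    cost_trace = trace,
    distances = stats::setNames(dist_to_med, ids)),
    class = "kmedoid_clustering")
}

#' @export
print.kmedoid_clustering <- function(x, ...) {
  cat(sprintf("k-medoid clustering: k = %d, n = %d, total cost %.4f\n",
              length(x$medoid_ids), length(x$labels), x$total_cost))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Rational train/test division from a clustering
#'
#' Within each cluster, compounds are ranked by distance from their medoid
#' (medoid first; ties broken by id) and every `round(1/fraction)`-th compound
#' in that ranking is assigned to the test set. The medoid itself always stays
#' in training, and singleton clusters contribute no test compound. With the
#' default fraction 0.25 this takes approximately 25% of each cluster for the
#' test set, spread across the cluster's density profile.
#'
#' @param clusters a `kmedoid_clustering`.
#' @param fraction target test fraction in (0, 1), default 0.25.
#' @return list with character vectors `train` and `test`.
#' @export
assign_test <- function(clusters, fraction = 0.25) {
  stopifnot(inherits(clusters, "kmedoid_clustering"),
            fraction > 0, fraction < 1)
  step <- max(2L, as.integer(round(1 / fraction)))
  test <- character(0)
  for (cl in sort(unique(clusters$labels))) {
    ids <- names(clusters$labels)[clusters$labels == cl]
    d <- clusters$distances[ids]
    ord <- ids[order(d, ids)]           # medoid has distance 0 -> first
    if (length(ord) >= step)
      test <- c(test, ord[seq(step, length(ord), by = step)])
  }
  all_ids <- names(clusters$labels)
  list(train = setdiff(all_ids, test), test = test)
}

#' Write split and cluster reports
#' @param clusters a `kmedoid_clustering`.
#' @param split list from [assign_test()].
#' @param split_path,cluster_path output CSV paths (NULL to skip either).
#' @export
write_split <- function(clusters, split, split_path = NULL,
                        cluster_path = NULL) {
  if (!is.null(split_path)) {
    df <- data.frame(id = c(split$train, split$test),
                     set = rep(c("train", "test"),
                               c(length(split$train), length(split$test))))
    write.csv(df[order(df$id), ], split_path, row.names = FALSE)
  }
  if (!is.null(cluster_path)) {
    df <- data.frame(id = names(clusters$labels),
                     cluster = as.integer(clusters$labels),
                     distance_to_medoid = as.numeric(clusters$distances))
    write.csv(df, cluster_path, row.names = FALSE)
  }
  invisible(NULL)
}
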
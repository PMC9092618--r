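# End-to-end orchestration: curate -> filter -> split -> GFA -> best subset
# -> PLS -> validation -> applicability domain -> randomization -> composite.

#' Pipeline configuration
#'
#' @param compounds path to a compound CSV (either dialect of
#'   [read_compounds()]) or a data.frame.
#' @param descriptors path to a descriptor CSV or a numeric matrix with
#'   compound rownames.
#' @param wines optional path to a wine-composition CSV, or a list of
#'   [wine_composition()]s, or `NULL` to skip the composite stage.
#' @param out_dir directory for persisted artifacts (`NULL` = in-memory only).
#' @param delta_max curation spread tolerance (log10 units).
#' @param sd_min,r_max prefilter thresholds.
#' @param k_clusters clusters for the rational split (default 6).
#' @param test_fraction per-cluster test fraction (default 0.25).
#' @param gfa a [gfa_config()]; its seed is re-derived from `seed`.
#' @param gfa_top_models GFA models pooled (default 5).
#' @param subset_size best-subset model size (default 6).
#' @param subset_top_models subset models pooled into the final pool
#'   (default 5).
#' @param subset_validation `"test"` ranks subsets on the held-out test set
#'   (the study's choice) or `"internal"` on an internal quarter of the
#'   training set.
#' @param subset_cap enumeration cap (default 2e6 fits).
#' @param a_max maximum latent variables considered (default 5).
#' @param n_perm Y-randomization permutations (default 100).
#' @param alpha_dmodx,alpha_t2 applicability-domain significance levels.
#' @param seed master seed; per-stage child seeds are derived from it via
#'   [child_seed()].
#' @export
pipeline_config <- function(compounds, descriptors, wines = NULL,
                            out_dir = NULL, delta_max = 1.0, sd_min = 1e-4,
                            r_max = 0.95, k_clusters = 6L,
                            test_fraction = 0.25, gfa = gfa_config(),
                            gfa_top_models = 5L, subset_size = 6L,
                            subset_top_models = 5L,
                            subset_validation = c("test", "internal"),
                            subset_cap = 2e6, a_max = 5L, n_perm = 100L,
                            alpha_dmodx = 0.01, alpha_t2 = 0.05, seed = 1L) {
  subset_validation <- match.arg(subset_validation)
  structure(as.list(environment()), class = "pipeline_config")
}

persist <- function(out_dir, name, writer) {
  if (!is.null(out_dir)) writer(file.path(out_dir, name))
}

#' Run the full QSPR pipeline
#'
#' Executes the stage chain on the configured inputs, persisting every
#' intermediate artifact when `out_dir` is set, and returns all stage outputs
#' plus a summary with pass/fail verdicts at the standard validation
#' thresholds. Idempotent given the seed. Only the subset-ranking stage
#' (under the `"test"` validation choice) and the final validation ever see
#' test-set responses.
#'
#' @param cfg a [pipeline_config()].
#' @return object of class `qspr_pipeline`: list with elements `curated`,
#'   `filter_log`, `split`, `clusters`, `gfa`, `gfa_pool`, `subset_ranking`,
#'   `final_descriptors`, `pls`, `lv_selection`, `report`, `ad_train`,
#'   `ad_test`, `randomization`, `composite`, `summary`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- curate ----------------------------------------------------------------
  comp <- if (is.character(cfg$compounds)) read_compounds(cfg$compounds)
          else cfg$compounds
  curated <- curate_compounds(comp, delta_max = cfg$delta_max)
  persist(cfg$out_dir, "curated.csv", function(p) write_curated(curated, p))
  ids <- curated$records$id
  y <- stats::setNames(curated$records$log_ot, ids)

  # -- filter ----------------------------------------------------------------
  Xraw <- if (is.character(cfg$descriptors)) read_descriptors(cfg$descriptors)
          else cfg$descriptors
  missing_rows <- setdiff(ids, rownames(Xraw))
  if (length(missing_rows))
    stopf("curated compounds missing from descriptor matrix: %s",
          paste(missing_rows, collapse = ", "))
  Xraw <- Xraw[ids, , drop = FALSE]
  X <- prefilter(Xraw, sd_min = cfg$sd_min, r_max = cfg$r_max)
  persist(cfg$out_dir, "filter_log.csv", function(p)
    write.csv(attr(X, "removed"), p, row.names = FALSE))

  # -- split -----------------------------------------------------------------
  sc <- autoscale(X)
  clusters <- kmedoid(sc$Xs, k = cfg$k_clusters,
                      seed = child_seed(cfg$seed, "split"))
  split <- assign_test(clusters, fraction = cfg$test_fraction)
  persist(cfg$out_dir, "split.csv", function(p)
    write_split(clusters, split, split_path = p,
                cluster_path = file.path(cfg$out_dir, "clusters.csv")))
  tr <- split$train; te <- split$test

  # -- GFA -------------------------------------------------------------------
  gcfg <- cfg$gfa; gcfg$seed <- child_seed(cfg$seed, "gfa")
  gfa <- evolve(X[tr, , drop = FALSE], y[tr], gcfg)
  persist(cfg$out_dir, "gfa_models.csv", function(p) write_gfa_report(gfa, p))
  pool_terms <- term_pool(gfa, m = cfg$gfa_top_models)
  gfa_pool <- descriptor_pool(gfa, m = cfg$gfa_top_models)

  # GFA spline terms become fixed transformed columns for the later stages
  Z <- term_design(pool_terms, X)
  rownames(Z) <- rownames(X)
  keep <- apply(Z, 2, sd) > 0
  Z <- Z[, keep, drop = FALSE]

  # -- best subset -----------------------------------------------------------
  if (cfg$subset_validation == "test") {
    vtr <- tr; vids <- te
  } else {
    vids <- tr[seq(4, length(tr), by = 4)]
    vtr <- setdiff(tr, vids)
  }
  size <- min(cfg$subset_size, ncol(Z))
  ranking <- enumerate_best_subsets(
    Z[vtr, , drop = FALSE], y[vtr], Z[vids, , drop = FALSE], y[vids],
    size = size, cap = cfg$subset_cap)
  persist(cfg$out_dir, "subset_ranking.csv", function(p)
    write.csv(head(as.data.frame(ranking), 100L), p, row.names = FALSE))
  final_cols <- final_pool(ranking, m = cfg$subset_top_models)
  Zf <- Z[, final_cols, drop = FALSE]

  # -- PLS -------------------------------------------------------------------
  if (ncol(Zf) < 2L) stopf("final descriptor pool has fewer than 2 columns")
  # keep residual X-space for DModX: A < K always
  lv <- select_lv(Zf[tr, , drop = FALSE], y[tr],
                  A_max = min(cfg$a_max, ncol(Zf) - 1L))
  pls <- fit_nipals(Zf[tr, , drop = FALSE], y[tr], lv$A)
  persist(cfg$out_dir, "pls_coefficients.csv", function(p)
    write.csv(data.frame(term = names(pls$b), coefficient = unname(pls$b)),
              p, row.names = FALSE))
  persist(cfg$out_dir, "pls_scores.csv", function(p)
    write.csv(data.frame(id = tr, pls$T), p, row.names = FALSE))

  # -- validation ------------------------------------------------------------
  loo_pred <- vapply(seq_along(tr), function(i) {
    m <- fit_nipals(Zf[tr[-i], , drop = FALSE], y[tr[-i]], lv$A)
    predict(m, Zf[tr[i], , drop = FALSE])
  }, numeric(1))
  pred_test <- predict(pls, Zf[te, , drop = FALSE])
  report <- validation_report(y[tr], pls$fitted, loo_pred, y[te], pred_test,
                              p = ncol(Zf))
  persist(cfg$out_dir, "validation.json", function(p)
    write_validation_report(report, json_path = p,
                            csv_path = file.path(cfg$out_dir, "validation.csv")))

  # -- applicability domain --------------------------------------------------
  ad_train <- ad_report(pls, alpha_dmodx = cfg$alpha_dmodx,
                        alpha_t2 = cfg$alpha_t2)
  ad_train$id <- tr
  ad_test <- ad_report(pls, Zf[te, , drop = FALSE],
                       alpha_dmodx = cfg$alpha_dmodx, alpha_t2 = cfg$alpha_t2)
  persist(cfg$out_dir, "ad_train.csv", function(p)
    write.csv(ad_train, p, row.names = FALSE))
  persist(cfg$out_dir, "ad_test.csv", function(p)
    write.csv(ad_test, p, row.names = FALSE))

  # -- Y-randomization -------------------------------------------------------
  rand <- y_randomization(Zf[tr, , drop = FALSE], y[tr], lv$A,
                          n_perm = cfg$n_perm,
                          seed = child_seed(cfg$seed, "randomize"))
  persist(cfg$out_dir, "randomization.csv", function(p)
    write.csv(rand$permutations, p, row.names = FALSE))

  # -- composite wines -------------------------------------------------------
  composite <- NULL
  wines <- cfg$wines
  if (is.character(wines)) wines <- read_wines(wines)
  if (!is.null(wines)) {
    composite <- composite_predictions(pls, wines, Zf)
    persist(cfg$out_dir, "composite_wines.csv", function(p)
      write.csv(composite, p, row.names = FALSE))
  }

  summary <- list(
    n_curated = length(ids), n_removed = nrow(curated$removed),
    n_descriptors_raw = ncol(Xraw), n_descriptors_filtered = ncol(X),
    n_train = length(tr), n_test = length(te),
    gfa_pool_size = length(gfa_pool),
    final_descriptors = final_cols, latent_variables = lv$A,
    r2 = report$fit$r2, q2_loo = report$q2_loo,
    r2_pred = report$external$r2_pred, q2_f2 = report$external$q2_f2,
    ccc = report$external$ccc,
    rm2_test = report$rm2_test$rm2_avg,
    delta_rm2_test = report$rm2_test$delta_rm2,
    mae_class_train = report$mae_train$class,
    mae_class_test = report$mae_test$class,
    verdicts = report$verdicts,
    randomization_passed = rand$passed,
    d_crit = attr(ad_train, "d_crit"),
    composite = if (!is.null(composite))
      stats::setNames(composite$composite_log_ot, composite$wine_id),
    seed = cfg$seed)
  persist(cfg$out_dir, "summary.json", function(p)
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         force = TRUE))

  structure(list(curated = curated, filter_log = attr(X, "removed"),
                 clusters = clusters, split = split, gfa = gfa,
                 gfa_pool = gfa_pool, pool_terms = pool_terms,
                 design = Z, subset_ranking = ranking,
                 final_descriptors = final_cols, pls = pls,
                 lv_selection = lv, report = report, ad_train = ad_train,
                 ad_test = ad_test, randomization = rand,
                 composite = composite, summary = summary),
            class = "qspr_pipeline")
}

#' @export
print.qspr_pipeline <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "QSPR pipeline: %d compounds (%d train / %d test), %d -> %d -> %d descriptors\n",
    s$n_curated, s$n_train, s$n_test, s$n_descriptors_raw,
    s$n_descriptors_filtered, length(s$final_descriptors)))
  cat(sprintf("final model: %d LV | R2 %.3f | Q2 %.3f | R2pred %.3f | CCC %.3f\n",
              s$latent_variables, s$r2, s$q2_loo, s$r2_pred, s$ccc))
  if (!is.null(s$composite)) {
    cat("composite log(OT):\n")
    print(signif(s$composite, 4))
  }
  invisible(x)
}
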
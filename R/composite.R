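# Composite odor-threshold prediction for multi-component wines: the model's
# descriptor columns are averaged over a wine's aroma components and the
# fitted PLS model is applied to the averaged ("composite") vector.

#' Read a wine composition table
#'
#' CSV with columns `wine_id,component_id[,weight]`; missing weights default
#' to uniform within each wine.
#' @param path CSV file path.
#' @return named list of `wine_composition` objects.
#' @export
read_wines <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("wine_id", "component_id")
  if (!all(need %in% names(df)))
    stopf("wine CSV needs columns: %s", paste(need, collapse = ", "))
  out <- lapply(split(df, df$wine_id), function(d)
    wine_composition(d$wine_id[1], as.character(d$component_id),
                     if ("weight" %in% names(d)) d$weight else NULL))
  out[order(names(out))]
}

#' Construct a wine composition
#'
#' @param wine_id wine label.
#' @param components character vector of component compound ids (>= 1).
#' @param weights optional non-negative weights (normalized internally);
#'   default uniform.
#' @export
wine_composition <- function(wine_id, components, weights = NULL) {
  stopifnot(length(components) >= 1)
  if (is.null(weights)) weights <- rep(1, length(components))
  stopifnot(length(weights) == length(components), all(weights >= 0))
  if (sum(weights) <= 0) stopf("weights must sum to a positive value")
  structure(list(wine_id = as.character(wine_id),
                 components = as.character(components),
                 weights = weights / sum(weights)),
            class = "wine_composition")
}

#' Composite descriptor vector of a wine
#'
#' Weighted mean of each model-descriptor column over the wine's components.
#' Averaging operates on the final model columns (after any spline
#' transformation), so composite predictions are exactly the weighted mean of
#' the per-component predictions.
#'
#' @param wine a `wine_composition`.
#' @param descriptor_table matrix of the fitted model's descriptor columns,
#'   rownames = compound ids.
#' @return numeric vector (one value per model descriptor).
#' @export
composite_descriptors <- function(wine, descriptor_table) {
  stopifnot(inherits(wine, "wine_composition"), is.matrix(descriptor_table))
  missing_ids <- setdiff(wine$components, rownames(descriptor_table))
  if (length(missing_ids))
    stopf("component id(s) not in descriptor table: %s",
          paste(missing_ids, collapse = ", "))
  rows <- descriptor_table[wine$components, , drop = FALSE]
  drop(crossprod(rows, wine$weights))
}

#' Predict the composite log(OT) of a wine
#'
#' Applies the model's back-transformed coefficient form to the composite
#' descriptor vector.
#' @param model a `pls_model`.
#' @param composite numeric vector from [composite_descriptors()].
#' @export
predict_composite <- function(model, composite) {
  stopifnot(inherits(model, "pls_model"))
  if (length(composite) != model$K)
    stopf("composite vector length %d != model descriptor count %d",
          length(composite), model$K)
  drop(c(1, composite) %*% model$b)
}

#' Rank wines by composite odor threshold
#'
#' @param predictions named numeric vector (wine -> composite log(OT)).
#' @return data.frame `wine_id,composite_log_ot,rank`, lowest threshold
#'   first; ties broken by wine id.
#' @export
rank_wines <- function(predictions) {
  stopifnot(length(predictions) >= 1, !is.null(names(predictions)))
  ord <- order(predictions, names(predictions))
  data.frame(wine_id = names(predictions)[ord],
             composite_log_ot = unname(predictions[ord]),
             rank = seq_along(ord))
}

#' Predict and rank a set of wines
#'
#' @param model a `pls_model`.
#' @param wines list of `wine_composition`s.
#' @param descriptor_table model descriptor columns for all candidate
#'   components (rownames = compound ids).
#' @export
composite_predictions <- function(model, wines, descriptor_table) {
  preds <- vapply(wines, function(w)
    predict_composite(model, composite_descriptors(w, descriptor_table)),
    numeric(1))
  names(preds) <- vapply(wines, `[[`, "", "wine_id")
  rank_wines(preds)
}
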
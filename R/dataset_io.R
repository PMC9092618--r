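#' Log-transform an odor threshold
#'
#' Odor thresholds (nmol) are modeled on the decimal log scale, log(OT).
#' A lower log(OT) means a more potent odorant.
#'
#' @param ot_nmol positive numeric vector of odor thresholds in nmol.
#' @param compound optional compound id(s) used in error messages.
#' @return base-10 logarithm of `ot_nmol`.
#' @examples
#' log_ot(c(1, 10, 100))
#' @export
log_ot <- function(ot_nmol, compound = NULL) {
  bad <- !is.finite(ot_nmol) | ot_nmol <= 0
  if (any(bad)) {
    who <- if (!is.null(compound)) paste(compound[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stopf("odor thresholds must be finite and > 0 nmol (offending: %s)", who)
  }
  log10(ot_nmol)
}

#' Read a compound table
#'
#' Two CSV dialects are accepted:
#' long format `id,name,smiles,source,ot_nmol` (one row per literature source)
#' or pre-curated `id,name,smiles,log_ot`. The `smiles` column is optional in
#' both.
#'
#' @param path CSV file path.
#' @return a data.frame in one of the two dialects, with attribute
#'   `"dialect"` set to `"long"` or `"curated"`.
#' @export
read_compounds <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stopf("compound table needs an 'id' column")
  if ("ot_nmol" %in% names(df)) {
    if (!"source" %in% names(df)) stopf("long-format table needs a 'source' column")
    attr(df, "dialect") <- "long"
  } else if ("log_ot" %in% names(df)) {
    attr(df, "dialect") <- "curated"
  } else stopf("compound table needs either 'ot_nmol'+'source' or 'log_ot'")
  df$id <- as.character(df$id)
  df
}

#' Merge multi-source odor-threshold records into a curated dataset
#'
#' Each compound may carry threshold values from several literature sources.
#' Values are compared on the log10 scale: when the spread between sources is
#' at most `delta_max` log-units the compound is kept with the arithmetic mean
#' of the log10 values; a larger spread is treated as a discordant literature
#' record and the compound is dropped. Averaging on the log scale matches the
#' scale on which the response is modeled.
#'
#' @param records data.frame with columns `id`, `name`, optional `smiles`,
#'   `source`, `ot_nmol` (long format, one row per source).
#' @param delta_max maximum tolerated spread, in log10 units, between sources
#'   of the same compound (default 1).
#' @return an object of class `curated_dataset`: a list with
#'   `records` (data.frame `id,name,smiles,log_ot`), `removed`
#'   (data.frame `id,reason`) and `provenance` (one decision per compound).
#' @export
merge_sources <- function(records, delta_max = 1.0) {
  stopifnot(is.data.frame(records), delta_max > 0)
  need <- c("id", "source", "ot_nmol")
  if (!all(need %in% names(records)))
    stopf("records need columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(records[, c("id", "source")]))
    stopf("duplicate (id, source) pairs in input")
  if (!"name" %in% names(records)) records$name <- records$id
  if (!"smiles" %in% names(records)) records$smiles <- NA_character_

  records$log10_ot <- log_ot(records$ot_nmol, records$id)
  ids <- unique(records$id)
  kept <- list(); removed <- list(); prov <- list()
  for (cid in ids) {
    rows <- records[records$id == cid, ]
    lv <- sort(rows$log10_ot)  # order-invariant w.r.t. source listing
    spread <- max(lv) - min(lv)
    if (nrow(rows) == 1L || spread <= delta_max) {
      kept[[cid]] <- data.frame(
        id = cid, name = rows$name[1], smiles = rows$smiles[1],
        log_ot = mean(lv), stringsAsFactors = FALSE)
      prov[[cid]] <- sprintf(
        "%s: kept (%d source%s, spread %.4f <= %.4f, mean log10 = %.4f)",
        cid, nrow(rows), if (nrow(rows) > 1) "s" else "", spread, delta_max,
        mean(lv))
    } else {
      removed[[cid]] <- data.frame(id = cid, reason = "discordant sources",
                                   stringsAsFactors = FALSE)
      prov[[cid]] <- sprintf(
        "%s: removed (spread %.4f > %.4f across %d sources)",
        cid, spread, delta_max, nrow(rows))
    }
  }
  out <- list(
    records = if (length(kept)) do.call(rbind, kept) else
      data.frame(id = character(), name = character(),
                 smiles = character(), log_ot = numeric()),
    removed = if (length(removed)) do.call(rbind, removed) else
      data.frame(id = character(), reason = character()),
    provenance = unlist(prov, use.names = FALSE))
  rownames(out$records) <- NULL; rownames(out$removed) <- NULL
  class(out) <- "curated_dataset"
  out
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat(sprintf("Curated odor-threshold dataset: %d compounds kept, %d removed\n",
              nrow(x$records), nrow(x$removed)))
  if (nrow(x$records))
    cat(sprintf("log(OT) span: %.3f to %.3f\n",
                min(x$records$log_ot), max(x$records$log_ot)))
  invisible(x)
}

#' Curate a compound table read from disk
#'
#' Convenience wrapper: applies [merge_sources()] to long-format input or
#' validates pre-curated input as-is.
#' @param df data.frame from [read_compounds()].
#' @param delta_max passed to [merge_sources()].
#' @export
curate_compounds <- function(df, delta_max = 1.0) {
  if (identical(attr(df, "dialect"), "curated") ||
      ("log_ot" %in% names(df) && !"ot_nmol" %in% names(df))) {
    if (anyDuplicated(df$id)) stopf("duplicate compound ids in curated input")
    if (any(!is.finite(df$log_ot))) stopf("non-finite log_ot in curated input")
    if (!"name" %in% names(df)) df$name <- df$id
    if (!"smiles" %in% names(df)) df$smiles <- NA_character_
    out <- list(records = df[, c("id", "name", "smiles", "log_ot")],
                removed = data.frame(id = character(), reason = character()),
                provenance = sprintf("%s: accepted pre-curated", df$id))
    class(out) <- "curated_dataset"
    return(out)
  }
  merge_sources(df, delta_max = delta_max)
}

#' Write a curated dataset (CSV + JSON provenance log)
#'
#' @param x a `curated_dataset`.
#' @param path output CSV path; the provenance log is written next to it with
#'   suffix `_provenance.json`.
#' @export
write_curated <- function(x, path) {
  stopifnot(inherits(x, "curated_dataset"))
  write.csv(x$records, path, row.names = FALSE)
  jsonlite::write_json(
    list(removed = x$removed, provenance = x$provenance),
    sub("\\.csv$", "_provenance.json", path), auto_unbox = TRUE)
  invisible(path)
}
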
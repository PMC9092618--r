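# Synthetic study generator: descriptor matrices with intercorrelated blocks
# and pathological columns, a response planted as intercept + linear +
# truncated-spline terms + Gaussian noise, multi-source odor-threshold
# records, and random wine compositions. Every pipeline stage is testable on
# its output, and the planted truth is returned for recovery scoring.

#' Specification of a synthetic QSPR study
#'
#' Defaults emulate the curated odor-threshold study: 85 retained compounds
#' plus 4 discordant ones (removed at curation), a descriptor pool with
#' correlated blocks, a handful of constant / near-constant / missing-value
#' columns for the prefilter to catch, and a response driven by two linear
#' and two spline terms with additive Gaussian noise.
#'
#' @param n_compounds retained compounds (default 85).
#' @param n_descriptors total descriptor columns including pathological ones
#'   (default 100).
#' @param n_blocks number of intercorrelated descriptor blocks (default 5).
#' @param rho within-block correlation (default 0.7).
#' @param n_constant,n_near_constant,n_missing pathological column counts
#'   (defaults 2, 2, 2).
#' @param true_terms list of lists `(descriptor, kind, knot, coefficient)`;
#'   `NULL` (default) plants two linear and two spline terms on the first
#'   columns of the first four blocks, coefficients 2, -1.5, 1.5, -2, spline
#'   knots at the within-sample median so the truncation is active for about
#'   half the compounds.
#' @param intercept response intercept (default 3).
#' @param noise_sd Gaussian noise SD on the response (default 0.6 log-units,
#'   a strong but noisy QSPR signal).
#' @param n_discordant extra compounds whose two literature sources disagree
#'   by > 1.5 log-units, to exercise curation (default 4).
#' @param two_source_frac fraction of retained compounds reported by two
#'   concordant sources (default 25/85).
#' @param source_jitter half-spread of the two concordant source values in
#'   log-units (default 0.05); their log-scale mean is exactly the true
#'   response.
#' @param seed integer seed.
#' @export
synthetic_spec <- function(n_compounds = 85L, n_descriptors = 100L,
                           n_blocks = 5L, rho = 0.7, n_constant = 2L,
                           n_near_constant = 2L, n_missing = 2L,
                           true_terms = NULL, intercept = 3,
                           noise_sd = 0.6, n_discordant = 4L,
                           two_source_frac = 25 / 85,
                           source_jitter = 0.05, seed = 1L) {
  n_path <- n_constant + n_near_constant + n_missing
  if (n_path >= n_descriptors)
    stopf("pathological columns (%d) must be fewer than n_descriptors (%d)",
          n_path, n_descriptors)
  stopifnot(noise_sd >= 0, rho >= 0, rho < 1, n_blocks >= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic study
#'
#' Informative descriptors are drawn block-wise from equicorrelated Gaussians
#' (shared latent factor), rescaled to per-column means and SDs, then
#' constant, near-constant and missing-value columns are appended. The
#' response is `intercept + sum(beta_i * term_i(x)) + N(0, noise_sd)`. Output
#' is fully deterministic per seed.
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `synthetic_study`: list with `compounds`
#'   (long-format data.frame `id,name,smiles,source,ot_nmol`), `X` (raw
#'   descriptor matrix, pathological columns included), `y` (named vector:
#'   the exact planted response of the retained compounds) and `truth`
#'   (planted terms with knots and coefficients, intercept, noise_sd,
#'   signal_sd).
#' @export
make_study <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_compounds + spec$n_discordant
    n_inf <- spec$n_descriptors -
      (spec$n_constant + spec$n_near_constant + spec$n_missing)
    block_of <- rep(seq_len(spec$n_blocks), length.out = n_inf)

    X <- matrix(0, n, n_inf)
    cn <- character(n_inf)
    for (b in seq_len(spec$n_blocks)) {
      cols <- which(block_of == b)
      latent <- rnorm(n)
      for (j in cols) {
        raw <- sqrt(spec$rho) * latent + sqrt(1 - spec$rho) * rnorm(n)
        X[, j] <- raw * runif(1, 0.5, 2) + runif(1, -1, 1)
      }
      cn[cols] <- sprintf("B%d_D%02d", b, seq_along(cols))
    }
    colnames(X) <- cn

    terms <- spec$true_terms
    if (is.null(terms)) {
      first_cols <- cn[match(1:4, block_of)]
      if (anyNA(first_cols)) stopf("need >= 4 blocks for default true terms")
      kinds <- c("linear", "linear", "spline", "spline")
      betas <- c(2, -1.5, 1.5, -2)
      terms <- Map(function(d, k, b) list(descriptor = d, kind = k,
                                          knot = NULL, coefficient = b),
                   first_cols, kinds, betas)
    }
    bad <- vapply(terms, function(t) !t$descriptor %in% cn, logical(1))
    if (any(bad)) stopf("true_terms reference unknown or pathological columns")
    terms <- lapply(terms, function(t) {
      if (t$kind == "spline" && is.null(t$knot))
        t$knot <- unname(quantile(X[, t$descriptor], 0.5))
      t
    })

    signal <- rep(spec$intercept, n)
    for (t in terms) {
      v <- X[, t$descriptor]
      if (t$kind == "spline") v <- spline_value(v, t$knot)
      signal <- signal + t$coefficient * v
    }
    y_all <- signal + rnorm(n, 0, spec$noise_sd)

    # pathological columns, injected after the signal is fixed
    path <- list()
    if (spec$n_constant)
      for (i in seq_len(spec$n_constant))
        path[[sprintf("CONST%d", i)]] <- rep(runif(1, -1, 1), n)
    if (spec$n_near_constant)
      for (i in seq_len(spec$n_near_constant))
        path[[sprintf("NEARCONST%d", i)]] <- runif(1, -1, 1) + rnorm(n, 0, 1e-5)
    if (spec$n_missing)
      for (i in seq_len(spec$n_missing)) {
        v <- rnorm(n); v[sample.int(n, max(1L, n %/% 10))] <- NA
        path[[sprintf("MISS%d", i)]] <- v
      }
    if (length(path)) X <- cbind(X, do.call(cbind, path))

    ids <- c(sprintf("C%03d", seq_len(spec$n_compounds)),
             if (spec$n_discordant) sprintf("X%03d", seq_len(spec$n_discordant)))
    rownames(X) <- ids
    retained <- seq_len(spec$n_compounds)
    y <- stats::setNames(y_all[retained], ids[retained])

    # long-format literature records: concordant pairs average exactly to y
    two_src <- runif(spec$n_compounds) < spec$two_source_frac
    rows <- list()
    for (i in retained) {
      if (two_src[i]) {
        d <- runif(1, 0, spec$source_jitter)
        rows[[length(rows) + 1L]] <- data.frame(
          id = ids[i], source = c("srcA", "srcB"),
          ot_nmol = 10^(y[i] + c(d, -d)))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          id = ids[i], source = "srcA", ot_nmol = 10^unname(y[i]))
      }
    }
    if (spec$n_discordant)
      for (i in seq_len(spec$n_discordant)) {
        base <- y_all[spec$n_compounds + i]
        gap <- 1.5 + runif(1, 0.1, 1.5)
        rows[[length(rows) + 1L]] <- data.frame(
          id = ids[spec$n_compounds + i], source = c("srcA", "srcB"),
          ot_nmol = 10^c(base, base + gap))
      }
    compounds <- do.call(rbind, rows)
    compounds$name <- compounds$id
    compounds$smiles <- NA_character_
    compounds <- compounds[, c("id", "name", "smiles", "source", "ot_nmol")]

    structure(list(compounds = compounds, X = X, y = y,
                   truth = list(terms = terms, intercept = spec$intercept,
                                noise_sd = spec$noise_sd,
                                signal_sd = sd(signal[retained])),
                   spec = spec),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic QSPR study: %d retained + %d discordant compounds, %d descriptors\n",
    x$spec$n_compounds, x$spec$n_discordant, ncol(x$X)))
  cat(sprintf("planted terms: %s | signal SD %.3f, noise SD %.3f\n",
              paste(vapply(x$truth$terms, function(t)
                if (t$kind == "spline") sprintf("<%g-%s>", t$knot, t$descriptor)
                else t$descriptor, ""), collapse = ", "),
              x$truth$signal_sd, x$truth$noise_sd))
  invisible(x)
}

#' Generate random wine compositions
#'
#' Random component subsets without replacement; compositions of different
#' wines may overlap (as the four study wines' component lists do) and the
#' mean pairwise overlap is reported.
#'
#' @param compound_ids pool of component ids.
#' @param n_wines number of wines (default 4).
#' @param components_per_wine single size or vector of per-wine sizes
#'   (default `c(42, 42, 45, 45)`, the component counts of the four study
#'   wines).
#' @param seed integer seed.
#' @return list of [wine_composition()]s with attribute `"overlap"` (mean
#'   pairwise Jaccard overlap).
#' @export
make_wines <- function(compound_ids, n_wines = 4L,
                       components_per_wine = c(42L, 42L, 45L, 45L),
                       seed = 1L) {
  sizes <- rep(components_per_wine, length.out = n_wines)
  if (any(sizes > length(compound_ids)))
    stopf("components_per_wine exceeds number of compounds")
  wines <- with_seed(seed, lapply(seq_len(n_wines), function(i)
    wine_composition(sprintf("wine%d", i),
                     sample(compound_ids, sizes[i]))))
  jac <- c()
  if (n_wines > 1)
    for (i in seq_len(n_wines - 1)) for (j in (i + 1):n_wines) {
      a <- wines[[i]]$components; b <- wines[[j]]$components
      jac <- c(jac, length(intersect(a, b)) / length(union(a, b)))
    }
  attr(wines, "overlap") <- if (length(jac)) mean(jac) else NA_real_
  wines
}

#' Write a synthetic study as the pipeline's CSV inputs
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if absent).
#' @return invisible named list of the file paths written
#'   (`compounds`, `descriptors`).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cp <- file.path(dir, "compounds.csv")
  dp <- file.path(dir, "descriptors.csv")
  write.csv(study$compounds, cp, row.names = FALSE)
  write.csv(data.frame(id = rownames(study$X), study$X,
                       check.names = FALSE),
            dp, row.names = FALSE)
  invisible(list(compounds = cp, descriptors = dp))
}
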
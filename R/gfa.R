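# Genetic function approximation (GFA): evolves regression equations whose
# terms are raw descriptors or truncated spline basis functions <knot - x>,
# scored by Friedman's lack-of-fit (LOF).

#' GFA configuration
#'
#' Defaults follow the settings used for descriptor selection on the
#' odor-threshold set: 50% mutation probability, 5000 iterations, smoothness
#' d = 1.00, initial equation length 4, no cap on equation length. Population
#' size is not published for the original software; 100 is used here.
#'
#' @param population_size number of genomes kept in the steady-state
#'   population.
#' @param iterations number of genetic operations (crossover + mutation +
#'   replacement steps).
#' @param p_mut per-child mutation probability.
#' @param smoothness Friedman LOF smoothness parameter d.
#' @param initial_length number of terms in each initial genome.
#' @param max_length optional cap on genome length (NULL = unlimited).
#' @param term_kinds `"mixed"` (linear and spline terms, default), `"linear"`,
#'   or `"spline"`.
#' @param seed integer seed; the whole run is deterministic given the seed.
#' @export
gfa_config <- function(population_size = 100L, iterations = 5000L,
                       p_mut = 0.5, smoothness = 1.0, initial_length = 4L,
                       max_length = NULL,
                       term_kinds = c("mixed", "linear", "spline"),
                       seed = 1L) {
  term_kinds <- match.arg(term_kinds)
  stopifnot(p_mut >= 0, p_mut <= 1, iterations >= 0, population_size >= 2,
            initial_length >= 1)
  structure(list(population_size = as.integer(population_size),
                 iterations = as.integer(iterations), p_mut = p_mut,
                 smoothness = smoothness,
                 initial_length = as.integer(initial_length),
                 max_length = max_length, term_kinds = term_kinds,
                 seed = as.integer(seed)),
            class = "gfa_config")
}

#' Friedman lack-of-fit score
#'
#' LOF = LSE / (1 - (c + d*p)/M)^2, where LSE is the least-squares error
#' (residual sum of squares), c the number of basis terms excluding the
#' intercept, p the total number of fitted parameters (coefficients including
#' the intercept, plus spline knots), M the number of training samples and d
#' the smoothness parameter. Smaller is better; models too large for their
#' sample (denominator <= 0) score +Inf.
#'
#' @param lse residual sum of squares (>= 0).
#' @param n_terms c, number of basis terms.
#' @param n_params p, total fitted parameters including knots.
#' @param n_samples M.
#' @param smoothness d.
#' @export
lof_score <- function(lse, n_terms, n_params, n_samples, smoothness = 1.0) {
  stopifnot(lse >= 0)
  den <- 1 - (n_terms + smoothness * n_params) / n_samples
  if (den <= 0) return(Inf)
  lse / den^2
}

term_label <- function(t)
  if (t$kind == "spline") sprintf("<%g-%s>", t$knot, t$descriptor) else t$descriptor

term_key <- function(t)
  paste(t$descriptor, t$kind, if (t$kind == "spline") signif(t$knot, 12) else "", sep = "\r")

dedup_terms <- function(terms) terms[!duplicated(vapply(terms, term_key, ""))]

#' Build the design matrix of a term list on raw descriptor values
#'
#' Linear terms contribute the raw descriptor column; spline terms contribute
#' the evaluated chevron basis `<knot - x>`. Column names use the chevron
#' notation.
#' @param terms list of term lists (`descriptor`, `kind`, `knot`).
#' @param X raw descriptor matrix.
#' @export
term_design <- function(terms, X) {
  cols <- lapply(terms, function(t) {
    x <- X[, t$descriptor]
    if (t$kind == "spline") spline_value(x, t$knot) else x
  })
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(terms, term_label, "")
  m
}

random_term <- function(pool, X, term_kinds) {
  d <- pool[sample.int(length(pool), 1L)]
  kind <- switch(term_kinds,
                 linear = "linear", spline = "spline",
                 mixed = if (runif(1) < 0.5) "spline" else "linear")
  knot <- if (kind == "spline") sample(X[, d], 1L) else NA_real_
  list(descriptor = d, kind = kind, knot = knot)
}

#' Least-squares fit and LOF scoring of a genome's term list
#' @noRd
fit_genome <- function(terms, X, y, smoothness) {
  terms <- dedup_terms(terms)
  M <- length(y)
  Z <- cbind(`(Intercept)` = 1, term_design(terms, X))
  fit <- lm.fit(Z, y)
  lse <- sum(fit$residuals^2)
  cc <- length(terms)
  n_knots <- sum(vapply(terms, function(t) t$kind == "spline", logical(1)))
  p <- cc + 1L + n_knots
  structure(list(terms = terms,
                 coefficients = stats::setNames(fit$coefficients, colnames(Z)),
                 lse = lse,
                 lof = lof_score(lse, cc, p, M, smoothness)),
            class = "gfa_genome")
}

#' @export
print.gfa_genome <- function(x, ...) {
  cat(sprintf("GFA equation (%d terms): LOF %.4g, LSE %.4g\n  log(OT) ~ %s\n",
              length(x$terms), x$lof, x$lse,
              paste(vapply(x$terms, term_label, ""), collapse = " + ")))
  invisible(x)
}

#' Initialize a GFA population
#'
#' Each genome draws `initial_length` distinct descriptors uniformly without
#' replacement; each term is linear or spline with probability 1/2 (under the
#' mixed option), spline knots being sampled from the observed training values
#' of that descriptor. Every genome is least-squares fitted and LOF-scored.
#'
#' @param X raw (prefiltered) training descriptor matrix.
#' @param y training response.
#' @param cfg a [gfa_config()].
#' @return list of `gfa_genome` objects.
#' @export
initialize_population <- function(X, y, cfg) {
  pool <- colnames(X)
  if (length(pool) < cfg$initial_length)
    stopf("descriptor pool (%d) smaller than initial equation length (%d)",
          length(pool), cfg$initial_length)
  with_seed(cfg$seed, replicate(cfg$population_size, simplify = FALSE, {
    ds <- sample(pool, cfg$initial_length)
    terms <- lapply(ds, function(d) {
      t <- random_term(d, X, cfg$term_kinds); t$descriptor <- d; t
    })
    fit_genome(terms, X, y, cfg$smoothness)
  }))
}

#' Crossover of two GFA genomes
#'
#' Each parent is cut at a random position; the child is the first parent's
#' prefix spliced to the second parent's suffix, with duplicate terms dropped,
#' then refitted and rescored. Cuts yielding an empty child are retried; after
#' `max_retry` failures the fitter parent is copied.
#'
#' @param a,b parent `gfa_genome`s.
#' @param X,y training data. @param smoothness LOF smoothness d.
#' @param max_retry bounded retries for empty children.
#' @export
crossover <- function(a, b, X, y, smoothness = 1.0, max_retry = 10L) {
  for (i in seq_len(max_retry)) {
    ia <- sample(0:length(a$terms), 1L)
    ib <- sample(0:length(b$terms), 1L)
    child <- c(a$terms[seq_len(ia)],
               if (ib < length(b$terms)) b$terms[(ib + 1L):length(b$terms)])
    child <- dedup_terms(child)
    if (length(child) >= 1L) return(fit_genome(child, X, y, smoothness))
  }
  if (a$lof <= b$lof) a else b
}

#' Mutate a GFA genome
#'
#' With probability `p_mut` one mutation is applied, drawn uniformly from:
#' add a random term, delete a random term (length > 1 only), replace a term's
#' descriptor, resample a spline knot (spline terms only), toggle a term
#' between linear and spline. The genome is refitted and rescored.
#'
#' @param g a `gfa_genome`. @param X,y training data.
#' @param p_mut mutation probability. @param cfg a [gfa_config()] (term kinds,
#'   smoothness, max length).
#' @export
mutate <- function(g, X, y, p_mut, cfg) {
  if (runif(1) >= p_mut) return(g)
  key0 <- sort(vapply(g$terms, term_key, ""))
  # a drawn operation can be a no-op (e.g. a knot resampled to the same
  # observed value); retry so that a requested mutation always changes
  # the genome
  for (try in 1:20) {
    out <- dedup_terms(mutate_once(g, X, cfg))
    if (!identical(sort(vapply(out, term_key, "")), key0))
      return(fit_genome(out, X, y, cfg$smoothness))
  }
  fit_genome(out, X, y, cfg$smoothness)
}

mutate_once <- function(g, X, cfg) {
  terms <- g$terms
  pool <- colnames(X)
  menu <- c("add", "replace", "toggle")
  if (length(terms) > 1L) menu <- c(menu, "delete")
  if (any(vapply(terms, function(t) t$kind == "spline", logical(1))))
    menu <- c(menu, "knot")
  if (!is.null(cfg$max_length) && length(terms) >= cfg$max_length)
    menu <- setdiff(menu, "add")
  if (cfg$term_kinds != "mixed") menu <- setdiff(menu, "toggle")
  op <- sample(menu, 1L)
  i <- sample.int(length(terms), 1L)
  switch(op,
    add = c(terms, list(random_term(pool, X, cfg$term_kinds))),
    delete = terms[-i],
    replace = { t <- terms[[i]]
      t$descriptor <- pool[sample.int(length(pool), 1L)]
      if (t$kind == "spline") t$knot <- sample(X[, t$descriptor], 1L)
      terms[[i]] <- t; terms },
    knot = { sp <- which(vapply(terms, function(t) t$kind == "spline", logical(1)))
      j <- sp[sample.int(length(sp), 1L)]
      terms[[j]]$knot <- sample(X[, terms[[j]]$descriptor], 1L); terms },
    toggle = { t <- terms[[i]]
      if (t$kind == "linear") { t$kind <- "spline"; t$knot <- sample(X[, t$descriptor], 1L) }
      else { t$kind <- "linear"; t$knot <- NA_real_ }
      terms[[i]] <- t; terms })
}

#' Evolve a GFA population
#'
#' Steady-state genetic search: per iteration two parents are chosen by size-2
#' tournaments on LOF, crossed over, the child possibly mutated, refitted, and
#' the worst member of the population replaced. The best LOF is non-increasing
#' across iterations. Fully deterministic given `cfg$seed`.
#'
#' @param X raw (prefiltered) training descriptor matrix.
#' @param y training response (log(OT)).
#' @param cfg a [gfa_config()].
#' @return object of class `gfa_result`: list with `population` (genomes
#'   sorted by ascending LOF), `best_trace` (best LOF per iteration), `config`.
#' @export
evolve <- function(X, y, cfg = gfa_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (sd(y) == 0) stopf("response has zero variance")
  pop <- initialize_population(X, y, cfg)
  best <- min(vapply(pop, `[[`, 0, "lof"))
  trace <- numeric(cfg$iterations)
  with_seed(child_seed(cfg$seed, "evolve"), {
    for (it in seq_len(cfg$iterations)) {
      lofs <- vapply(pop, `[[`, 0, "lof")
      tourn <- function() { c2 <- sample.int(length(pop), 2L)
                            c2[which.min(lofs[c2])] }
      a <- pop[[tourn()]]; b <- pop[[tourn()]]
      child <- crossover(a, b, X, y, cfg$smoothness)
      child <- mutate(child, X, y, cfg$p_mut, cfg)
      worst <- which.max(lofs)
      pop[[worst]] <- child
      best <- min(best, child$lof)
      trace[it] <- best
    }
  })
  ord <- order(vapply(pop, `[[`, 0, "lof"))
  structure(list(population = pop[ord], best_trace = trace, config = cfg),
            class = "gfa_result")
}

#' @export
print.gfa_result <- function(x, ...) {
  cat(sprintf("GFA run: population %d, %d iterations, best LOF %.4g\n",
              length(x$population), x$config$iterations,
              x$population[[1]]$lof))
  print(x$population[[1]])
  invisible(x)
}

#' Union descriptor pool of the top GFA models
#'
#' Collects the distinct descriptor names used by the `m` best equations
#' (spline and linear occurrences of the same descriptor count once),
#' insertion-ordered by model rank then term order.
#'
#' @param result a `gfa_result` (or plain list of genomes, already ranked).
#' @param m number of top models to pool (default 5).
#' @export
descriptor_pool <- function(result, m = 5L) {
  models <- if (inherits(result, "gfa_result")) result$population else result
  if (length(models) == 0L) stopf("empty model list")
  m <- min(m, length(models))
  unique(unlist(lapply(models[seq_len(m)], function(g)
    vapply(g$terms, function(t) t$descriptor, ""))))
}

#' Union spline/linear term pool of the top GFA models
#'
#' Like [descriptor_pool()] but keeps the distinct terms themselves (with
#' knots), so downstream stages can use GFA-derived spline terms as fixed
#' transformed columns.
#' @inheritParams descriptor_pool
#' @export
term_pool <- function(result, m = 5L) {
  models <- if (inherits(result, "gfa_result")) result$population else result
  if (length(models) == 0L) stopf("empty model list")
  m <- min(m, length(models))
  dedup_terms(do.call(c, lapply(models[seq_len(m)], `[[`, "terms")))
}

#' Write a ranked GFA model report
#' @param result a `gfa_result`. @param path CSV path.
#' @param top how many models to report.
#' @export
write_gfa_report <- function(result, path, top = 10L) {
  models <- result$population[seq_len(min(top, length(result$population)))]
  df <- data.frame(
    rank = seq_along(models),
    lof = vapply(models, `[[`, 0, "lof"),
    lse = vapply(models, `[[`, 0, "lse"),
    terms = vapply(models, function(g)
      paste(vapply(g$terms, term_label, ""), collapse = " + "), ""),
    coefficients = vapply(models, function(g)
      paste(signif(g$coefficients, 6), collapse = ";"), ""))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
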
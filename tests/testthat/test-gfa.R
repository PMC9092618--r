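toy_pool <- function(n = 40, p = 8, seed = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", seq_len(p))))
  X
}

test_that("lack-of-fit score follows the penalized closed form", {
  expect_equal(lof_score(0, 3, 4, 50), 0)
  expect_equal(lof_score(10, 2, 2, 10, smoothness = 0), 10 / 0.8^2)  # 15.625
  expect_equal(lof_score(10, 2, 2, 10, smoothness = 1), 10 / 0.6^2)
  expect_equal(lof_score(10, 5, 5, 10, smoothness = 1), Inf)  # overparameterized
  # strictly increasing in lse, c, p
  base <- lof_score(5, 2, 3, 40)
  expect_gt(lof_score(6, 2, 3, 40), base)
  expect_gt(lof_score(5, 3, 3, 40), base)
  expect_gt(lof_score(5, 2, 4, 40), base)
})

test_that("initial population is deterministic, sized and fitted", {
  X <- toy_pool()
  y <- rnorm(40)
  cfg <- gfa_config(population_size = 20, initial_length = 4, seed = 42)
  pop1 <- initialize_population(X, y, cfg)
  pop2 <- initialize_population(X, y, cfg)
  expect_identical(pop1, pop2)                       # same seed -> same genomes
  expect_length(pop1, 20)
  expect_true(all(vapply(pop1, function(g) length(g$terms), 0L) == 4))
  # every genome's LSE equals an independently solved least-squares RSS
  for (g in pop1[1:5]) {
    Z <- term_design(g$terms, X)
    rss <- sum(resid(lm(y ~ Z))^2)
    expect_equal(g$lse, rss, tolerance = 1e-8)
  }
  # forced full pool when initial_length equals pool size
  Xs <- X[, 1:4]
  cfg4 <- gfa_config(population_size = 5, initial_length = 4, seed = 1)
  pop4 <- initialize_population(Xs, y, cfg4)
  for (g in pop4)
    expect_setequal(vapply(g$terms, `[[`, "", "descriptor"), colnames(Xs))
  expect_error(initialize_population(X[, 1:3], y, cfg), "smaller")
})

test_that("crossover splices prefixes/suffixes and deduplicates terms", {
  X <- toy_pool(); y <- rnorm(40)
  cfg <- gfa_config(population_size = 4, initial_length = 3, seed = 7)
  pop <- initialize_population(X, y, cfg)
  set.seed(1)
  for (i in 1:20) {
    child <- crossover(pop[[1]], pop[[2]], X, y)
    keys <- vapply(child$terms, function(t)
      paste(t$descriptor, t$kind, t$knot), "")
    expect_false(any(duplicated(keys)))
    expect_gte(length(child$terms), 1)
    parent_keys <- vapply(c(pop[[1]]$terms, pop[[2]]$terms), function(t)
      paste(t$descriptor, t$kind, t$knot), "")
    expect_true(all(keys %in% parent_keys))
  }
  # identical parents: child terms are a subset of the parent's
  child <- crossover(pop[[3]], pop[[3]], X, y)
  pk <- vapply(pop[[3]]$terms, function(t) paste(t$descriptor, t$kind, t$knot), "")
  ck <- vapply(child$terms, function(t) paste(t$descriptor, t$kind, t$knot), "")
  expect_true(all(ck %in% pk))
})

test_that("mutation respects probability and the operation guards", {
  X <- toy_pool(); y <- rnorm(40)
  cfg <- gfa_config(population_size = 2, initial_length = 3, seed = 5)
  g <- initialize_population(X, y, cfg)[[1]]
  set.seed(2)
  expect_identical(mutate(g, X, y, p_mut = 0, cfg), g)
  key <- function(m) vapply(m$terms, function(t)
    paste(t$descriptor, t$kind, t$knot), "")
  for (i in 1:20) {
    m <- mutate(g, X, y, p_mut = 1, cfg)
    expect_false(identical(sort(key(m)), sort(key(g))))
  }
  # a length-1 genome is never deleted to extinction
  g1 <- aromaQSPR:::fit_genome(g$terms[1], X, y, 1)
  for (i in 1:20) expect_gte(length(mutate(g1, X, y, 1, cfg)$terms), 1)
})

test_that("evolution recovers an exact linear signal and is elitist", {
  X <- toy_pool(n = 50, p = 10, seed = 8)
  y <- 2 + 3 * X[, "x1"]                 # noise-free, single linear truth
  cfg <- gfa_config(population_size = 40, iterations = 150, seed = 3)
  res <- evolve(X, y, cfg)
  best <- res$population[[1]]
  expect_true("x1" %in% vapply(best$terms, `[[`, "", "descriptor"))
  expect_lt(best$lse, 1e-10)
  expect_true(all(diff(res$best_trace) <= 1e-12))  # best LOF non-increasing
  # zero iterations returns the scored initial population
  res0 <- evolve(X, y, gfa_config(population_size = 10, iterations = 0, seed = 4))
  expect_length(res0$population, 10)
  expect_error(evolve(X, rep(1, 50), cfg), "zero variance")
  # determinism of the whole run
  res2 <- evolve(X, y, cfg)
  expect_identical(res$population[[1]], res2$population[[1]])
})

test_that("with d = 0 and fixed term count, LOF ranks like LSE", {
  X <- toy_pool(); y <- rnorm(40)
  cfg <- gfa_config(population_size = 15, initial_length = 3, seed = 9,
                    smoothness = 0)
  pop <- initialize_population(X, y, cfg)
  all_linear <- vapply(pop, function(g)
    all(vapply(g$terms, `[[`, "", "kind") == "linear"), logical(1))
  sub <- pop[all_linear]   # same c and p across these genomes
  lofs <- vapply(sub, `[[`, 0, "lof")
  lses <- vapply(sub, `[[`, 0, "lse")
  expect_equal(order(lofs), order(lses))
})

test_that("descriptor pool is the rank-ordered union over top models", {
  mk <- function(...) list(terms = lapply(list(...), function(d)
    list(descriptor = d, kind = "linear", knot = NA_real_)))
  models <- list(mk("A", "B"), mk("B", "C"), mk("D"))
  expect_equal(descriptor_pool(models, m = 1), c("A", "B"))
  expect_equal(descriptor_pool(models, m = 2), c("A", "B", "C"))
  expect_equal(descriptor_pool(models, m = 3), c("A", "B", "C", "D"))
  expect_error(descriptor_pool(list()), "empty")
})
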
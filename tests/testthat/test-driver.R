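fast_cfg <- function(...) {
  run_config(n_generations = 15L, pop_size = 8L, sa_refine_iters = 8L,
             ...)
}

test_that("all four optimizers keep a non-decreasing gbest trace", {
  target <- rep(c(1L, 0L), 6)
  fit <- bitmatch_fitness(target)
  for (m in c("proposed", "hybrid_no_diversity", "bumda", "ga")) {
    res <- run_baseline(m, NULL, NULL, fast_cfg(seed = 3L),
                        fitness_fn = fit)
    expect_s3_class(res, "run_result")
    expect_false(is.unsorted(res$logs$gbest_fitness))
    expect_equal(res$gbest$fitness, fit(res$gbest$bits))
    expect_true(all(res$selection_frequency >= 0 &
                      res$selection_frequency <= 1))
    expect_lte(res$best_generation, res$n_generations)
  }
  sa_cfg <- run_config(pop_size = 2L, sa_t0 = 1, sa_t_end = 0,
                       sa_step = 1 / 60, seed = 3L)
  res_sa <- run_baseline("sa", NULL, NULL, sa_cfg, fitness_fn = fit)
  expect_false(is.unsorted(res_sa$logs$gbest_fitness))
  expect_equal(res_sa$n_generations, 60L)
  expect_error(run_baseline("nope", NULL, NULL, fast_cfg(seed = 1L),
                            fitness_fn = fit), class = "driver_error")
})

test_that("runs are reproducible from their seed", {
  fit <- bitmatch_fitness(rep(c(1L, 0L, 1L), 4))
  a <- run_hybrid(NULL, NULL, fast_cfg(seed = 11L), fitness_fn = fit)
  b <- run_hybrid(NULL, NULL, fast_cfg(seed = 11L), fitness_fn = fit)
  expect_identical(a$gbest, b$gbest)
  expect_identical(a$logs, b$logs)
})

test_that("the gbest is only replaced on strict improvement", {
  # constant fitness: the first refined individual sets gbest, and no later
  # tie may move best_generation
  fit <- function(bits) 0.5
  attr(fit, "n_features") <- 6L
  res <- run_hybrid(NULL, NULL, fast_cfg(seed = 2L), fitness_fn = fit)
  expect_equal(res$best_generation, 1L)
  expect_true(all(res$logs$gbest_fitness == 0.5))
})

test_that("SA refinement inside the loop helps over plain BUMDA", {
  target <- c(rep(1L, 4), rep(0L, 12))
  fit <- bitmatch_fitness(target)
  wins <- 0L
  for (seed in 1:10) {
    cfg <- fast_cfg(seed = seed)
    a <- run_baseline("hybrid_no_diversity", NULL, NULL, cfg,
                      fitness_fn = fit)
    b <- run_baseline("bumda", NULL, NULL, cfg, fitness_fn = fit)
    if (a$gbest$fitness >= b$gbest$fitness) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("diversity control inverts sorting when the worst outranks", {
  prob <- tiny_problem(n_samples = 80, n_features = 10, seed = 13)
  cfg <- run_config(n_generations = 12L, pop_size = 6L,
                    sa_refine_iters = 10L, seed = 13L)
  res <- run_hybrid(prob$ds, prob$part, cfg, diversity = TRUE)
  res0 <- run_hybrid(prob$ds, prob$part, cfg, diversity = FALSE)
  expect_false(any(res0$logs$sort_inverted))
  expect_type(res$logs$sort_inverted, "logical")
  expect_false(is.unsorted(res$logs$gbest_fitness))
})

test_that("selection frequencies count bit occupancy exactly", {
  counts <- rbind(c(2L, 0L, 1L), c(2L, 1L, 0L)) # 2 generations, pop 2
  freq <- selection_frequencies(counts, pop_size = 2L)
  expect_equal(freq, c(1, 0.25, 0.25))

  set.seed(19)
  npop <- 20L; G <- 50L; n <- 30L
  counts2 <- matrix(rbinom(G * n, npop, 0.5), G, n)
  freq2 <- selection_frequencies(counts2, pop_size = npop)
  se <- sqrt(0.25 / (G * npop))
  expect_true(all(abs(freq2 - 0.5) < 5 * se))
})

test_that("frequency statistics agree with base R", {
  expect_equal(unname(frequency_stats(rep(0.3, 4))),
               c(0.3, 0.3, 0.3, 0.3, 0, 0))
  expect_equal(unname(frequency_stats(c(0, 1))[1:4]), c(0, 1, 0.5, 0.5))
  set.seed(23)
  x <- runif(100)
  fs <- frequency_stats(x)
  expect_equal(fs[["mean"]], mean(x), tolerance = 1e-12)
  expect_equal(fs[["variance"]], var(x), tolerance = 1e-12)
  expect_equal(fs[["std"]]^2, fs[["variance"]], tolerance = 1e-12)
  expect_equal(fs[["median"]], median(x), tolerance = 1e-12)
})

test_that("best-generation statistics require and use multiple trials", {
  fake <- function(g) structure(list(best_generation = g),
                                class = "run_result")
  st <- best_generation_stats(list(fake(100), fake(300)))
  expect_equal(st[["mean"]], 200)
  expect_equal(st[["median"]], 200)
  expect_error(best_generation_stats(list(fake(10))),
               class = "driver_error")
})

test_that("the wrapper-driven hybrid recovers planted features", {
  prob <- tiny_problem(n_samples = 100, n_features = 12, n_informative = 3,
                       effect_size = 2.5, seed = 29)
  cfg <- run_config(n_generations = 20L, pop_size = 10L,
                    sa_refine_iters = 10L, seed = 29L)
  res <- run_hybrid(prob$ds, prob$part, cfg)
  expect_gte(sum(res$gbest$bits[prob$truth]), 2L)
  fin <- finalize_result(res, prob$ds, prob$part, cfg)
  expect_s3_class(fin$metrics, "metric_report")
  expect_gt(fin$metrics$accuracy, 0.5)
})
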
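test_that("feature tables load with labels and preserved column order", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,label", "1,4,0", "2,5,1", "3,6,1"), f)
  ds <- load_feature_table(f)
  expect_equal(dim(ds$features), c(3L, 2L))
  expect_equal(ds$labels, c(0L, 1L, 1L))
  expect_equal(ds$feature_names, c("a", "b"))
  expect_equal(ds$features[, "b"], c(4, 5, 6), ignore_attr = TRUE)
})

test_that("defective tables are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,a,label", "1,2,0", "3,4,1"), f)
  expect_error(load_feature_table(f), "a", class = "dataset_error")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,label", "1,x,0", "2,5,1"), g)
  expect_error(load_feature_table(g), class = "dataset_error")

  h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,other", "1,2,0"), h)
  expect_error(load_feature_table(h, "label"), class = "dataset_error")
})

test_that("write/load round-trips a random table", {
  set.seed(11)
  ds <- labeled_dataset(matrix(rnorm(50), 10, 5),
                        rep(c(0L, 1L), 5), sprintf("f%d", 1:5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ds, f)
  back <- load_feature_table(f)
  expect_equal(back$features, ds$features, tolerance = 1e-12)
  expect_identical(back$labels, ds$labels)
})

test_that("dataset invariants are enforced", {
  expect_error(labeled_dataset(matrix(c(1, NA), 1), 0L),
               class = "dataset_error")
  expect_error(labeled_dataset(matrix(1:4, 2), c(0L, 2L)),
               class = "dataset_error")
  expect_error(labeled_dataset(matrix(1:4, 2), c(0L, 1L), c("x", "x")),
               class = "dataset_error")
})

test_that("the reference 458/50/100 split has the right shape", {
  gen <- make_feature_dataset(synthetic_spec(n_samples = 608L,
                                             n_features = 5L, seed = 2))
  part <- split_dataset(gen$dataset, c(458L, 50L, 100L), seed = 9)
  expect_length(part$train_idx, 458L)
  expect_length(part$validation_idx, 50L)
  expect_length(part$test_idx, 100L)
  all_idx <- c(part$train_idx, part$validation_idx, part$test_idx)
  expect_equal(sort(all_idx), 1:608)
  # balanced 304/304 source stays balanced within +/- 1 per split
  for (idx in list(part$train_idx, part$validation_idx, part$test_idx)) {
    n_pos <- sum(gen$dataset$labels[idx])
    expect_lte(abs(n_pos - length(idx) / 2), 1)
  }
})

test_that("splits are disjoint, covering and seed-deterministic", {
  gen <- make_feature_dataset(synthetic_spec(n_samples = 60L,
                                             n_features = 4L,
                                             n_informative = 2L, seed = 5))
  for (seed in 1:5) {
    for (strat in c(TRUE, FALSE)) {
      p <- split_dataset(gen$dataset, c(40L, 10L, 10L), seed, strat)
      all_idx <- c(p$train_idx, p$validation_idx, p$test_idx)
      expect_equal(sort(all_idx), 1:60)
      expect_equal(anyDuplicated(all_idx), 0L)
    }
    p1 <- split_dataset(gen$dataset, c(40L, 10L, 10L), seed)
    p2 <- split_dataset(gen$dataset, c(40L, 10L, 10L), seed)
    expect_identical(p1, p2)
  }
})

test_that("degenerate split requests error", {
  gen <- make_feature_dataset(synthetic_spec(n_samples = 20L,
                                             n_features = 3L,
                                             n_informative = 1L, seed = 1))
  expect_error(split_dataset(gen$dataset, c(20L, 0L, 0L), 1),
               class = "partition_error")
  expect_error(split_dataset(gen$dataset, c(10L, 5L, 4L), 1),
               class = "partition_error")
})

test_that("run configuration validates and round-trips through files", {
  expect_error(run_config(pop_size = 1L), class = "config_error")
  expect_error(run_config(w_accuracy = 0.5, w_fdr = 0.6),
               class = "config_error")
  expect_error(run_config(sa_t0 = 0, sa_t_end = 0), class = "config_error")
  expect_error(kernel_spec("polynomial", kernel_scale = 0),
               class = "config_error")

  cfg <- run_config(n_generations = 50L, pop_size = 10L, seed = 3L,
                    kernel = kernel_spec("polynomial", 5, 2, 0.3569))
  f <- withr::local_tempfile(fileext = ".json")
  save_run_config(cfg, f)
  back <- load_run_config(f)
  expect_equal(back$n_generations, 50L)
  expect_equal(back$weights$w_accuracy, 0.9)
  expect_equal(back$kernel$kernel_offset, 0.3569)

  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_generations: 25", "pop_size: 8", "seed: 4",
               "kernel:", "  kind: linear"), y)
  cfg_y <- load_run_config(y)
  expect_equal(cfg_y$n_generations, 25L)
  expect_equal(cfg_y$kernel$kind, "linear")
})
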
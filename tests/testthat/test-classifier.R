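make_blobs <- function(n_per = 20, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2, -sep / 2, 0.5), ncol = 2),
             matrix(rnorm(n_per * 2, sep / 2, 0.5), ncol = 2))
  list(X = X, y = rep(c(0L, 1L), each = n_per))
}

make_xor <- function(n_per = 10, seed = 2) {
  set.seed(seed)
  centers <- rbind(c(-2, -2), c(2, 2), c(-2, 2), c(2, -2))
  lab <- c(0L, 0L, 1L, 1L)
  X <- NULL; y <- NULL
  for (k in 1:4) {
    X <- rbind(X, sweep(matrix(rnorm(n_per * 2, 0, 0.3), ncol = 2), 2,
                        centers[k, ], `+`))
    y <- c(y, rep(lab[k], n_per))
  }
  list(X = X, y = y)
}

test_that("separable blobs are fit perfectly by the linear kernel", {
  b <- make_blobs()
  clf <- train_classifier(b$X, b$y, kernel_spec("linear"))
  expect_equal(predict(clf, b$X), b$y)
  # score sign agrees with the class contract
  sc <- predict(clf, b$X, type = "score")
  expect_equal(as.integer(sc >= 0), b$y)
})

test_that("XOR defeats every linear separator but yields to a polynomial", {
  x <- make_xor()
  # brute-force oracle: no linear threshold w.x + b separates XOR means the
  # best achievable linear accuracy stays well below 1
  best_linear <- 0
  for (ang in seq(0, pi, length.out = 60)) {
    proj <- x$X %*% c(cos(ang), sin(ang))
    for (thr in sort(proj)) {
      acc <- max(mean((proj >= thr) == (x$y == 1)),
                 mean((proj < thr) == (x$y == 1)))
      best_linear <- max(best_linear, acc)
    }
  }
  expect_lte(best_linear, 0.75)

  lin <- train_classifier(x$X, x$y, kernel_spec("linear"))
  expect_lte(mean(predict(lin, x$X) == x$y), 0.75)

  poly <- train_classifier(x$X, x$y, kernel_spec("polynomial", 2, 1, 1))
  expect_equal(mean(predict(poly, x$X) == x$y), 1)
})

test_that("training and prediction are deterministic", {
  b <- make_blobs(sep = 2)
  grid <- as.matrix(expand.grid(seq(-3, 3, 0.5), seq(-3, 3, 0.5)))
  p1 <- predict(train_classifier(b$X, b$y), grid, type = "score")
  p2 <- predict(train_classifier(b$X, b$y), grid, type = "score")
  expect_identical(p1, p2)
})

test_that("degenerate training inputs error", {
  b <- make_blobs()
  expect_error(train_classifier(b$X[b$y == 1, ], b$y[b$y == 1]),
               class = "classifier_error")
  expect_error(train_classifier(b$X[, 0], b$y), class = "classifier_error")
})

test_that("masking selects columns: permuting unselected columns is inert", {
  prob <- tiny_problem(n_samples = 80, n_features = 8, seed = 4)
  mask <- c(1, 1, 1, 0, 0, 0, 0, 0)
  ev1 <- evaluate_subset(prob$ds, prob$part, mask)
  ds2 <- prob$ds
  perm <- c(1:3, 8, 7, 6, 5, 4)
  ds2$features[, 4:8] <- ds2$features[, perm[4:8]]
  ev2 <- evaluate_subset(ds2, prob$part, mask)
  expect_identical(ev1$confusion, ev2$confusion)

  # full mask equals training on the unmasked matrix directly
  full <- rep(1, 8)
  ev3 <- evaluate_subset(prob$ds, prob$part, full)
  clf <- train_classifier(prob$ds$features[prob$part$train_idx, ],
                          prob$ds$labels[prob$part$train_idx])
  pred <- predict(clf, prob$ds$features[prob$part$validation_idx, ])
  expect_equal(ev3$accuracy,
               mean(pred == prob$ds$labels[prob$part$validation_idx]))
})

test_that("informative features beat noise features on holdout data", {
  prob <- tiny_problem(n_samples = 150, n_features = 10, n_informative = 3,
                       effect_size = 2.5, seed = 6)
  acc_true <- evaluate_subset(prob$ds, prob$part,
                              as.integer(prob$truth))$accuracy
  noise_mask <- as.integer(!prob$truth)
  acc_noise <- evaluate_subset(prob$ds, prob$part, noise_mask)$accuracy
  expect_gt(acc_true, acc_noise)
  expect_gt(acc_true, 0.8)
})

test_that("no-signal data stays near chance accuracy", {
  gen <- make_feature_dataset(synthetic_spec(n_samples = 200, n_features = 8,
                                             n_informative = 3,
                                             effect_size = 0, seed = 7))
  part <- split_dataset(gen$dataset, c(120L, 40L, 40L), seed = 7)
  acc <- evaluate_subset(gen$dataset, part, rep(1, 8))$accuracy
  expect_lt(abs(acc - 0.5), 0.25) # 3 binomial sds on 40 samples
})

test_that("empty masks are flagged as invalid individuals", {
  prob <- tiny_problem(n_samples = 60, n_features = 6, seed = 8)
  expect_error(evaluate_subset(prob$ds, prob$part, rep(0, 6)),
               class = "invalid_individual")
  fit <- wrapper_fitness(prob$ds, prob$part, run_config(pop_size = 4))
  expect_equal(fit(rep(0, 6)), 0)
})

test_that("wrapper fitness is memoized and within [0,1]", {
  prob <- tiny_problem(n_samples = 60, n_features = 6, seed = 9)
  fit <- wrapper_fitness(prob$ds, prob$part, run_config(pop_size = 4))
  v1 <- fit(c(1, 0, 1, 0, 0, 0))
  v2 <- fit(c(1, 0, 1, 0, 0, 0))
  expect_identical(v1, v2)
  expect_gte(v1, 0)
  expect_lte(v1, 1)
  expect_length(ls(attr(fit, "cache")), 1L)
})
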
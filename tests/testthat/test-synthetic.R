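test_that("intensity statistics match base R on arbitrary images", {
  img <- gray_image(matrix(7L, 5, 5))
  f <- intensity_features(img)
  expect_equal(unname(f), c(7, 7, 7, 7, 0, 0))

  two <- gray_image(matrix(c(0L, 255L), 2, 1))
  f2 <- intensity_features(two)
  expect_equal(f2[["Average Intensity"]], 127.5)
  expect_equal(f2[["Minimum Intensity"]], 0)
  expect_equal(f2[["Maximum Intensity"]], 255)

  set.seed(61)
  img3 <- gray_image(matrix(sample(0:255, 64 * 64, TRUE), 64, 64))
  f3 <- intensity_features(img3)
  v <- as.numeric(img3$pixels)
  expect_equal(unname(f3), c(min(v), max(v), median(v), mean(v), var(v),
                             sd(v)))
})

test_that("feature tables are balanced, planted and seed-deterministic", {
  spec <- synthetic_spec(n_samples = 100, n_features = 20, n_informative = 4,
                         effect_size = 2, n_redundant = 3, seed = 5)
  g1 <- make_feature_dataset(spec)
  g2 <- make_feature_dataset(spec)
  expect_identical(g1$dataset$features, g2$dataset$features)
  expect_equal(sum(g1$dataset$labels), 50)
  expect_equal(sum(g1$truth_mask), 4)
  # redundant copies correlate with their informative source
  expect_gt(cor(g1$dataset$features[, 1], g1$dataset$features[, 5]), 0.8)
  expect_error(synthetic_spec(n_features = 3, n_informative = 4),
               class = "synthetic_error")
})

test_that("planted effect sizes control achievable accuracy", {
  null <- make_feature_dataset(synthetic_spec(n_samples = 200,
                                              n_features = 6,
                                              effect_size = 0, seed = 6))
  part <- split_dataset(null$dataset, c(120L, 40L, 40L), seed = 6)
  acc0 <- evaluate_subset(null$dataset, part, rep(1, 6))$accuracy
  expect_lt(abs(acc0 - 0.5), 0.25)

  strong <- make_feature_dataset(synthetic_spec(n_samples = 200,
                                                n_features = 10,
                                                n_informative = 5,
                                                effect_size = 3, seed = 7))
  part2 <- split_dataset(strong$dataset, c(120L, 40L, 40L), seed = 7)
  acc1 <- evaluate_subset(strong$dataset, part2,
                          as.integer(strong$truth_mask))$accuracy
  expect_gt(acc1, 0.9)
})

test_that("vessel patches have the constructed width profile", {
  p0 <- make_vessel_patch(width = 6, curvature = 4, narrowing = 0,
                          noise_sd = 0, seed = 3)
  mask <- p0$image$pixels < 150
  dt <- EBImage::imageData(EBImage::distmap(mask))
  widths <- 2 * dt[p0$centerline] - 1
  mid_cols <- 28:36
  expect_lt(max(abs(widths - 6)), 2) # constant width along the tube

  p5 <- make_vessel_patch(width = 6, curvature = 4, narrowing = 0.5,
                          noise_sd = 0, seed = 3)
  mask5 <- p5$image$pixels < 150
  dt5 <- EBImage::imageData(EBImage::distmap(mask5))
  cl_idx <- which(p5$centerline, arr.ind = TRUE)
  mid <- cl_idx[cl_idx[, 2] %in% mid_cols, , drop = FALSE]
  end <- cl_idx[cl_idx[, 2] %in% c(2:6, 59:63), , drop = FALSE]
  w_mid <- median(2 * dt5[mid] - 1)
  w_end <- median(2 * dt5[end] - 1)
  expect_lt(w_mid, 0.75 * w_end) # mid-arc narrowing is visible

  p0b <- make_vessel_patch(width = 6, curvature = 4, narrowing = 0,
                           noise_sd = 0, seed = 3)
  expect_identical(p0$image$pixels, p0b$image$pixels)

  expect_error(make_vessel_patch(width = 6, curvature = 70, seed = 1),
               class = "synthetic_error")
})

test_that("patch banks are balanced and labeled", {
  bank <- make_patch_bank(608, positive_fraction = 0.5, seed = 2, size = 16)
  expect_equal(sum(bank$labels == 1L), 304)
  expect_equal(sum(bank$labels == 0L), 304)
  expect_length(bank$images, 608)

  small <- make_patch_bank(10, positive_fraction = 0.3, seed = 4, size = 16)
  expect_length(small$labels, 10)
  expect_equal(sum(small$labels), 3)
})

test_that("extraction is deterministic with the documented catalog size", {
  img <- make_vessel_patch(seed = 9, narrowing = 0.4)$image
  v1 <- extract_feature_vector(img)
  v2 <- extract_feature_vector(img)
  expect_identical(v1, v2)
  expect_equal(attr(v1, "catalog_size"), 228L)
  expect_false(anyNA(v1))
  expect_equal(anyDuplicated(names(v1)), 0L)
})

test_that("narrowed and uniform tubes differ in morphological features", {
  n_pairs <- 12
  feats <- c("Number Of Vessel Segments (Frangi)",
             "Minimum Vessel Length (Frangi)",
             "Median Elongatedness (Frangi)",
             "Gray Level Coefficient of Variation (Frangi)")
  pos <- matrix(NA_real_, n_pairs, length(feats))
  neg <- matrix(NA_real_, n_pairs, length(feats))
  for (i in seq_len(n_pairs)) {
    ppos <- make_vessel_patch(width = 6, curvature = 5, narrowing = 0.6,
                              noise_sd = 5, seed = 100 + i)$image
    pneg <- make_vessel_patch(width = 6, curvature = 5, narrowing = 0,
                              noise_sd = 5, seed = 100 + i)$image
    vpos <- suppressWarnings(extract_feature_vector(ppos))
    vneg <- suppressWarnings(extract_feature_vector(pneg))
    pos[i, ] <- vpos[feats]
    neg[i, ] <- vneg[feats]
  }
  tstats <- vapply(seq_along(feats), function(j) {
    d <- pos[, j] - neg[, j]
    if (sd(d) == 0) 0 else abs(mean(d)) / (sd(d) / sqrt(n_pairs))
  }, numeric(1))
  expect_gt(max(tstats), 2)
})
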
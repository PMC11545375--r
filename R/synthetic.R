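# Synthetic generators.  Two paths make every module testable without the
# external angiogram database: (a) Gaussian class-shift feature tables with
# a known informative subset (analytically tractable Bayes error), and (b)
# 64x64 vessel-like patches -- a dark quadratic-arc tube on a brighter
# noisy background, with an optional mid-arc narrowing emulating a
# stenosis.  All generators are pure functions of their seed.

#' Specification of a synthetic feature dataset
#'
#' @param n_samples number of samples (labels balanced).
#' @param n_features total number of features.
#' @param n_informative number of class-informative features.
#' @param effect_size standardized mean shift between classes (informative
#'   features are `Normal(+/- effect_size/2, 1)` by class).
#' @param n_redundant number of noisy copies of informative features.
#' @param noise_sd noise on redundant copies.
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 200L, n_features = 30L,
                           n_informative = 5L, effect_size = 2,
                           n_redundant = 0L, noise_sd = 0.3, seed = 1L) {
  if (n_informative + n_redundant > n_features || effect_size < 0) {
    stop_ssfs(
      "require n_informative + n_redundant <= n_features and effect_size >= 0",
      class = "synthetic_error")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 n_redundant = as.integer(n_redundant),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labeled feature dataset with planted informative features
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `dataset` (a [labeled_dataset()]) and `truth_mask`
#'   (logical vector marking the informative columns).
#' @export
make_feature_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples; p <- spec$n_features
    labels <- rep(c(0L, 1L), length.out = n)
    X <- matrix(stats::rnorm(n * p), n, p)
    shift <- spec$effect_size / 2
    info <- seq_len(spec$n_informative)
    for (jj in info) {
      X[, jj] <- X[, jj] + ifelse(labels == 1L, shift, -shift)
    }
    if (spec$n_redundant > 0L) {
      red <- spec$n_informative + seq_len(spec$n_redundant)
      src <- rep(info, length.out = spec$n_redundant)
      X[, red] <- X[, src, drop = FALSE] +
        matrix(stats::rnorm(n * spec$n_redundant, sd = spec$noise_sd),
               n, spec$n_redundant)
    }
    truth <- rep(FALSE, p)
    truth[info] <- TRUE
    ds <- labeled_dataset(X, labels, sprintf("F%03d", seq_len(p)))
    list(dataset = ds, truth_mask = truth)
  })
}

#' Generate a vessel-like image patch
#'
#' A dark tube follows a quadratic-arc centerline across the patch; a
#' positive `narrowing` reduces the tube width at mid-arc by that fraction
#' (a stenosis-like lesion).  The background is brighter with additive
#' Gaussian noise.
#'
#' @param size patch side in pixels (>= 16, default 64).
#' @param width base tube width in pixels (>= 1).
#' @param curvature quadratic coefficient of the centerline, in pixels of
#'   mid-arc deflection.
#' @param narrowing width-reduction fraction at mid-arc, in `[0, 1)`.
#' @param noise_sd Gaussian noise standard deviation (gray levels).
#' @param seed integer seed.
#' @param background,vessel background/vessel gray levels (0..255).
#' @return A list with `image` (a [gray_image()]) and `centerline`
#'   (logical matrix of the rasterized true centerline).
#' @export
make_vessel_patch <- function(size = 64L, width = 5, curvature = 6,
                              narrowing = 0, noise_sd = 8, seed = 1L,
                              background = 200, vessel = 80) {
  if (size < 16L || width < 1) {
    stop_ssfs("require size >= 16 and width >= 1", class = "synthetic_error")
  }
  if (narrowing < 0 || narrowing >= 1) {
    stop_ssfs("narrowing must lie in [0, 1)", class = "synthetic_error")
  }
  with_seed(seed, {
    # centerline: row r(c) = mid + curvature * (2c/size - 1)^2 - curvature/2
    cs <- seq_len(size)
    tt <- 2 * (cs - 0.5) / size - 1
    rows <- size / 2 + curvature * tt^2 - curvature / 2
    if (any(rows < 1 + width / 2) || any(rows > size - width / 2)) {
      stop_ssfs("tube exits the frame (curvature %g, width %g)",
                curvature, width, class = "synthetic_error")
    }
    # local half-width with a smooth mid-arc dip
    wloc <- width * (1 - narrowing * exp(-(tt / 0.25)^2 / 2))
    # distance of each pixel to the centerline polyline (dense sampling)
    dense <- seq(0.5, size + 0.5, by = 0.25)
    td <- 2 * dense / size - 1
    rd <- size / 2 + curvature * td^2 - curvature / 2
    wd <- width * (1 - narrowing * exp(-(td / 0.25)^2 / 2))
    px_r <- matrix(rep(seq_len(size), times = size), size)
    px_c <- matrix(rep(seq_len(size), each = size), size)
    inside <- matrix(FALSE, size, size)
    dmin <- matrix(Inf, size, size)
    for (k in seq_along(dense)) {
      d <- sqrt((px_r - rd[k])^2 + (px_c - dense[k])^2)
      hit <- d <= wd[k] / 2
      inside <- inside | hit
      dmin <- pmin(dmin, d)
    }
    img <- matrix(background, size, size)
    img[inside] <- vessel
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(size * size, sd = noise_sd),
                          size, size)
    }
    img <- round(pmin(pmax(img, 0), 255))
    centerline <- matrix(FALSE, size, size)
    cl_r <- round(rows)
    ok <- cl_r >= 1L & cl_r <= size
    centerline[cbind(cl_r[ok], cs[ok])] <- TRUE
    list(image = gray_image(img, 255L), centerline = centerline)
  })
}

#' Generate a balanced bank of vessel patches
#'
#' Positives carry a mid-arc narrowing drawn from `[0.3, 0.7]`; negatives
#' have uniform width.  Width, curvature and noise vary per patch.
#'
#' @param n number of patches (>= 2).
#' @param positive_fraction fraction of positive (stenosis) patches.
#' @param seed integer seed.
#' @param size patch side in pixels.
#' @param noise_sd Gaussian noise standard deviation.
#' @return A list with `images` (list of [gray_image()]) and `labels`
#'   (integer vector, 1 = stenosis).
#' @export
make_patch_bank <- function(n, positive_fraction = 0.5, seed = 1L,
                            size = 64L, noise_sd = 8) {
  if (n < 2L) stop_ssfs("n must be >= 2", class = "synthetic_error")
  n_pos <- round(n * positive_fraction)
  labels <- sample_labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  with_seed(seed, {
    order_idx <- sample.int(n)
    labels <- sample_labels[order_idx]
    seeds <- sample.int(2^30, n)
    # geometry scales with the frame so any patch size stays in-frame
    scale <- size / 64
    widths <- pmax(1, stats::runif(n, 5, 9) * scale)
    curv <- stats::runif(n, 2, 10) * scale
    narrow <- ifelse(labels == 1L, stats::runif(n, 0.3, 0.7), 0)
    imgs <- lapply(seq_len(n), function(i) {
      make_vessel_patch(size = size, width = widths[i],
                        curvature = curv[i], narrowing = narrow[i],
                        noise_sd = noise_sd, seed = seeds[i])$image
    })
    list(images = imgs, labels = labels)
  })
}
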
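# Vessel-enhancement filter bank.  Eight methods, each producing a
# real-valued ridge response on the inverted patch (X-ray vessels are darker
# than background; responses are defined on the inverted image scaled to
# 0..255 so the Hessian thresholds keep their conventional meaning):
#
#   frangi / salem            Hessian-eigenvalue vesselness, sigma 1..12
#                             step 0.5, alpha 0.5, beta 15
#   gabor_single              45 orientations, thickness 5 px, elongation 2.5
#   gabor_multi               3 scales with thickness spanning 2..20 px,
#                             45 orientations
#   linear_matched_multi      oriented zero-mean line kernels, lengths
#                             1..15 px, 12 orientations
#   gaussian_matched_single   Gaussian cross-section matched filter,
#                             length 13 px, sigma 2.82, orientations every 15
#                             degrees
#   gaussian_matched_multi    as above with sigma 1.5..2.5 step 0.5
#   tophat                    morphological top-hat, disk structuring
#                             element of size 19
#
# Multi-scale / multi-orientation methods take the per-pixel maximum over
# their kernel bank.  All kernels of a method are applied through one shared
# FFT of the padded image; kernel FFTs are precomputed per bank and cached.

#' Filter-bank parameter specification
#'
#' Defaults follow the standard parameterization for coronary angiograms
#' (see the package vignette for the semantics of each symbol).
#'
#' @param frangi,salem lists with `sigma` (vector of scales, px), `alpha`,
#'   `beta`.
#' @param gabor_single list with `K` (orientations over 180 degrees), `T`
#'   (target vessel thickness, px), `L` (kernel elongation).
#' @param gabor_multi list with `I` (number of scales), `T_range`
#'   (thickness range, px), `K`.
#' @param linear_matched_multi list with `L` (vector of line lengths, px)
#'   and `K`.
#' @param gaussian_matched_single list with `L` (kernel length, px),
#'   `T_deg` (angular step, degrees), `sigma`.
#' @param gaussian_matched_multi as above with a vector `sigma`.
#' @param tophat list with `shape` and `size` of the structuring element.
#' @return An object of class `filter_bank_spec`.
#' @export
filter_bank_spec <- function(
    frangi = list(sigma = seq(1, 12, by = 0.5), alpha = 0.5, beta = 15),
    salem = list(sigma = seq(1, 12, by = 0.5), alpha = 0.5, beta = 15),
    gabor_single = list(K = 45L, T = 5, L = 2.5),
    gabor_multi = list(I = 3L, T_range = c(2, 20), K = 45L),
    linear_matched_multi = list(L = 1:15, K = 12L),
    gaussian_matched_single = list(L = 13, T_deg = 15, sigma = 2.82),
    gaussian_matched_multi = list(L = 13, T_deg = 15, K = 12L,
                                  sigma = seq(1.5, 2.5, by = 0.5)),
    tophat = list(shape = "disc", size = 19L)) {
  spec <- list(frangi = frangi, salem = salem, gabor_single = gabor_single,
               gabor_multi = gabor_multi,
               linear_matched_multi = linear_matched_multi,
               gaussian_matched_single = gaussian_matched_single,
               gaussian_matched_multi = gaussian_matched_multi,
               tophat = tophat)
  if (!length(frangi$sigma) || !length(linear_matched_multi$L) ||
      tophat$size < 1) {
    stop_ssfs("filter bank ranges must be non-empty with positive sizes",
              class = "filter_error")
  }
  structure(spec, class = "filter_bank_spec")
}

#' Names of the eight enhancement methods
#' @return Character vector in catalog order.
#' @export
enhancement_methods <- function() {
  c("frangi", "salem", "gabor_single", "gabor_multi",
    "linear_matched_multi", "gaussian_matched_single",
    "gaussian_matched_multi", "tophat")
}

# maximum kernel half-width; 64x64 patches admit kernels up to 63x63
.KMAX <- 31L

# ---- convolution engine -------------------------------------------------

.pad_replicate <- function(mat, pad, P) {
  nr <- nrow(mat); nc <- ncol(mat)
  ri <- c(rep(1L, pad), seq_len(nr), rep(nr, P - pad - nr))
  ci <- c(rep(1L, pad), seq_len(nc), rep(nc, P - pad - nc))
  mat[ri, ci]
}

# FFT of a (2r+1)x(2r+1) kernel centered at the origin of a PxP grid
.kernel_fft <- function(kern, P) {
  r <- (nrow(kern) - 1L) %/% 2L
  big <- matrix(0, P, P)
  idx <- function(d) ((d - r - 1L) %% P) + 1L
  big[idx(seq_len(2L * r + 1L)), idx(seq_len(2L * r + 1L))] <- kern
  stats::fft(big)
}

# Correlate an image with a precomputed kernel-FFT bank; one forward FFT of
# the padded image, one inverse FFT per kernel.  reduce = "max" folds the
# bank into a single per-pixel maximum response.
.conv_bank <- function(img, kffts, pad, reduce = c("max", "list")) {
  reduce <- match.arg(reduce)
  nr <- nrow(img); nc <- ncol(img)
  P <- attr(kffts, "P")
  F <- stats::fft(.pad_replicate(img, pad, P))
  crop_r <- pad + seq_len(nr); crop_c <- pad + seq_len(nc)
  out <- NULL
  lst <- if (reduce == "list") vector("list", length(kffts))
  for (k in seq_along(kffts)) {
    # kernels are symmetric-or-handled-as-correlation: use Conj for correlation
    resp <- Re(stats::fft(F * Conj(kffts[[k]]), inverse = TRUE)) / (P * P)
    resp <- resp[crop_r, crop_c]
    if (reduce == "max") {
      out <- if (is.null(out)) resp else pmax(out, resp)
    } else {
      lst[[k]] <- resp
    }
  }
  if (reduce == "max") out else lst
}

.bank_cached <- function(key, builder, img_size) {
  key <- paste(key, img_size, sep = "@")
  hit <- .ssfs_cache[[key]]
  if (!is.null(hit)) return(hit)
  kerns <- builder()
  pad <- max(vapply(kerns, function(k) (nrow(k) - 1L) %/% 2L, integer(1)))
  P <- stats::nextn(img_size + 2L * pad, 2L)
  kffts <- lapply(kerns, .kernel_fft, P = P)
  attr(kffts, "P") <- P
  bank <- list(kffts = kffts, pad = pad)
  .ssfs_cache[[key]] <- bank
  bank
}

# ---- kernel builders ----------------------------------------------------

.gauss_hessian_kernels <- function(sigma) {
  r <- min(as.integer(ceiling(3 * sigma)), .KMAX)
  x <- matrix(rep(-r:r, each = 2L * r + 1L), 2L * r + 1L)
  y <- t(x)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  list(gxx = g * (x^2 - sigma^2) / sigma^4,
       gxy = g * x * y / sigma^4,
       gyy = g * (y^2 - sigma^2) / sigma^4)
}

.gabor_kernel <- function(thickness, elong, theta) {
  sx <- thickness / 2
  sy <- elong * sx
  lambda <- 2 * thickness
  r <- min(as.integer(ceiling(2.5 * max(sx, sy))), .KMAX)
  x <- matrix(rep(-r:r, each = 2L * r + 1L), 2L * r + 1L)
  y <- t(x)
  xr <- x * cos(theta) + y * sin(theta)   # across the vessel
  yr <- -x * sin(theta) + y * cos(theta)  # along the vessel
  k <- exp(-(xr^2 / (2 * sx^2) + yr^2 / (2 * sy^2))) *
    cos(2 * pi * xr / lambda)
  k - mean(k)
}

.line_kernel <- function(len, theta) {
  r <- max(1L, min(as.integer(ceiling(len / 2)), .KMAX))
  x <- matrix(rep(-r:r, each = 2L * r + 1L), 2L * r + 1L)
  y <- t(x)
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  k <- (abs(yr) <= len / 2 & abs(xr) <= 0.5) + 0
  if (sum(k) == 0) k[r + 1L, r + 1L] <- 1
  k / sum(k) - 1 / length(k)
}

.gmf_kernel <- function(len, sigma, theta) {
  r <- min(max(as.integer(ceiling(3 * sigma)), as.integer(ceiling(len / 2))),
           .KMAX)
  x <- matrix(rep(-r:r, each = 2L * r + 1L), 2L * r + 1L)
  y <- t(x)
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  k <- exp(-xr^2 / (2 * sigma^2)) * (abs(yr) <= len / 2)
  k - mean(k)
}

.spec_key <- function(method, params) {
  paste(method, paste(signif(unlist(params), 8), collapse = "_"), sep = "|")
}

.orientations <- function(K) (seq_len(K) - 1L) * pi / K

# ---- vesselness ---------------------------------------------------------

# Hessian-eigenvalue vesselness, gamma-normalized (sigma^2), max over scale.
# type "frangi": exp(-Rb^2/2a^2) * (1 - exp(-S^2/2b^2)) for ridge-like
# (lambda2 < 0) pixels; type "salem": scale-normalized eigenvalue magnitude
# difference |l2| - |l1|, a compatible stand-in for the Salem formulation.
.vesselness <- function(img, params, type) {
  out <- NULL
  sz <- max(dim(img))
  for (sigma in params$sigma) {
    key <- .spec_key("hessian", list(sigma = sigma))
    bank <- .bank_cached(key, function() .gauss_hessian_kernels(sigma), sz)
    h <- .conv_bank(img, bank$kffts, bank$pad, reduce = "list")
    s2 <- sigma^2
    hxx <- h[[1]] * s2; hxy <- h[[2]] * s2; hyy <- h[[3]] * s2
    tmp <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
    m <- (hxx + hyy) / 2
    e1 <- m + tmp; e2 <- m - tmp
    # order by magnitude: l1 small, l2 large
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    v <- if (type == "frangi") {
      rb2 <- (l1 / ifelse(l2 == 0, .Machine$double.eps, l2))^2
      s2n <- l1^2 + l2^2
      ifelse(l2 < 0,
             exp(-rb2 / (2 * params$alpha^2)) *
               (1 - exp(-s2n / (2 * params$beta^2))),
             0)
    } else {
      ifelse(l2 < 0, abs(l2) - abs(l1), 0)
    }
    out <- if (is.null(out)) v else pmax(out, v)
  }
  out
}

# ---- public entry -------------------------------------------------------

.as_work_image <- function(img) {
  if (inherits(img, "gray_image")) {
    (img$maxval - img$pixels) * (255 / img$maxval)
  } else {
    m <- as.matrix(img)
    (max(m) - m) * if (diff(range(m)) > 0) 255 / diff(range(m)) else 0
  }
}

#' Apply a vessel-enhancement method
#'
#' @param img a [gray_image()] (vessels darker than background) or a
#'   numeric matrix treated the same way.
#' @param method one of [enhancement_methods()].
#' @param spec a [filter_bank_spec()].
#' @return A numeric response matrix of the same shape; higher values mark
#'   vessel-like structure.  Deterministic.
#' @export
enhance <- function(img, method, spec = filter_bank_spec()) {
  stopifnot(inherits(spec, "filter_bank_spec"))
  if (!method %in% enhancement_methods()) {
    stop_ssfs("unknown enhancement method '%s'", method,
              class = "filter_error")
  }
  work <- .as_work_image(img)
  sz <- max(dim(work))
  switch(method,
    frangi = .vesselness(work, spec$frangi, "frangi"),
    salem = .vesselness(work, spec$salem, "salem"),
    gabor_single = {
      p <- spec$gabor_single
      bank <- .bank_cached(.spec_key(method, p), function() {
        lapply(.orientations(p$K), function(th)
          .gabor_kernel(p$T, p$L, th))
      }, sz)
      .conv_bank(work, bank$kffts, bank$pad)
    },
    gabor_multi = {
      p <- spec$gabor_multi
      thick <- seq(p$T_range[1], p$T_range[2], length.out = p$I)
      bank <- .bank_cached(.spec_key(method, p), function() {
        kerns <- list()
        for (tt in thick) {
          for (th in .orientations(p$K)) {
            kerns[[length(kerns) + 1L]] <-
              .gabor_kernel(tt, spec$gabor_single$L, th)
          }
        }
        kerns
      }, sz)
      .conv_bank(work, bank$kffts, bank$pad)
    },
    linear_matched_multi = {
      p <- spec$linear_matched_multi
      bank <- .bank_cached(.spec_key(method, p), function() {
        kerns <- list()
        for (len in p$L) {
          for (th in .orientations(p$K)) {
            kerns[[length(kerns) + 1L]] <- .line_kernel(len, th)
          }
        }
        kerns
      }, sz)
      .conv_bank(work, bank$kffts, bank$pad)
    },
    gaussian_matched_single = {
      p <- spec$gaussian_matched_single
      K <- as.integer(round(180 / p$T_deg))
      bank <- .bank_cached(.spec_key(method, p), function() {
        lapply(.orientations(K), function(th)
          .gmf_kernel(p$L, p$sigma, th))
      }, sz)
      .conv_bank(work, bank$kffts, bank$pad)
    },
    gaussian_matched_multi = {
      p <- spec$gaussian_matched_multi
      bank <- .bank_cached(.spec_key(method, p), function() {
        kerns <- list()
        for (s in p$sigma) {
          for (th in .orientations(p$K)) {
            kerns[[length(kerns) + 1L]] <- .gmf_kernel(p$L, s, th)
          }
        }
        kerns
      }, sz)
      .conv_bank(work, bank$kffts, bank$pad)
    },
    tophat = {
      p <- spec$tophat
      brush <- EBImage::makeBrush(
        if (p$size %% 2L == 0L) p$size + 1L else p$size,
        shape = if (p$shape == "disk") "disc" else p$shape)
      w <- work / 255
      as.matrix(w - EBImage::opening(w, brush)) * 255
    }
  )
}
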
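# Gray-level co-occurrence matrix and the 14 Haralick texture statistics.
# The GLCM is made symmetric, normalized, and averaged over the requested
# offsets before the statistics are computed.  Natural logarithms are used
# throughout, with the 0 * log(0) = 0 convention.

#' Gray-level co-occurrence matrix
#'
#' @param img a [gray_image()] (quantized over `[0, maxval]`) or a numeric
#'   matrix (quantized over its own range).
#' @param levels number of gray levels (>= 2).
#' @param offsets list of integer `c(dy, dx)` neighbor offsets; defaults to
#'   the four distance-1 directions.
#' @return A `levels x levels` symmetric matrix summing to 1 (average of
#'   the per-offset normalized matrices).
#' @export
glcm <- function(img, levels = 8L,
                 offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L),
                                c(1L, -1L))) {
  if (levels < 2L) {
    stop_ssfs("levels must be >= 2", class = "glcm_error")
  }
  if (inherits(img, "gray_image")) {
    lo <- 0; hi <- img$maxval
    m <- img$pixels
  } else {
    m <- as.matrix(img)
    lo <- min(m); hi <- max(m)
  }
  q <- if (hi > lo) {
    pmin(floor((m - lo) / (hi - lo) * levels) + 1L, levels)
  } else {
    matrix(1L, nrow(m), ncol(m))
  }
  acc <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (off in offsets) {
    dy <- off[1]; dx <- off[2]
    r1 <- max(1L, 1L - dy):min(nr, nr - dy)
    c1 <- max(1L, 1L - dx):min(nc, nc - dx)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dy, c1 + dx, drop = FALSE]
    tab <- matrix(0, levels, levels)
    cnt <- table(factor(a, levels = seq_len(levels)),
                 factor(b, levels = seq_len(levels)))
    tab[] <- as.numeric(cnt)
    tab <- tab + t(tab) # symmetric
    acc <- acc + tab / sum(tab)
  }
  acc / length(offsets)
}

.xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' The 14 Haralick texture features
#'
#' Angular second moment, contrast, correlation, sum of squares variance,
#' inverse difference moment, sum average, sum variance, sum entropy,
#' entropy, difference variance, difference entropy, the two information
#' measures of correlation, and the maximal correlation coefficient.
#'
#' @inheritParams glcm
#' @return A named numeric vector of length 14.  For a degenerate image
#'   (single occupied gray level) the entropy-type features are 0, ASM is
#'   1, contrast 0, and correlation is returned as 0 with a warning.
#' @export
glcm_haralick <- function(img, levels = 8L,
                          offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L),
                                         c(1L, -1L))) {
  p <- glcm(img, levels, offsets)
  N <- nrow(p)
  i <- matrix(rep(seq_len(N), each = N), N) # column index varies over rows
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(seq_len(N) * px)
  muy <- sum(seq_len(N) * py)
  sdx <- sqrt(sum((seq_len(N) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(N) - muy)^2 * py))
  # p_{x+y}(k), k = 2..2N and p_{x-y}(k), k = 0..N-1
  sums <- j + i
  diffs <- abs(j - i)
  pxy_sum <- vapply(2:(2L * N), function(k) sum(p[sums == k]), numeric(1))
  pxy_diff <- vapply(0:(N - 1L), function(k) sum(p[diffs == k]), numeric(1))
  ks <- 2:(2L * N)
  kd <- 0:(N - 1L)

  asm <- sum(p^2)
  contrast <- sum(kd^2 * pxy_diff)
  degenerate <- sdx == 0 || sdy == 0
  correlation <- if (degenerate) {
    warning("degenerate GLCM (single gray level): correlation set to 0")
    0
  } else {
    (sum(j * i * p) - mux * muy) / (sdx * sdy)
  }
  variance <- sum((j - mux)^2 * p) # sum-of-squares variance about mu_x
  idm <- sum(p / (1 + (j - i)^2))
  sum_avg <- sum(ks * pxy_sum)
  sum_var <- sum((ks - sum_avg)^2 * pxy_sum)
  sum_entropy <- -sum(.xlogx(pxy_sum))
  entropy <- -sum(.xlogx(p))
  diff_avg <- sum(kd * pxy_diff)
  diff_var <- sum((kd - diff_avg)^2 * pxy_diff)
  diff_entropy <- -sum(.xlogx(pxy_diff))
  # information measures of correlation
  hxy <- entropy
  hx <- -sum(.xlogx(px))
  hy <- -sum(.xlogx(py))
  pq <- outer(px, py)
  hxy1 <- -sum(ifelse(p > 0 & pq > 0, p * log(pq), 0))
  hxy2 <- -sum(.xlogx(pq))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  # maximal correlation coefficient: sqrt of the second-largest eigenvalue
  # of Q_ij = sum_k p_ik p_jk / (px_i py_k)
  nz <- px > 0
  mcc <- if (sum(nz) < 2L) 0 else {
    pk <- p[nz, nz, drop = FALSE]
    pxk <- px[nz]; pyk <- py[nz]
    Q <- matrix(0, sum(nz), sum(nz))
    for (kk in seq_len(sum(nz))) {
      Q <- Q + outer(pk[, kk] / pxk, pk[, kk] / pyk[kk])
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  c(
    "Angular Second Moment" = asm, "Contrast" = contrast,
    "Correlation" = correlation, "Sum of Squares Variance" = variance,
    "Inverse Difference Moment" = idm, "Sum Average" = sum_avg,
    "Sum Variance" = sum_var, "Sum Entropy" = sum_entropy,
    "Entropy" = entropy, "Difference Variance" = diff_var,
    "Difference Entropy" = diff_entropy,
    "Information Measure of Correlation 1" = imc1,
    "Information Measure of Correlation 2" = imc2,
    "Maximal Correlation Coefficient" = mcc
  )
}
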
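# Segmentation and skeleton-based morphology of enhanced vessel responses.
# An "arterial section" is a connected component of the segmented mask;
# "segments" are the skeleton branches between branch/end points.
# Degenerate inputs (empty mask, zero-perimeter components) yield sentinel
# value -1 with a warning -- every regular feature here is >= 0, so the
# sentinel is unambiguous and never a silent zero.

.SENTINEL <- -1

#' Segment a filter response into vessel / non-vessel pixels
#'
#' Otsu's threshold on the min-max-normalized response.
#'
#' @param response numeric response matrix.
#' @return A logical mask of the same shape (`TRUE` = vessel).  A constant
#'   response yields an all-`FALSE` mask with a warning.
#' @export
segment_vessels <- function(response) {
  response <- as.matrix(response)
  if (any(!is.finite(response))) {
    stop_ssfs("response contains non-finite values", class = "segment_error")
  }
  rng <- range(response)
  if (diff(rng) == 0) {
    warning("constant response: empty vessel mask")
    return(matrix(FALSE, nrow(response), ncol(response)))
  }
  norm <- (response - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  norm > thr
}

# ---- skeletonization (Zhang-Suen thinning) ------------------------------

.shift <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  sr <- max(1L, 1L + dy):min(nr, nr + dy)
  sc <- max(1L, 1L + dx):min(nc, nc + dx)
  out[sr, sc] <- m[sr - dy, sc - dx]
  out
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen morphological thinning to a one-pixel-wide, 8-connected
#' skeleton.
#'
#' @param mask logical matrix.
#' @return A logical skeleton matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  # neighbors clockwise from north: P2..P9
  offs <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
               c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nb <- lapply(offs, function(o) .shift(img, o[1], o[2]))
      B <- Reduce(`+`, nb)
      ring <- c(nb, nb[1])
      A <- Reduce(`+`, lapply(seq_len(8), function(k)
        (ring[[k]] == 0L) & (ring[[k + 1L]] == 1L)))
      if (phase == 1) {
        c3 <- nb[[1]] * nb[[3]] * nb[[5]] == 0L # P2*P4*P6
        c4 <- nb[[3]] * nb[[5]] * nb[[7]] == 0L # P4*P6*P8
      } else {
        c3 <- nb[[1]] * nb[[3]] * nb[[7]] == 0L # P2*P4*P8
        c4 <- nb[[1]] * nb[[5]] * nb[[7]] == 0L # P2*P6*P8
      }
      del <- img == 1L & B >= 2L & B <= 6L & A == 1L & c3 & c4
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1L
}

# ---- skeleton branch decomposition --------------------------------------

#' Decompose a skeleton into branches
#'
#' Branches are maximal 8-connected paths between nodes (end points, degree
#' <= 1, and junctions, degree >= 3); isolated cycles become one branch.
#'
#' @param skel logical skeleton matrix.
#' @param labels optional integer component-label matrix (e.g. from the
#'   segmented mask) used to assign each branch a parent arterial section.
#' @return A data.frame with one row per branch: `section` (component id),
#'   `length` (pixel count, >= 1), and the path stored in attribute
#'   `"paths"` (list of index matrices).
#' @export
skeleton_segments <- function(skel, labels = NULL) {
  pts <- which(skel, arr.ind = TRUE)
  empty <- data.frame(section = integer(0), length = integer(0))
  attr(empty, "paths") <- list()
  if (nrow(pts) == 0L) return(empty)
  nr <- nrow(skel)
  key <- function(r, c) (c - 1L) * nr + r
  pix <- key(pts[, 1], pts[, 2])
  inskel <- logical(nr * ncol(skel))
  inskel[pix] <- TRUE
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L), c(0L, 1L),
                c(1L, -1L), c(1L, 0L), c(1L, 1L))
  nbrs_of <- function(r, c) {
    rr <- r + offs[, 1]; cc <- c + offs[, 2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(skel)
    rr <- rr[ok]; cc <- cc[ok]
    keep <- inskel[key(rr, cc)]
    cbind(rr[keep], cc[keep])
  }
  deg <- integer(length(pix))
  nb_cache <- vector("list", length(pix))
  idx_of <- integer(nr * ncol(skel))
  idx_of[pix] <- seq_along(pix)
  for (u in seq_along(pix)) {
    nb <- nbrs_of(pts[u, 1], pts[u, 2])
    nb_cache[[u]] <- nb
    deg[u] <- nrow(nb)
  }
  is_node <- deg != 2L
  used_edge <- new.env(parent = emptyenv())
  edge_key <- function(a, b) paste(min(a, b), max(a, b))
  paths <- list()
  walk <- function(u, v) {
    # walk from node u through v until the next node, a dead end, or --
    # for pure cycles -- back to the start
    path <- c(u, v)
    assign(edge_key(u, v), TRUE, envir = used_edge)
    prev <- u; cur <- v
    while (!is_node[cur]) {
      nb <- nb_cache[[cur]]
      nxt <- idx_of[key(nb[, 1], nb[, 2])]
      nxt <- nxt[nxt != prev]
      if (!length(nxt)) break
      nxt <- nxt[1]
      assign(edge_key(cur, nxt), TRUE, envir = used_edge)
      if (nxt == u) break # closed a cycle; u is already in the path
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    path
  }
  for (u in which(is_node)) {
    nb <- nb_cache[[u]]
    if (nrow(nb) == 0L) {
      paths[[length(paths) + 1L]] <- u # isolated pixel
      next
    }
    for (vi in seq_len(nrow(nb))) {
      v <- idx_of[key(nb[vi, 1], nb[vi, 2])]
      if (!is.null(used_edge[[edge_key(u, v)]])) next
      paths[[length(paths) + 1L]] <- walk(u, v)
    }
  }
  # pure cycles: remaining degree-2 pixels with no incident used edge
  visited <- logical(length(pix))
  for (p in paths) visited[p] <- TRUE
  for (u in which(!visited & deg == 2L)) {
    if (visited[u]) next
    nb <- nb_cache[[u]]
    v <- idx_of[key(nb[1, 1], nb[1, 2])]
    path <- walk(u, v)
    visited[path] <- TRUE
    paths[[length(paths) + 1L]] <- path
  }
  section <- vapply(paths, function(p) {
    if (is.null(labels)) 1L else as.integer(labels[pts[p[1], 1], pts[p[1], 2]])
  }, integer(1))
  out <- data.frame(section = section,
                    length = vapply(paths, length, integer(1)))
  attr(out, "paths") <- lapply(paths, function(p) pts[p, , drop = FALSE])
  out
}

# ---- geometry -----------------------------------------------------------

# Minimum-area rotated rectangle of a pixel set (rotating calipers over the
# convex hull of the pixel corners); returns c(length, width).
.min_area_rect <- function(pts) {
  # pts: n x 2 pixel centers; expand to corners so a 10x2 block measures 10x2
  x <- c(pts[, 1] - 0.5, pts[, 1] - 0.5, pts[, 1] + 0.5, pts[, 1] + 0.5)
  y <- c(pts[, 2] - 0.5, pts[, 2] + 0.5, pts[, 2] - 0.5, pts[, 2] + 0.5)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  m <- length(h)
  best <- c(Inf, Inf, Inf) # area, length, width
  for (e in seq_len(m)) {
    e2 <- if (e == m) 1L else e + 1L
    dx <- hx[e2] - hx[e]; dy <- hy[e2] - hy[e]
    len <- sqrt(dx^2 + dy^2)
    if (len == 0) next
    ux <- dx / len; uy <- dy / len
    proj <- hx * ux + hy * uy
    perp <- -hx * uy + hy * ux
    d1 <- diff(range(proj)); d2 <- diff(range(perp))
    if (d1 * d2 < best[1]) best <- c(d1 * d2, max(d1, d2), min(d1, d2))
  }
  best[2:3]
}

# Perimeter from an ordered boundary chain: unit steps count 1, diagonal
# steps sqrt(2).  Components too small to trace get the unit-square value 4.
.chain_perimeter <- function(contour) {
  if (is.null(contour) || nrow(contour) < 2L) return(4)
  d <- abs(diff(rbind(contour, contour[1, , drop = FALSE])))
  sum(ifelse(d[, 1] > 0 & d[, 2] > 0, sqrt(2), 1) *
        (d[, 1] > 0 | d[, 2] > 0))
}

# Sobel gradient magnitude.
.gradient_magnitude <- function(img) {
  img <- as.matrix(img)
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  gx <- as.matrix(EBImage::filter2(img, sx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(img, t(sx), boundary = "replicate"))
  sqrt(gx^2 + gy^2)
}

# ---- morphological feature vector ---------------------------------------

#' Morphological features of a segmented vessel mask
#'
#' Per connected component (arterial section): perimeter `P` (boundary
#' chain with diagonal steps counted sqrt(2)), area `A`, compactness
#' `P^2/A`, circularity ratio `4*pi*A/P^2` (computed as `4*pi /
#' compactness`, so the product of the two is exactly `4*pi`), and
#' elongatedness = length/width of the minimum-area rotated bounding
#' rectangle.  The skeleton of the mask supplies per-section vessel lengths
#' and branch segments; gray-level and gradient coefficients of variation
#' are taken over vessel pixels of the response.
#'
#' @param mask logical vessel mask.
#' @param response numeric response (or intensity) image for the gray-level
#'   statistics.
#' @param gradient optional gradient-magnitude image; Sobel magnitude of
#'   `response` by default.
#' @return A named numeric vector of 20 features.  With an empty mask every
#'   feature is the sentinel `-1` and a warning is raised.
#' @export
morphology_features <- function(mask, response, gradient = NULL) {
  mask <- as.matrix(mask)
  nm <- c(
    "Number Of Vessel Segments",
    "Minimum Vessel Length", "Maximum Vessel Length", "Mean Vessel Length",
    "Median Vessel Length", "Standard Deviation of Vessel Length",
    "Minimum Compactness", "Maximum Compactness", "Median Compactness",
    "Minimum Circularity Ratio", "Maximum Circularity Ratio",
    "Median Circularity Ratio",
    "Minimum Elongatedness", "Maximum Elongatedness", "Median Elongatedness",
    "Gray Level Coefficient of Variation",
    "Gradient Coefficient of Variation",
    "Median Standard Deviation of Segments Length in all Arterial Sections",
    "Maximum Standard Deviation of Segments Length in all Arterial Sections",
    paste("Standard Deviation of the Standard Deviations of Segments",
          "Length in all Arterial Sections")
  )
  if (!any(mask)) {
    warning("empty vessel mask: morphological features set to sentinel -1")
    return(stats::setNames(rep(.SENTINEL, length(nm)), nm))
  }
  limg <- EBImage::bwlabel(mask)
  labels <- EBImage::imageData(limg)
  nlab <- max(labels)
  contours <- EBImage::ocontour(limg)
  comp <- vapply(seq_len(nlab), function(l) {
    pts <- which(labels == l, arr.ind = TRUE)
    area <- nrow(pts)
    per <- .chain_perimeter(contours[[l]])
    cmp <- per^2 / area
    lw <- .min_area_rect(pts)
    elong <- if (lw[2] > 0) lw[1] / lw[2] else lw[1] / 0.5
    c(compactness = cmp, circularity = 4 * pi / cmp, elong = elong)
  }, numeric(3))

  skel <- skeletonize(mask)
  segs <- skeleton_segments(skel, labels)
  # vessel length per arterial section = its skeleton pixel count
  skl <- labels[skel]
  skl <- skl[skl > 0]
  sec_len <- as.numeric(table(factor(skl, levels = seq_len(nlab))))
  sec_len <- sec_len[sec_len > 0]
  if (!length(sec_len)) sec_len <- 0
  # per-section standard deviation of its segment lengths
  sec_sd <- if (nrow(segs)) {
    vapply(split(segs$length, segs$section), function(v)
      if (length(v) > 1L) stats::sd(v) else 0, numeric(1))
  } else 0
  # gray levels over vessel pixels, shifted to a non-negative scale so the
  # coefficient of variation is well defined for zero-mean filter responses
  resp_m <- as.matrix(response)
  resp_v <- resp_m[mask] - min(resp_m)
  grad <- gradient %||% .gradient_magnitude(response)
  grad_v <- as.matrix(grad)[mask]
  cov_of <- function(v) {
    m <- mean(v)
    if (m == 0 || length(v) < 2L) .SENTINEL else stats::sd(v) / m
  }
  vlen_sd <- if (length(sec_len) > 1L) stats::sd(sec_len) else 0
  sd_of_sd <- if (length(sec_sd) > 1L) stats::sd(sec_sd) else 0
  stats::setNames(c(
    nrow(segs),
    min(sec_len), max(sec_len), mean(sec_len), stats::median(sec_len),
    vlen_sd,
    min(comp["compactness", ]), max(comp["compactness", ]),
    stats::median(comp["compactness", ]),
    min(comp["circularity", ]), max(comp["circularity", ]),
    stats::median(comp["circularity", ]),
    min(comp["elong", ]), max(comp["elong", ]),
    stats::median(comp["elong", ]),
    cov_of(resp_v), cov_of(grad_v),
    stats::median(sec_sd), max(sec_sd), sd_of_sd
  ), nm)
}
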
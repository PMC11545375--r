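# The per-patch feature catalog: 6 raw-image intensity statistics, 14
# Haralick texture features, and for each of the 8 enhancement methods the
# 6 intensity statistics of its response plus 20 morphological features of
# its segmentation -- 228 features in all for the default bank.

.INTENSITY_NAMES <- c(
  "Minimum Intensity", "Maximum Intensity", "Median Intensity",
  "Average Intensity", "Intensity Variance",
  "Standard Deviation of the Intensities")

.METHOD_LABELS <- c(
  frangi = "Frangi", salem = "Salem",
  gabor_single = "Single-Scale Gabor Filter",
  gabor_multi = "Multi-Scale Gabor Filter",
  linear_matched_multi = "Multi-Scale Linear Matched-Filter",
  gaussian_matched_single = "Single-Scale Gaussian Matched-Filter",
  gaussian_matched_multi = "Multi-Scale Gaussian Matched-Filter",
  tophat = "Top-Hat Operator")

#' Intensity statistics of an image or response
#'
#' Minimum, maximum, median, average, variance and standard deviation of
#' the pixel values.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @return A named numeric vector of length 6.
#' @export
intensity_features <- function(img) {
  v <- if (inherits(img, "gray_image")) as.numeric(img$pixels) else
    as.numeric(as.matrix(img))
  va <- if (length(v) > 1L) stats::var(v) else 0
  stats::setNames(
    c(min(v), max(v), stats::median(v), mean(v), va, sqrt(va)),
    .INTENSITY_NAMES)
}

#' Extract the full feature vector of one patch
#'
#' Concatenates the raw-image intensity statistics, the 14 Haralick texture
#' features, and, per enhancement method, the intensity statistics of the
#' filter response and the morphological features of its segmentation.
#' Naming and ordering are stable for a given [filter_bank_spec()];
#' method-specific features carry the method label as a suffix, e.g.
#' `"Mean Vessel Length (Frangi)"`.
#'
#' @param img a [gray_image()].
#' @param spec a [filter_bank_spec()].
#' @param glcm_levels gray levels for the co-occurrence matrix (default 8).
#' @return A named numeric vector; `attr(x, "catalog_size")` reports its
#'   length (228 for the default bank).
#' @export
extract_feature_vector <- function(img, spec = filter_bank_spec(),
                                   glcm_levels = 8L) {
  stopifnot(inherits(img, "gray_image"))
  out <- c(intensity_features(img), glcm_haralick(img, glcm_levels))
  for (m in enhancement_methods()) {
    resp <- enhance(img, m, spec)
    seg <- segment_vessels(resp)
    vals <- c(intensity_features(resp), morphology_features(seg, resp))
    names(vals) <- paste0(names(vals), " (", .METHOD_LABELS[[m]], ")")
    out <- c(out, vals)
  }
  attr(out, "catalog_size") <- length(out)
  out
}

#' Extract a feature table from a bank of patches
#'
#' @param imgs list of [gray_image()] patches.
#' @param labels optional binary labels (1 = positive stenosis); when given
#'   the result is a [labeled_dataset()], otherwise a plain matrix.
#' @param spec a [filter_bank_spec()].
#' @param glcm_levels gray levels for the co-occurrence matrix.
#' @return A [labeled_dataset()] or numeric matrix, one row per patch.
#' @export
extract_feature_table <- function(imgs, labels = NULL,
                                  spec = filter_bank_spec(),
                                  glcm_levels = 8L) {
  rows <- lapply(imgs, function(im)
    suppressWarnings(extract_feature_vector(im, spec, glcm_levels)))
  mat <- do.call(rbind, rows)
  if (is.null(labels)) return(mat)
  labeled_dataset(mat, labels, colnames(mat))
}
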
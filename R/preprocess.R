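# CT patch preprocessing: Hounsfield-unit windowing, fixed-size ROI cropping,
# and radiologist score averaging.

#' Map Hounsfield units to display gray levels with a lung window
#'
#' Values at or below `lo` map to 0, values at or above `hi` map to 1, and
#' the response is linear in between. The default \[-1400, 200\] HU window is
#' the standard lung window used when nodule patches are converted to
#' grayscale.
#'
#' @param hu_image Numeric vector, matrix or array of Hounsfield units.
#' @param lo,hi Window bounds in HU, `lo < hi`.
#' @return Object of the same shape with values in \[0, 1\].
#' @export
#' @examples
#' window_hu(c(-1400, -600, 200))  # 0, 0.5, 1
window_hu <- function(hu_image, lo = -1400, hi = 200) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi) {
    abort("window bounds must satisfy lo < hi", class = "milcascade_config_error")
  }
  clip((hu_image - lo) / (hi - lo), 0, 1)
}

#' Crop a fixed-size region of interest around a nodule center
#'
#' Uses 0-based coordinates with a half-open window: the crop covers source
#' indices `[c - size/2, c + size/2)` in each dimension, so the center pixel
#' lands at output index `size/2`. Regions falling outside the image are
#' filled with 0, the windowed equivalent of air at the bottom of the lung
#' window.
#'
#' @param slice_image 2-D numeric matrix (a windowed CT slice).
#' @param center `c(row, col)` of the nodule center, 0-based.
#' @param size Output side length in pixels; even, at least 2.
#' @return `size` x `size` numeric matrix.
#' @export
#' @examples
#' img <- matrix(1, 64, 64)
#' identical(crop_roi(img, c(32, 32), 64), img)
crop_roi <- function(slice_image, center, size = 64L) {
  size <- as.integer(size)
  if (size < 2L || size %% 2L != 0L) {
    abort("`size` must be an even integer >= 2", class = "milcascade_config_error")
  }
  if (length(center) != 2L || any(center < 0) ||
      center[1] >= nrow(slice_image) || center[2] >= ncol(slice_image)) {
    abort("`center` must lie inside the image (0-based coordinates)",
          class = "milcascade_domain_error")
  }
  out <- matrix(0, size, size)
  rs <- floor(center[1]) - size %/% 2L + 0:(size - 1L)   # 0-based source rows
  cs <- floor(center[2]) - size %/% 2L + 0:(size - 1L)
  rok <- rs >= 0L & rs < nrow(slice_image)
  cok <- cs >= 0L & cs < ncol(slice_image)
  out[rok, cok] <- slice_image[rs[rok] + 1L, cs[cok] + 1L]
  out
}

#' Average per-radiologist attribute ratings into ground-truth scores
#'
#' When a nodule is rated by several radiologists, the per-attribute
#' arithmetic mean of their scores is used as the ground truth for training
#' and evaluation, without rounding.
#'
#' @param ratings Named list, one element per attribute, each a numeric
#'   vector of individual radiologist scores (at least one per attribute).
#' @return Named numeric vector of mean scores.
#' @export
#' @examples
#' average_scores(list(mal = c(4, 4, 4, 5)))  # mal = 4.25
average_scores <- function(ratings) {
  if (!is.list(ratings) || is.null(names(ratings)) || any(names(ratings) == "")) {
    abort("`ratings` must be a named list of score vectors", class = "milcascade_domain_error")
  }
  out <- vapply(names(ratings), function(a) {
    r <- ratings[[a]]
    if (length(r) < 1L || !is.numeric(r)) {
      abort(paste0("attribute '", a, "' has no ratings"), class = "milcascade_domain_error")
    }
    mean(r)
  }, numeric(1))
  out
}
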
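#' Fallback lung-field segmentation
#'
#' A non-learned stand-in for an externally supplied lung mask: the image is
#' histogram-equalized, thresholded with Otsu's method, opened with a disc
#' structuring element (radius = side/32), and the two largest connected
#' components are kept. It is intended for phantom-style material where the
#' lung fields are the two dominant bright regions; externally provided masks
#' always take precedence in the pipeline.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @return A 0/1 integer matrix of the same shape.
#' @export
segment_lungs_fallback <- function(image) {
  assert_image(image)
  if (max(image) == min(image)) {
    stop("segmentation produced an empty mask: image has no contrast",
         call. = FALSE)
  }
  eq <- equalize_histogram(image)
  th <- EBImage::otsu(EBImage::Image(eq), range = c(0, 1))
  bw <- matrix(as.numeric(eq > th), nrow(image), ncol(image))
  if (sum(bw) == 0) {
    stop("segmentation produced an empty mask: no pixels above threshold",
         call. = FALSE)
  }
  radius <- max(1L, round(min(dim(image)) / 32))
  kern <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  opened <- EBImage::opening(bw, kern)
  lab <- EBImage::bwlabel(opened)
  sizes <- tabulate(as.integer(lab[lab > 0]))
  if (length(sizes) == 0) {
    stop("segmentation produced an empty mask after opening", call. = FALSE)
  }
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(2L, length(sizes)))]
  matrix(as.integer(matrix(lab, nrow(image)) %in% keep),
         nrow(image), ncol(image))
}

#' Crop an image to the bounding box of a mask
#'
#' Returns the tight axis-aligned bounding box of the mask foreground, with
#' 0-based half-open bounds `[rmin, rmax + 1)` on both axes (equivalently,
#' inclusive index ranges in R's 1-based terms).
#'
#' @param image Numeric matrix.
#' @param mask 0/1 matrix of identical shape with at least one foreground
#'   pixel.
#' @return The cropped sub-image.
#' @export
crop_to_mask_bbox <- function(image, mask) {
  if (!all(dim(image) == dim(mask))) {
    stop("`image` and `mask` must have identical shapes", call. = FALSE)
  }
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("`mask` is empty; nothing to crop to", call. = FALSE)
  image[min(fg[, 1]):max(fg[, 1]), min(fg[, 2]):max(fg[, 2]), drop = FALSE]
}

#' Intersection-over-union and Dice overlap of two binary masks
#'
#' `iou = |A n B| / |A u B|`, `dice = 2 |A n B| / (|A| + |B|)`; two empty
#' masks are defined to agree perfectly, giving `(1, 1)`. The two measures
#' are linked by `dice = 2 iou / (1 + iou)`.
#'
#' @param mask_a,mask_b 0/1 matrices of identical shape.
#' @return A list with elements `iou` and `dice`.
#' @export
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(1, 0, 1, 0), 2)
#' iou_dice(a, b)
iou_dice <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) {
    stop("masks must have identical shapes", call. = FALSE)
  }
  a <- mask_a != 0; b <- mask_b != 0
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) return(list(iou = 1, dice = 1))
  inter <- sum(a & b)
  list(iou = inter / (na + nb - inter), dice = 2 * inter / (na + nb))
}
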
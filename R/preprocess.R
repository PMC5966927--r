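#' Histogram equalization
#'
#' Classical 256-bin cumulative-histogram equalization: each intensity is
#' mapped to the empirical CDF value of its bin. The mapping is monotone in
#' the input, so pixel rank order is preserved, and it is idempotent up to one
#' bin width. 256 bins are used regardless of the source bit depth so that 8-
#' and 12-bit material share one deterministic dialect.
#'
#' @param image Numeric matrix with intensities in `[0, 1]`.
#' @return Equalized matrix in `[0, 1]`.
#' @export
#' @examples
#' x <- matrix(c(0.2, 0.2, 0.8, 0.8, 0.8, 0.8, 0.8, 0.2), 2)
#' unique(as.vector(equalize_histogram(x)))
equalize_histogram <- function(image) {
  assert_image(image)
  bins <- pmin(floor(image * 256) + 1L, 256L)
  counts <- tabulate(bins, nbins = 256L)
  cdf <- cumsum(counts) / length(image)
  matrix(cdf[bins], nrow(image), ncol(image))
}

# Bilinear sampling at fractional (row, col) positions with centered
# coordinates; positions outside the source grid read as `fill`.
bilinear_sample <- function(image, r, c, fill = 0) {
  h <- nrow(image); w <- ncol(image)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  px <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- rep(fill, length(ri))
    v[ok] <- image[cbind(ri[ok], ci[ok])]
    v
  }
  v00 <- px(r0, c0); v10 <- px(r0 + 1, c0)
  v01 <- px(r0, c0 + 1); v11 <- px(r0 + 1, c0 + 1)
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' Resize an image by bilinear interpolation
#'
#' Uses a centered sampling grid (`src = (dst + 0.5) * scale - 0.5`, clamped
#' to the source extent), so down-scaling by an integer factor averages the
#' corresponding source block — resizing a 4x4 checkerboard to 2x2 yields the
#' block means. The intensity range stays within `[0, 1]` because bilinear
#' weights are a convex combination.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param target_side Output side length (square output).
#' @return `target_side` x `target_side` matrix.
#' @export
resize_image <- function(image, target_side) {
  assert_image(image)
  if (!is.numeric(target_side) || target_side < 1) {
    stop("`target_side` must be a positive side length", call. = FALSE)
  }
  target_side <- as.integer(target_side)
  h <- nrow(image); w <- ncol(image)
  sr <- pmin(pmax((seq_len(target_side) - 0.5) * h / target_side + 0.5, 1), h)
  sc <- pmin(pmax((seq_len(target_side) - 0.5) * w / target_side + 0.5, 1), w)
  rr <- matrix(sr, target_side, target_side)
  cc <- matrix(sc, target_side, target_side, byrow = TRUE)
  matrix(bilinear_sample(image, as.vector(rr), as.vector(cc)),
         target_side, target_side)
}

#' Randomly partition case ids into training and test sets
#'
#' Shuffles uniformly under `seed` and takes `round(train_fraction * N)`
#' cases (round half up) for training — splitting 2480 cases at 0.7 gives
#' exactly 1736 training and 744 test cases.
#'
#' @param case_ids Character vector of unique case identifiers.
#' @param train_fraction Fraction in (0, 1); default 0.7.
#' @param seed Integer seed.
#' @return A tibble with columns `case_id` and `partition`
#'   (`"train"`/`"test"`).
#' @export
#' @examples
#' split_dataset(sprintf("c%02d", 1:10), seed = 1) |> dplyr::count(partition)
split_dataset <- function(case_ids, train_fraction = 0.7, seed = 1) {
  if (length(case_ids) < 2L) stop("need at least 2 cases to split", call. = FALSE)
  if (anyDuplicated(case_ids)) stop("`case_ids` must be unique", call. = FALSE)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly inside (0, 1)", call. = FALSE)
  }
  n <- length(case_ids)
  n_train <- as.integer(floor(train_fraction * n + 0.5))
  with_seed(seed, {
    shuffled <- sample(case_ids)
    tibble::tibble(
      case_id = case_ids,
      partition = ifelse(case_ids %in% shuffled[seq_len(n_train)],
                         "train", "test")
    )
  })
}

#' Augmentation settings
#'
#' @param rotation_range_deg Rotation range in degrees, drawn uniformly
#'   (default `c(0, 10)`).
#' @param width_shift_frac,height_shift_frac Maximum shift as a fraction of
#'   the side length; shifts are drawn uniformly in the signed range and
#'   rounded to whole pixels.
#' @param seed Integer seed.
#' @return An `augment_spec` list.
#' @export
augment_spec <- function(rotation_range_deg = c(0, 10),
                         width_shift_frac = 0.2, height_shift_frac = 0.2,
                         seed = 1) {
  structure(list(rotation_range_deg = rotation_range_deg,
                 width_shift_frac = width_shift_frac,
                 height_shift_frac = height_shift_frac,
                 seed = as.integer(seed)),
            class = "augment_spec")
}

#' Randomly rotate and shift a training image
#'
#' Applies a rotation about the image centre (angle uniform in the configured
#' range, bilinear resampling) followed by an integer-pixel shift (uniform in
#' the signed fraction of the side length). Pixels mapped from outside the
#' frame are filled with 0 and the output shape equals the input shape.
#'
#' @param image Square numeric matrix in `[0, 1]`.
#' @param spec An [augment_spec()].
#' @param seed Seed for this draw; defaults to `spec$seed`.
#' @return Augmented matrix, same shape.
#' @export
augment_image <- function(image, spec = augment_spec(), seed = spec$seed) {
  assert_image(image)
  if (nrow(image) != ncol(image)) stop("`image` must be square", call. = FALSE)
  s <- nrow(image)
  with_seed(seed, {
    theta <- runif(1, spec$rotation_range_deg[1], spec$rotation_range_deg[2]) *
      pi / 180
    dx <- round(runif(1, -spec$width_shift_frac, spec$width_shift_frac) * s)
    dy <- round(runif(1, -spec$height_shift_frac, spec$height_shift_frac) * s)
    out <- image
    if (theta != 0) {
      ctr <- (s + 1) / 2
      rows <- matrix(seq_len(s), s, s) - ctr
      cols <- matrix(seq_len(s), s, s, byrow = TRUE) - ctr
      # inverse mapping: sample the source at the back-rotated position
      sr <- cos(theta) * rows + sin(theta) * cols + ctr
      sc <- -sin(theta) * rows + cos(theta) * cols + ctr
      out <- matrix(bilinear_sample(image, as.vector(sr), as.vector(sc)),
                    s, s)
    }
    if (dx != 0 || dy != 0) {
      shifted <- matrix(0, s, s)
      src_r <- seq_len(s) - dy
      src_c <- seq_len(s) - dx
      ok_r <- src_r >= 1 & src_r <= s
      ok_c <- src_c >= 1 & src_c <= s
      shifted[which(ok_r), which(ok_c)] <- out[src_r[ok_r], src_c[ok_c]]
      out <- shifted
    }
    clip01(out)
  })
}
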
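# Block mean-pooling of a matrix onto a g x g grid (rows/cols partitioned as
# evenly as integer arithmetic allows).
mean_pool_grid <- function(image, g) {
  rb <- pmin(floor((seq_len(nrow(image)) - 1) * g / nrow(image)) + 1L, g)
  cb <- pmin(floor((seq_len(ncol(image)) - 1) * g / ncol(image)) + 1L, g)
  sums <- rowsum(t(rowsum(image, rb)), cb)          # g x g (col-block x row-block)
  counts <- tcrossprod(tabulate(cb, g), tabulate(rb, g))
  t(sums / counts)
}

block_mean_vector <- function(v, g) {
  b <- pmin(floor((seq_along(v) - 1) * g / length(v)) + 1L, g)
  as.vector(rowsum(v, b) / tabulate(b, g))
}

#' Extract a fixed-length feature vector from an image
#'
#' The pluggable extractor contract: any function mapping a preprocessed
#' square image to a fixed-length numeric vector can stand behind the
#' classifier branch (e.g. an adapter over a pretrained backbone projected to
#' 512 dimensions). The deterministic built-in extractor produces the default
#' 512-dimensional layout:
#' \itemize{
#'   \item 256 values: 16 x 16 block-mean intensity grid;
#'   \item 128 values: intensity histogram proportions over 128 equal bins;
#'   \item 64 values: row- and column-mean profiles, each block-averaged to
#'     32 values;
#'   \item 64 values: 8 x 8 block-mean grid of the central-difference
#'     gradient magnitude.
#' }
#'
#' @param image Square numeric matrix in `[0, 1]` (side at least 16).
#' @param extractor `"builtin"` or a function `image -> numeric vector`.
#' @return Numeric feature vector (length 512 for the built-in extractor).
#' @export
extract_features <- function(image, extractor = "builtin") {
  assert_image(image)
  if (is.function(extractor)) return(as.numeric(extractor(image)))
  if (!identical(extractor, "builtin")) {
    stop(sprintf("unknown extractor '%s'", extractor), call. = FALSE)
  }
  pooled <- as.vector(mean_pool_grid(image, 16L))
  bins <- pmin(floor(image * 128) + 1L, 128L)
  histo <- tabulate(bins, nbins = 128L) / length(image)
  profiles <- c(block_mean_vector(rowMeans(image), 32L),
                block_mean_vector(colMeans(image), 32L))
  h <- nrow(image); w <- ncol(image)
  gr <- (image[pmin(seq_len(h) + 1, h), ] - image[pmax(seq_len(h) - 1, 1), ]) / 2
  gc <- (image[, pmin(seq_len(w) + 1, w)] - image[, pmax(seq_len(w) - 1, 1)]) / 2
  grad <- as.vector(mean_pool_grid(sqrt(gr^2 + gc^2), 8L))
  c(pooled, histo, profiles, grad)
}

#' Extract features for every image in a dataset
#'
#' @param data Tibble with a `case_id` column and an `image` list-column
#'   (e.g. from [generate_phantom_dataset()]); a `label` column is carried
#'   through when present.
#' @param extractor Passed to [extract_features()].
#' @return A feature table: `case_id`, optional `label`, and columns
#'   `V1..VD`.
#' @export
extract_features_dataset <- function(data, extractor = "builtin") {
  stopifnot(is.data.frame(data), "image" %in% names(data))
  x <- do.call(rbind, purrr::map(data$image, extract_features,
                                 extractor = extractor))
  out <- tibble::as_tibble(as.data.frame(x), .name_repair = "minimal")
  names(out) <- paste0("V", seq_len(ncol(x)))
  lead <- tibble::tibble(case_id = data$case_id)
  if ("label" %in% names(data)) lead$label <- as.integer(data$label)
  dplyr::bind_cols(lead, out)
}

#' Z-score features using training-set statistics
#'
#' Per-dimension mean and standard deviation are estimated on the training
#' table only and applied to `apply_to`, so no test-set information leaks
#' into the scaling. Standard deviations are floored at `1e-8`; constant
#' dimensions therefore map to zeros rather than failing.
#'
#' @param train Feature table whose feature columns define the statistics.
#' @param apply_to Feature table to transform (defaults to `train`).
#' @return `apply_to` with feature columns replaced by z-scores.
#' @export
normalize_features <- function(train, apply_to = train) {
  ftr <- feature_matrix(train)
  fap <- feature_matrix(apply_to)
  if (ncol(ftr$x) != ncol(fap$x)) {
    stop("feature dimension mismatch between `train` and `apply_to`",
         call. = FALSE)
  }
  mu <- colMeans(ftr$x)
  sdev <- pmax(apply(ftr$x, 2, sd), 1e-8)
  z <- sweep(sweep(fap$x, 2, mu), 2, sdev, "/")
  out <- apply_to
  out[colnames(fap$x)] <- as.data.frame(z)
  out
}
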
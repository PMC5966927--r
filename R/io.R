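#' Read a case manifest
#'
#' A manifest is a CSV with one row per case and required columns `case_id`,
#' `path`, `label`; an optional `mask_path` column points at externally
#' supplied lung masks (blank or missing entries fall back to
#' [segment_lungs_fallback()]).
#'
#' @param path Path to the manifest CSV.
#' @return A tibble of validated case records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("case_id", "path", "label")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m$label <- as.integer(m$label)
  if (anyNA(m$label) || !all(m$label %in% c(0L, 1L))) {
    stop("manifest `label` must be 0 (normal) or 1 (abnormal)", call. = FALSE)
  }
  m
}

#' Load a grayscale image from PNG
#'
#' Reads 8- or 16-bit PNGs; intensities are rescaled to `[0, 1]` by the
#' maximum representable value of the stored bit depth. Multi-channel images
#' are averaged to one channel.
#'
#' @param path Path to a PNG file.
#' @return Numeric matrix in `[0, 1]`.
#' @export
load_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    x <- apply(x[, , seq_len(min(3L, dim(x)[3])), drop = FALSE], c(1, 2),
               mean)
  }
  x
}

#' Write an image as an 8-bit grayscale PNG
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  assert_image(image)
  png::writePNG(image, path)
  invisible(path)
}

#' Write an evaluation report (or any list) as pretty-printed JSON
#'
#' @param report A list or evaluation object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, c("triage_eval", "triage_levels_eval"))) {
    report <- unclass(report)
    report <- purrr::map(report, function(el) {
      if (inherits(el, "table")) as.list(as.data.frame(el)) else el
    })
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path Path to the JSON file.
#' @return The parsed list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a phantom dataset to disk
#'
#' Renders a [generate_phantom_dataset()] draw as 8-bit PNG images and masks
#' plus a `manifest.csv` with columns `case_id`, `path`, `mask_path`,
#' `label`, ready for [run_pipeline()].
#'
#' @param config A [phantom_config()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_phantom_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- generate_phantom_dataset(config)
  manifest <- tibble::tibble(
    case_id = d$case_id,
    path = file.path(dir, paste0(d$case_id, ".png")),
    mask_path = file.path(dir, paste0(d$case_id, "_mask.png")),
    label = d$label
  )
  purrr::pwalk(list(d$image, d$mask, manifest$path, manifest$mask_path),
               function(img, mask, p, mp) {
                 write_image_png(img, p)
                 write_image_png(matrix(as.numeric(mask), nrow(mask)), mp)
               })
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
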
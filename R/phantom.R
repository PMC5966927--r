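#' Configuration for the phantom radiograph generator
#'
#' The phantom generator emulates the gross structure of a frontal chest
#' radiograph at configurable resolution: two bright elliptical lung fields on
#' a darker thorax background, a low-amplitude horizontal sinusoidal banding
#' that mimics ribs, pixel noise, and — for abnormal cases — one or more
#' additive Gaussian blob lesions placed inside a lung field. It exists so the
#' whole triage pipeline can be exercised and tested without external imaging
#' data.
#'
#' @param image_size Side length in pixels (square images). At least 16;
#'   64 keeps autoencoder training fast, 512 mirrors full-resolution use.
#' @param n_normal,n_abnormal Case counts for [generate_phantom_dataset()].
#'   The defaults (63/20) reproduce the 3.15:1 normal:abnormal imbalance of
#'   mass-screening archives at desk scale.
#' @param imbalance_ratio Nominal normal:abnormal ratio carried along as
#'   metadata (default 3.15).
#' @param lesion_radius_range Two-element range, in pixels, of lesion radii.
#' @param lesion_contrast Additive peak intensity of a lesion, in (0, 1].
#' @param n_lesions Number of lesions per abnormal case.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return An object of class `phantom_config`.
#' @seealso [generate_phantom()], [generate_phantom_dataset()]
#' @export
#' @examples
#' cfg <- phantom_config(image_size = 32, seed = 1)
#' ph <- generate_phantom(cfg, abnormal = TRUE)
#' range(ph$image)
phantom_config <- function(image_size = 64, n_normal = 63, n_abnormal = 20,
                           imbalance_ratio = 3.15,
                           lesion_radius_range = c(4, 8),
                           lesion_contrast = 0.5, n_lesions = 1,
                           noise_sd = 0.02, seed = 1) {
  if (!is.numeric(image_size) || image_size < 16) {
    stop("`image_size` must be at least 16 pixels", call. = FALSE)
  }
  if (n_normal < 0 || n_abnormal < 0) {
    stop("case counts must be non-negative", call. = FALSE)
  }
  if (!is.numeric(lesion_contrast) || lesion_contrast <= 0 || lesion_contrast > 1) {
    stop("`lesion_contrast` must lie in (0, 1]", call. = FALSE)
  }
  if (length(lesion_radius_range) != 2L || any(lesion_radius_range <= 0) ||
      lesion_radius_range[1] > lesion_radius_range[2]) {
    stop("`lesion_radius_range` must be an increasing pair of positive radii",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(
    list(image_size = as.integer(image_size), n_normal = as.integer(n_normal),
         n_abnormal = as.integer(n_abnormal),
         imbalance_ratio = imbalance_ratio,
         lesion_radius_range = as.numeric(lesion_radius_range),
         lesion_contrast = lesion_contrast, n_lesions = as.integer(n_lesions),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Lung-field geometry shared by image and ground-truth mask: ellipse centres
# and semi-axes as fractions of the side length.
phantom_geometry <- function(s) {
  list(
    centers = list(c(0.52, 0.32), c(0.52, 0.68)) ,  # (row, col) fractions
    semi_axes = c(0.30, 0.14) * s                   # (row, col) in pixels
  )
}

phantom_lung_masks <- function(s) {
  geo <- phantom_geometry(s)
  rows <- matrix(seq_len(s), s, s)
  cols <- matrix(seq_len(s), s, s, byrow = TRUE)
  lapply(geo$centers, function(ctr) {
    dr <- (rows - ctr[1] * s) / geo$semi_axes[1]
    dc <- (cols - ctr[2] * s) / geo$semi_axes[2]
    (dr^2 + dc^2) <= 1
  })
}

#' Generate one phantom radiograph
#'
#' Draws a single labelled phantom image: elliptical lung fields (intensity
#' raised over the background), sinusoidal rib banding inside the lungs,
#' additive Gaussian pixel noise, and — if `abnormal` — Gaussian blob
#' lesions (sd = radius / 2, clipped so intensities stay in `[0, 1]`) centred
#' well inside a lung ellipse. The ground-truth mask is the union of the two
#' lung ellipses, so every lesion pixel centre lies inside the mask.
#'
#' @param config A [phantom_config()].
#' @param abnormal Logical; add lesions and label the case 1.
#' @param seed Integer seed for this draw; defaults to `config$seed`.
#' @param case_id Case identifier string.
#'
#' @return A `labeled_image` list with elements `image` (matrix in `[0, 1]`),
#'   `mask` (0/1 integer matrix), `label` (0 normal / 1 abnormal), `case_id`,
#'   and `lesions` (tibble of centres, radii, contrast; empty when normal).
#' @export
generate_phantom <- function(config, abnormal = FALSE, seed = config$seed,
                             case_id = if (abnormal) "abnormal_1" else "normal_1") {
  stopifnot(inherits(config, "phantom_config"))
  s <- config$image_size
  with_seed(seed, {
    lungs <- phantom_lung_masks(s)
    mask <- lungs[[1]] | lungs[[2]]
    img <- matrix(0.15, s, s)
    img[mask] <- img[mask] + 0.45
    # rib banding: horizontal sinusoid, ~8 bands across the field
    ribs <- matrix(0.05 * sin(2 * pi * seq_len(s) / (s / 8)), s, s)
    img[mask] <- img[mask] + ribs[mask]
    lesions <- tibble::tibble(row = numeric(), col = numeric(),
                              radius = numeric(), contrast = numeric())
    if (abnormal) {
      geo <- phantom_geometry(s)
      rows <- matrix(seq_len(s), s, s)
      cols <- matrix(seq_len(s), s, s, byrow = TRUE)
      for (i in seq_len(config$n_lesions)) {
        side <- sample.int(2L, 1L)
        ctr <- geo$centers[[side]]
        radius <- runif(1, config$lesion_radius_range[1],
                        config$lesion_radius_range[2])
        radius <- min(radius, min(geo$semi_axes) - 1)
        # rejection-sample the centre until the whole +-2 sigma core (a
        # disc of one radius) lies inside the lung mask
        repeat {
          u <- runif(2, -1, 1)
          if (sum(u^2) > 1) next
          cr <- ctr[1] * s + u[1] * (geo$semi_axes[1] - radius)
          cc <- ctr[2] * s + u[2] * (geo$semi_axes[2] - radius)
          disc <- ((rows - cr)^2 + (cols - cc)^2) <= radius^2
          if (all(mask[disc])) break
        }
        sigma <- radius / 2
        blob <- config$lesion_contrast *
          exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * sigma^2))
        img <- img + blob
        lesions <- dplyr::bind_rows(
          lesions, tibble::tibble(row = cr, col = cc, radius = radius,
                                  contrast = config$lesion_contrast))
      }
    }
    img <- img + rnorm(s * s, sd = config$noise_sd)
    structure(
      list(image = clip01(img), mask = matrix(as.integer(mask), s, s),
           label = as.integer(abnormal), case_id = case_id,
           lesions = lesions),
      class = "labeled_image"
    )
  })
}

#' Generate a labelled phantom dataset
#'
#' Draws `n_normal` normal and `n_abnormal` abnormal phantoms (normals first),
#' each from an independent per-case seed derived from `config$seed`, so the
#' whole collection is reproducible bit-for-bit.
#'
#' @param config A [phantom_config()].
#' @return A tibble with columns `case_id`, `label`, and list-columns `image`,
#'   `mask`, `lesions`.
#' @export
#' @examples
#' d <- generate_phantom_dataset(phantom_config(image_size = 32, n_normal = 3,
#'                                              n_abnormal = 1))
#' table(d$label)
generate_phantom_dataset <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$n_normal + config$n_abnormal
  if (n < 1L) stop("requested dataset is empty", call. = FALSE)
  labels <- c(rep(0L, config$n_normal), rep(1L, config$n_abnormal))
  ids <- sprintf("case_%04d", seq_len(n))
  cases <- purrr::map(seq_len(n), function(i) {
    generate_phantom(config, abnormal = labels[i] == 1L,
                     seed = stage_seed(config$seed, paste0("phantom_", i)),
                     case_id = ids[i])
  })
  tibble::tibble(
    case_id = ids,
    label = labels,
    image = purrr::map(cases, "image"),
    mask = purrr::map(cases, "mask"),
    lesions = purrr::map(cases, "lesions")
  )
}

#' Generate a synthetic feature table with a controlled class separation
#'
#' Class-0 rows are standard normal deviates about the origin; class-1 rows
#' are shifted by `class_shift` along the first feature axis. Used as a
#' fixture family for classifier and score-combination tests: `class_shift =
#' 0` gives chance-level separability, large shifts give near-perfect
#' separability.
#'
#' @param n_per_class Length-2 vector `c(n0, n1)` (a scalar is recycled).
#' @param dim Feature dimension (default 512).
#' @param class_shift Mean shift of class 1 along the first axis.
#' @param seed Integer seed.
#' @return A tibble with `case_id`, `label`, and feature columns `V1..Vdim`.
#' @export
generate_feature_table <- function(n_per_class, dim = 512, class_shift = 0,
                                   seed = 1) {
  if (dim < 1) stop("`dim` must be at least 1", call. = FALSE)
  n_per_class <- rep(as.integer(n_per_class), length.out = 2L)
  n <- sum(n_per_class)
  with_seed(seed, {
    x <- matrix(rnorm(n * dim), n, dim)
    labels <- rep(c(0L, 1L), n_per_class)
    x[labels == 1L, 1] <- x[labels == 1L, 1] + class_shift
    out <- tibble::as_tibble(as.data.frame(x), .name_repair = "minimal")
    names(out) <- paste0("V", seq_len(dim))
    dplyr::bind_cols(tibble::tibble(case_id = sprintf("case_%04d", seq_len(n)),
                                    label = labels), out)
  })
}

#' Extract the feature matrix and labels from a feature table
#'
#' @param data A feature table (tibble with optional `case_id`/`label`
#'   columns; every other numeric column is a feature).
#' @return A list with `x` (numeric matrix) and `label` (integer vector or
#'   NULL).
#' @export
feature_matrix <- function(data) {
  stopifnot(is.data.frame(data))
  label <- if ("label" %in% names(data)) as.integer(data$label) else NULL
  keep <- setdiff(names(data), c("case_id", "label", "partition"))
  x <- as.matrix(data[keep])
  storage.mode(x) <- "double"
  list(x = x, label = label)
}
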
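#' Convolutional sparse denoising autoencoder architecture
#'
#' The fixed channel plan of the reconstruction network: a three-stage
#' encoder (conv 16 -> pool -> conv 8 -> pool -> conv 8 -> pool), a conv-8
#' code stage, and a mirrored decoder (conv 8 -> up -> conv 16 -> up ->
#' conv 1). All convolutions are 3x3 same-padded with ReLU activations except
#' the final sigmoid layer, which keeps reconstructions inside `[0, 1]`.
#' At side 512 the encoder code has shape 64x64x8; per-layer parameter
#' counts (160, 1160, 584, 584, 584, 1168, 145) are independent of the side.
#'
#' @param side Input side length in pixels; must be a positive multiple of 8
#'   (three 2x2 poolings).
#' @return An `nn_arch` object.
#' @export
csdae_architecture <- function(side = 512) {
  if (!is.numeric(side) || side <= 0 || side %% 8 != 0) {
    stop("`side` must be a positive multiple of 8", call. = FALSE)
  }
  new_nn_arch(list(
    layer_input(c(side, side, 1L)),
    layer_conv2d(16), layer_maxpool(),
    layer_conv2d(8), layer_maxpool(),
    layer_conv2d(8), layer_maxpool(),
    layer_conv2d(8), layer_upsample(),
    layer_conv2d(8), layer_upsample(),
    layer_conv2d(16), layer_upsample(),
    layer_conv2d(1, activation = "sigmoid")
  ))
}

#' Training configuration for the autoencoder
#'
#' Defaults follow the reconstruction branch's stated settings: Adam with
#' learning rate `1e-4`, batch size 62, an L1 sparsity penalty of `1e-5` on
#' the encoder-code activations, and Gaussian corruption of the inputs with a
#' configurable noise factor (0.01 or 0.05 in the studied settings; 0
#' together with `sparsity_weight = 0` reproduces the plain autoencoder
#' baseline). `weight_decay` is the optional L2 term on the weights,
#' defaulting to 0.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size (shrinks to the dataset size when
#'   fewer images are available).
#' @param epochs Number of training epochs (required; no default is implied
#'   by the method).
#' @param sparsity_weight L1 weight on encoder-code activations.
#' @param weight_decay L2 weight on all convolution weights.
#' @param noise_factor Standard-deviation multiplier of the additive
#'   Gaussian input corruption.
#' @param seed Integer seed controlling initialization, shuffling and noise.
#' @return A `csdae_config` list.
#' @export
csdae_config <- function(learning_rate = 1e-4, batch_size = 62, epochs = 30,
                         sparsity_weight = 1e-5, weight_decay = 0,
                         noise_factor = 0.01, seed = 1) {
  if (learning_rate <= 0 || batch_size <= 0 || epochs <= 0 ||
      sparsity_weight < 0) {
    stop("rates and counts must be positive (sparsity may be 0)", call. = FALSE)
  }
  if (weight_decay < 0 || noise_factor < 0) {
    stop("`weight_decay` and `noise_factor` must be non-negative", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 sparsity_weight = sparsity_weight,
                 weight_decay = weight_decay, noise_factor = noise_factor,
                 seed = as.integer(seed)),
            class = "csdae_config")
}

#' Corrupt an image with additive Gaussian noise
#'
#' `x + noise_factor * e`, `e ~ N(0, 1)` i.i.d. per pixel, clipped to
#' `[0, 1]`. A factor of 0 is the identity.
#'
#' @param image Numeric matrix or array in `[0, 1]`.
#' @param noise_factor Non-negative noise standard deviation.
#' @param seed Optional seed for this draw.
#' @return Corrupted image, same shape.
#' @export
corrupt <- function(image, noise_factor, seed = NULL) {
  if (!is.numeric(noise_factor) || noise_factor < 0) {
    stop("`noise_factor` must be non-negative", call. = FALSE)
  }
  if (noise_factor == 0) return(image)
  with_seed(seed, {
    out <- clip01(image + noise_factor * rnorm(length(image)))
    if (!is.null(dim(image))) dim(out) <- dim(image)
    out
  })
}

# Stack a list of equally sized image matrices into an (H, W, N, 1) array.
stack_images <- function(images) {
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  x <- array(unlist(images, use.names = FALSE), dim = c(h, w, length(images)))
  dim(x) <- c(h, w, length(images), 1L)
  x
}

#' Training cost of the autoencoder
#'
#' `0.5 * mean((x - y)^2) + weight_decay / 2 * sum(W^2) + sparsity_weight *
#' sum(|code|)` — squared reconstruction error (the mean is over every pixel
#' of the batch), an optional L2 term over all convolution weights, and the
#' L1 sparsity term over the encoder-code activations.
#'
#' @param batch_in,batch_out Input and reconstructed arrays/matrices of
#'   identical shape.
#' @param model A trained [train_autoencoder()] model (or `NULL` when both
#'   regularization weights are zero).
#' @param config A [csdae_config()] supplying the regularization weights.
#' @param code Optional encoder-code activations; when omitted they are
#'   recomputed by running the encoder on `batch_in`.
#' @return The scalar cost.
#' @export
reconstruction_loss <- function(batch_in, batch_out, model = NULL,
                                config = csdae_config(), code = NULL) {
  if (!all(dim(batch_in) == dim(batch_out)) ||
      length(batch_in) != length(batch_out)) {
    stop("input and reconstruction shapes differ", call. = FALSE)
  }
  err <- 0.5 * mean((batch_in - batch_out)^2)
  reg <- 0; sparse <- 0
  if (config$weight_decay > 0) {
    w2 <- sum(purrr::map_dbl(model$params, function(p) {
      if (is.null(p$W)) 0 else sum(p$W^2)
    }))
    reg <- config$weight_decay / 2 * w2
  }
  if (config$sparsity_weight > 0) {
    if (is.null(code)) {
      x <- if (length(dim(batch_in)) == 4L) batch_in else
        stack_images(list(as.matrix(batch_in)))
      code <- conv_forward(model$params, model$arch, x, keep = TRUE)$code
    }
    sparse <- config$sparsity_weight * sum(abs(code))
  }
  err + reg + sparse
}

#' Train the convolutional (sparse denoising) autoencoder
#'
#' Trains the [csdae_architecture()] network to reconstruct clean images from
#' Gaussian-corrupted inputs with Adam, recording the mean training cost per
#' epoch. With `noise_factor = 0` and `sparsity_weight = 0` this is the plain
#' autoencoder baseline. Fully reproducible under `config$seed`; training
#' aborts with a diagnostic if the cost turns non-finite.
#'
#' @param images List of square image matrices in `[0, 1]` (side a multiple
#'   of 8), or a tibble with an `image` list-column.
#' @param config A [csdae_config()].
#' @return A `csdae_model` with elements `arch`, `params`, `config`,
#'   `history` (per-epoch cost tibble) and `side`.
#' @export
train_autoencoder <- function(images, config = csdae_config()) {
  if (is.data.frame(images)) images <- images$image
  stopifnot(length(images) >= 1L)
  side <- nrow(images[[1]])
  arch <- csdae_architecture(side)
  n <- length(images)
  x_all <- stack_images(images)
  history <- numeric(config$epochs)
  with_seed(config$seed, {
    params <- nn_init(arch, seed = NULL)
    opt <- adam_init(params)
    t <- 0
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample.int(n)
      bs <- min(config$batch_size, n)
      starts <- seq(1, n, by = bs)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- order_idx[starts[bi]:min(starts[bi] + bs - 1, n)]
        x <- x_all[, , idx, , drop = FALSE]
        xn <- corrupt(x, config$noise_factor)
        fwd <- conv_forward(params, arch, xn, keep = TRUE)
        loss <- reconstruction_loss(
          x, fwd$out, model = list(params = params, arch = arch),
          config = config, code = fwd$code)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training cost at epoch %d, batch %d",
                       epoch, bi), call. = FALSE)
        }
        losses[bi] <- loss
        dout <- (fwd$out - x) / length(x)
        grads <- conv_backward(params, arch, fwd, xn, dout,
                               lambda_s = config$sparsity_weight,
                               lambda_w = config$weight_decay)
        t <- t + 1
        step <- adam_step(params, grads, opt, config$learning_rate, t)
        params <- step$params
        opt <- step$state
      }
      history[epoch] <- mean(losses)
    }
    structure(list(arch = arch, params = params, config = config,
                   history = tibble::tibble(epoch = seq_len(config$epochs),
                                            cost = history),
                   side = side),
              class = "csdae_model")
  })
}

#' Per-image reconstruction error
#'
#' Mean squared difference between a clean input image and its
#' reconstruction. Inputs are not corrupted at scoring time; this is the
#' anomaly score C2 of the triage combination.
#'
#' @param model A trained `csdae_model`.
#' @param images A single matrix, a list of matrices, or a tibble with an
#'   `image` list-column, each at the trained side length.
#' @param batch_size Scoring batch size.
#' @return Numeric vector of per-image mean squared errors.
#' @export
reconstruction_error <- function(model, images, batch_size = 62) {
  stopifnot(inherits(model, "csdae_model"))
  if (is.data.frame(images)) images <- images$image
  if (is.matrix(images)) images <- list(images)
  if (!all(purrr::map_lgl(images, function(m) all(dim(m) == model$side)))) {
    stop("images must match the model's trained side length", call. = FALSE)
  }
  n <- length(images)
  out <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x <- stack_images(images[idx])
    xhat <- conv_forward(model$params, model$arch, x)$out
    out[idx] <- apply((x - xhat)^2, 3, mean)
  }
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.csdae_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$epoch, .data$cost)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training cost",
                  title = "Autoencoder training cost")
}

#' Compare the plain and sparse-denoising autoencoders
#'
#' Trains, for each noise factor, a plain autoencoder (no corruption, no
#' sparsity) and the sparse denoising autoencoder on the same training images
#' and seed, then summarizes per-image mean squared reconstruction error on
#' the training set, the clean test set, and the noise-corrupted test set.
#' For the noised column the corrupted image is fed forward and, as for the
#' other columns, the error is measured against the network's input (the
#' corrupted image), so added noise always costs reconstruction accuracy.
#'
#' @param train_images,test_images Lists of image matrices (or tibbles with
#'   an `image` list-column).
#' @param noise_factors Noise factors to study (default `c(0.01, 0.05)`).
#' @param epochs,seed Training epochs and seed shared by all fits.
#' @return A tibble with columns `model`, `noise_factor`, `split`,
#'   `mse_mean`, `mse_sd`.
#' @export
compare_ae_csdae <- function(train_images, test_images,
                             noise_factors = c(0.01, 0.05), epochs = 30,
                             seed = 1) {
  if (is.data.frame(train_images)) train_images <- train_images$image
  if (is.data.frame(test_images)) test_images <- test_images$image
  rows <- list()
  for (nf in noise_factors) {
    fits <- list(
      ae = train_autoencoder(train_images, csdae_config(
        epochs = epochs, noise_factor = 0, sparsity_weight = 0, seed = seed)),
      csdae = train_autoencoder(train_images, csdae_config(
        epochs = epochs, noise_factor = nf, seed = seed))
    )
    for (mname in names(fits)) {
      model <- fits[[mname]]
      noised <- purrr::imap(test_images, function(img, i) {
        corrupt(img, nf, seed = stage_seed(seed, paste0("noise_eval_", i)))
      })
      err_noised <- reconstruction_error(model, noised)
      sets <- list(train = reconstruction_error(model, train_images),
                   test = reconstruction_error(model, test_images),
                   test_noised = err_noised)
      for (sname in names(sets)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          model = mname, noise_factor = nf, split = sname,
          mse_mean = mean(sets[[sname]]), mse_sd = sd(sets[[sname]]))
      }
    }
  }
  dplyr::bind_rows(rows)
}
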
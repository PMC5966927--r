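# ---------------------------------------------------------------------------
# A compact, fully deterministic neural-network engine: 3x3 same-padded
# convolutions (im2col + BLAS matmul), 2x2 max-pooling / nearest up-sampling,
# dense layers, batch normalization, inverted dropout, and Adam. Feature maps
# are 4-D arrays with dims (H, W, N, C); dense activations are N x D
# matrices. This is all the machinery the autoencoder and classifier head
# need, with exact control over seeding and parameter counts.
# ---------------------------------------------------------------------------

layer_input <- function(shape) list(kind = "input", shape = as.integer(shape))
layer_conv2d <- function(filters, activation = "relu") {
  list(kind = "conv2d", filters = as.integer(filters), activation = activation)
}
layer_maxpool <- function() list(kind = "maxpool2d")
layer_upsample <- function() list(kind = "upsample2d")
layer_dense <- function(units, activation = "relu") {
  list(kind = "dense", units = as.integer(units), activation = activation)
}
layer_batchnorm <- function() list(kind = "batchnorm")
layer_dropout <- function(rate) list(kind = "dropout", rate = rate)

new_nn_arch <- function(layers) structure(list(layers = layers), class = "nn_arch")

# Propagate output shapes through an architecture. Conv-path shapes are
# c(H, W, C); dense-path shapes are a scalar dimension.
arch_shapes <- function(arch) {
  shape <- NULL
  lapply(arch$layers, function(l) {
    shape <<- switch(
      l$kind,
      input = l$shape,
      conv2d = c(shape[1:2], l$filters),
      maxpool2d = c(shape[1:2] %/% 2L, shape[3]),
      upsample2d = c(shape[1:2] * 2L, shape[3]),
      dense = l$units,
      batchnorm = shape,
      dropout = shape,
      stop("unknown layer kind: ", l$kind)
    )
    shape
  })
}

#' Per-layer parameter counts of an architecture
#'
#' Counting rules follow the usual framework conventions: a 3x3 convolution
#' with `C` input channels and `F` filters has `(9 C + 1) F` parameters, a
#' dense layer `(in + 1) units`, batch normalization `4 C` (scale, offset and
#' the two running moments), and pooling/up-sampling/dropout/input layers
#' none. Convolution counts are independent of the spatial side length
#' (weight sharing).
#'
#' @param arch An architecture from [csdae_architecture()] or
#'   [head_architecture()].
#' @return A tibble with columns `layer`, `type`, `output_shape`, `params`.
#' @export
#' @examples
#' count_parameters(csdae_architecture(64))
count_parameters <- function(arch) {
  stopifnot(inherits(arch, "nn_arch"))
  shapes <- arch_shapes(arch)
  prev_channels <- function(i) {
    s <- shapes[[i - 1]]
    if (length(s) == 1L) s else s[3]
  }
  counters <- new.env()
  rows <- purrr::imap(arch$layers, function(l, i) {
    n <- (get0(l$kind, counters, ifnotfound = 0L) + 1L)
    assign(l$kind, n, counters)
    params <- switch(
      l$kind,
      conv2d = (9L * prev_channels(i) + 1L) * l$filters,
      dense = (prev_channels(i) + 1L) * l$units,
      batchnorm = 4L * prev_channels(i),
      0L
    )
    tibble::tibble(
      layer = sprintf("%s_%d", l$kind, n), type = l$kind,
      output_shape = paste(shapes[[i]], collapse = "x"),
      params = as.integer(params)
    )
  })
  dplyr::bind_rows(rows)
}

# Glorot-uniform initialization of all trainable tensors, plus batchnorm
# state. Conv weights are stored as (9*Cin) x F matrices matching im2col.
nn_init <- function(arch, seed = 1) {
  shapes <- arch_shapes(arch)
  with_seed(seed, {
    purrr::imap(arch$layers, function(l, i) {
      if (l$kind == "conv2d") {
        cin <- shapes[[i - 1]][3]
        fan_in <- 9 * cin; fan_out <- 9 * l$filters
        lim <- sqrt(6 / (fan_in + fan_out))
        list(W = matrix(runif(9 * cin * l$filters, -lim, lim),
                        9 * cin, l$filters),
             b = rep(0, l$filters))
      } else if (l$kind == "dense") {
        din <- shapes[[i - 1]]
        lim <- sqrt(6 / (din + l$units))
        list(W = matrix(runif(din * l$units, -lim, lim), din, l$units),
             b = rep(0, l$units))
      } else if (l$kind == "batchnorm") {
        d <- shapes[[i - 1]]
        d <- if (length(d) == 1L) d else d[3]
        list(gamma = rep(1, d), beta = rep(0, d),
             running_mean = rep(0, d), running_var = rep(1, d))
      } else {
        NULL
      }
    })
  })
}

apply_activation <- function(z, activation) {
  switch(activation,
         relu = z * (z > 0),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z,
         stop("unknown activation: ", activation))
}

# Forward pass through a conv architecture. `x` is (H, W, N, 1). Returns the
# output array, per-layer outputs and im2col matrices (kept for backprop so
# nothing is recomputed there), and the code-layer activations (the last
# max-pool output — the encoder code the sparsity penalty acts on).
conv_forward <- function(params, arch, x, keep = FALSE) {
  outs <- vector("list", length(arch$layers))
  cols_cache <- vector("list", length(arch$layers))
  code_layer <- max(which(purrr::map_chr(arch$layers, "kind") == "maxpool2d"))
  a <- x
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    if (l$kind == "conv2d") {
      d <- dim(a)
      cols <- .im2col3x3(a, d[1], d[2], d[3], d[4])
      if (keep) cols_cache[[i]] <- cols
      z <- cols %*% params[[i]]$W
      z <- z + rep(params[[i]]$b, each = nrow(z))
      a <- apply_activation(z, l$activation)
      dim(a) <- c(d[1], d[2], d[3], l$filters)
    } else if (l$kind == "maxpool2d") {
      d <- dim(a)
      r1 <- seq(1, d[1], 2); r2 <- seq(2, d[1], 2)
      c1 <- seq(1, d[2], 2); c2 <- seq(2, d[2], 2)
      a <- pmax(a[r1, c1, , , drop = FALSE], a[r2, c1, , , drop = FALSE],
                a[r1, c2, , , drop = FALSE], a[r2, c2, , , drop = FALSE])
    } else if (l$kind == "upsample2d") {
      d <- dim(a)
      a <- a[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
             drop = FALSE]
    }
    if (keep) outs[[i]] <- a
  }
  list(out = a, outs = outs, cols = cols_cache,
       code = if (keep) outs[[code_layer]] else NULL,
       code_layer = code_layer)
}

# Backward pass mirroring conv_forward. `dout` is dL/d(output). Adds the
# sparsity subgradient lambda_s * sign(code) at the code layer and weight
# decay lambda_w * W to every conv gradient.
conv_backward <- function(params, arch, fwd, x, dout, lambda_s = 0,
                          lambda_w = 0) {
  grads <- vector("list", length(arch$layers))
  d <- dout
  for (i in rev(seq_along(arch$layers))) {
    l <- arch$layers[[i]]
    if (i == fwd$code_layer && lambda_s > 0) {
      d <- d + lambda_s * sign(fwd$outs[[i]])
    }
    input <- if (i > 1) fwd$outs[[i - 1]] else NULL
    if (l$kind == "conv2d") {
      a <- fwd$outs[[i]]
      dz <- switch(l$activation,
                   relu = d * (a > 0),
                   sigmoid = d * a * (1 - a),
                   linear = d)
      din <- dim(input); dzm <- dz
      dim(dzm) <- c(prod(dim(a)[1:3]), dim(a)[4])
      grads[[i]] <- list(
        W = crossprod(fwd$cols[[i]], dzm) + lambda_w * params[[i]]$W,
        b = colSums(dzm))
      if (i == 2) break  # first conv: no gradient past the input needed
      d <- .col2im3x3(tcrossprod(dzm, params[[i]]$W),
                      din[1], din[2], din[3], din[4])
    } else if (l$kind == "maxpool2d") {
      din <- dim(input)
      m <- fwd$outs[[i]]
      r1 <- seq(1, din[1], 2); r2 <- seq(2, din[1], 2)
      c1 <- seq(1, din[2], 2); c2 <- seq(2, din[2], 2)
      dx <- array(0, din)
      used <- array(FALSE, dim(m))
      for (slice in list(list(r1, c1), list(r2, c1), list(r1, c2),
                         list(r2, c2))) {
        sub <- input[slice[[1]], slice[[2]], , , drop = FALSE]
        hit <- (sub == m) & !used
        dx[slice[[1]], slice[[2]], , ] <- d * hit
        used <- used | hit
      }
      d <- dx
    } else if (l$kind == "upsample2d") {
      dd <- dim(d)
      r1 <- seq(1, dd[1], 2); r2 <- seq(2, dd[1], 2)
      c1 <- seq(1, dd[2], 2); c2 <- seq(2, dd[2], 2)
      d <- d[r1, c1, , , drop = FALSE] + d[r2, c1, , , drop = FALSE] +
        d[r1, c2, , , drop = FALSE] + d[r2, c2, , , drop = FALSE]
    }
  }
  grads
}

# Forward pass through the dense head. `x` is N x D. In training mode batch
# statistics and fresh dropout masks (drawn from the current RNG stream) are
# used and the running moments updated with momentum 0.9; in eval mode the
# running moments are used and dropout is the identity. Returns the output,
# the per-layer caches needed by the backward pass, and the (possibly
# updated) parameter list.
dense_forward <- function(params, arch, x, train = FALSE, keep = FALSE,
                          bn_momentum = 0.9, bn_eps = 1e-5) {
  caches <- vector("list", length(arch$layers))
  a <- x
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    if (l$kind == "dense") {
      z <- a %*% params[[i]]$W + rep(params[[i]]$b, each = nrow(a))
      out <- apply_activation(z, l$activation)
      if (keep) caches[[i]] <- list(input = a, out = out)
      a <- out
    } else if (l$kind == "batchnorm") {
      p <- params[[i]]
      if (train) {
        mu <- colMeans(a)
        v <- colMeans(a^2) - mu^2
        invstd <- 1 / sqrt(v + bn_eps)
        xhat <- sweep(sweep(a, 2, mu), 2, invstd, "*")
        params[[i]]$running_mean <- bn_momentum * p$running_mean +
          (1 - bn_momentum) * mu
        params[[i]]$running_var <- bn_momentum * p$running_var +
          (1 - bn_momentum) * v
        if (keep) caches[[i]] <- list(xhat = xhat, invstd = invstd)
      } else {
        xhat <- sweep(sweep(a, 2, p$running_mean), 2,
                      1 / sqrt(p$running_var + bn_eps), "*")
      }
      a <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
    } else if (l$kind == "dropout") {
      if (train) {
        mask <- matrix((runif(length(a)) >= l$rate) / (1 - l$rate), nrow(a))
        if (keep) caches[[i]] <- list(mask = mask)
        a <- a * mask
      }
    }
  }
  list(out = a, caches = caches, params = params)
}

# Backward pass through the dense head; `dout` is dL/d(output). L1 weight
# regularization adds l1_weight * sign(W) to every dense weight gradient.
dense_backward <- function(params, arch, caches, dout, l1_weight = 0) {
  grads <- vector("list", length(arch$layers))
  d <- dout
  for (i in rev(seq_along(arch$layers))) {
    l <- arch$layers[[i]]
    if (l$kind == "dense") {
      cc <- caches[[i]]
      dz <- switch(l$activation,
                   relu = d * (cc$out > 0),
                   sigmoid = d * cc$out * (1 - cc$out),
                   linear = d)
      grads[[i]] <- list(
        W = crossprod(cc$input, dz) + l1_weight * sign(params[[i]]$W),
        b = colSums(dz))
      d <- tcrossprod(dz, params[[i]]$W)
    } else if (l$kind == "batchnorm") {
      cc <- caches[[i]]
      n <- nrow(d)
      dgamma <- colSums(d * cc$xhat)
      dbeta <- colSums(d)
      dxhat <- sweep(d, 2, params[[i]]$gamma, "*")
      d <- sweep(
        dxhat - matrix(colMeans(dxhat), n, ncol(d), byrow = TRUE) -
          cc$xhat * matrix(colMeans(dxhat * cc$xhat), n, ncol(d), byrow = TRUE),
        2, cc$invstd, "*")
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
    } else if (l$kind == "dropout") {
      if (!is.null(caches[[i]])) d <- d * caches[[i]]$mask
    }
  }
  grads
}

# Adam optimizer over nested parameter/gradient lists. Batchnorm running
# moments are state, not trainable, and are skipped.
adam_init <- function(params) {
  purrr::map(params, function(p) {
    if (is.null(p)) return(NULL)
    purrr::map(p[setdiff(names(p), c("running_mean", "running_var"))],
               function(w) list(m = w * 0, v = w * 0))
  })
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(params = params, state = state)
}
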
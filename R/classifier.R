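#' Classifier head architecture
#'
#' The supervised branch: a feed-forward head on fixed 512-dimensional image
#' features — three (batchnorm, dropout, dense) blocks with 512-unit ReLU
#' hidden layers and a single sigmoid output unit. With the default sizes the
#' per-layer parameter counts are 2048 (batchnorm over 512), 262,656
#' (512 -> 512 dense) and 513 (512 -> 1 dense).
#'
#' @param input_dim Feature dimension (default 512).
#' @param hidden_units Width of the two hidden dense layers.
#' @param dropout_rate Dropout rate in each block (0.25 or 0.5 in the
#'   studied settings).
#' @return An `nn_arch` object.
#' @export
head_architecture <- function(input_dim = 512, hidden_units = 512,
                              dropout_rate = 0.25) {
  new_nn_arch(list(
    layer_input(input_dim),
    layer_batchnorm(), layer_dropout(dropout_rate),
    layer_dense(hidden_units, "relu"),
    layer_batchnorm(), layer_dropout(dropout_rate),
    layer_dense(hidden_units, "relu"),
    layer_batchnorm(), layer_dropout(dropout_rate),
    layer_dense(1, "sigmoid")
  ))
}

#' Training configuration for the classifier head
#'
#' Defaults follow the supervised branch's stated settings: Adam with
#' learning rate `3e-5`, batch size 62, dropout 0.25, L1 weight
#' regularization, and either cross-entropy or focal loss with
#' `focal_alpha = 0.1` and `focal_gamma = 0.1`.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param dropout_rate Dropout rate (0.25 or 0.5).
#' @param l1_weight L1 penalty on dense weights.
#' @param loss `"cross_entropy"` or `"focal"`.
#' @param focal_alpha,focal_gamma Focal-loss weighting and focusing
#'   parameters.
#' @param epochs Training epochs (required configuration).
#' @param seed Integer seed.
#' @return A `head_config` list.
#' @export
head_config <- function(learning_rate = 3e-5, batch_size = 62,
                        dropout_rate = 0.25, l1_weight = 1e-5,
                        loss = c("focal", "cross_entropy"),
                        focal_alpha = 0.1, focal_gamma = 0.1, epochs = 50,
                        seed = 1) {
  loss <- match.arg(loss)
  if (learning_rate <= 0 || batch_size <= 0 || epochs <= 0) {
    stop("rates and counts must be positive", call. = FALSE)
  }
  if (!dropout_rate %in% c(0.25, 0.5)) {
    stop("`dropout_rate` must be 0.25 or 0.5", call. = FALSE)
  }
  if (focal_gamma < 0) stop("`focal_gamma` must be non-negative", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 dropout_rate = dropout_rate, l1_weight = l1_weight,
                 loss = loss, focal_alpha = focal_alpha,
                 focal_gamma = focal_gamma, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "head_config")
}

clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Binary cross-entropy loss
#'
#' `-(y log p + (1 - y) log(1 - p))` with probabilities clipped to
#' `[1e-7, 1 - 1e-7]` for stability. Vectorized over `(p, y)` pairs.
#'
#' @param p Predicted probabilities of the positive class.
#' @param y Labels in \{0, 1\}.
#' @return Per-observation losses.
#' @export
cross_entropy <- function(p, y) {
  p <- clip_prob(p)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Focal loss
#'
#' With `p_t = p` for positives and `1 - p` for negatives:
#' `-alpha (1 - p_t)^gamma log(p_t)`. Reduces to [cross_entropy()] at
#' `alpha = 1, gamma = 0`; larger `gamma` down-weights well-classified
#' examples, which matters under class imbalance. The studied settings use
#' `alpha = 0.1, gamma = 0.1`.
#'
#' @param p Predicted probabilities of the positive class.
#' @param y Labels in \{0, 1\}.
#' @param alpha Class weighting factor.
#' @param gamma Focusing exponent, non-negative.
#' @return Per-observation losses.
#' @export
focal_loss <- function(p, y, alpha = 0.1, gamma = 0.1) {
  if (gamma < 0) stop("`gamma` must be non-negative", call. = FALSE)
  pt <- clip_prob(ifelse(y == 1, p, 1 - p))
  -alpha * (1 - pt)^gamma * log(pt)
}

# dL/dp of the configured loss, mean-reduced over the batch.
head_loss_grad <- function(p, y, config) {
  p <- clip_prob(p)
  if (config$loss == "cross_entropy") {
    ((p - y) / (p * (1 - p))) / length(p)
  } else {
    a <- config$focal_alpha; g <- config$focal_gamma
    pt <- ifelse(y == 1, p, 1 - p)
    # clipping keeps pt <= 1 - 1e-7, so (1 - pt)^(g - 1) stays finite
    dpt <- a * (g * (1 - pt)^(g - 1) * log(pt) - (1 - pt)^g / pt)
    dpt * ifelse(y == 1, 1, -1) / length(p)
  }
}

#' Train the classifier head
#'
#' Fits [head_architecture()] on normalized feature vectors with Adam,
#' minimizing the configured loss plus an L1 penalty on the dense weights.
#' Dropout and batch statistics are active only during training; prediction
#' uses the running batch-norm moments and no dropout, so it is
#' deterministic. Reproducible under `config$seed`.
#'
#' @param features Feature table (tibble with feature columns) or numeric
#'   matrix.
#' @param labels 0/1 labels (taken from a `label` column when omitted).
#' @param config A [head_config()].
#' @return A `triage_head` model.
#' @export
train_head <- function(features, labels = NULL, config = head_config()) {
  fm <- if (is.data.frame(features)) feature_matrix(features) else
    list(x = features, label = NULL)
  y <- if (is.null(labels)) fm$label else as.integer(labels)
  if (is.null(y)) stop("labels are required", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  x <- fm$x
  arch <- head_architecture(input_dim = ncol(x),
                            dropout_rate = config$dropout_rate)
  n <- nrow(x)
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
        fwd <- dense_forward(params, arch, x[idx, , drop = FALSE],
                             train = TRUE, keep = TRUE)
        params <- fwd$params
        p <- as.vector(fwd$out)
        loss_vec <- if (config$loss == "focal") {
          focal_loss(p, y[idx], config$focal_alpha, config$focal_gamma)
        } else cross_entropy(p, y[idx])
        losses[bi] <- mean(loss_vec)
        dout <- matrix(head_loss_grad(p, y[idx], config), ncol = 1)
        grads <- dense_backward(params, arch, fwd$caches, dout,
                                l1_weight = config$l1_weight)
        t <- t + 1
        step <- adam_step(params, grads, opt, config$learning_rate, t)
        params <- step$params
        opt <- step$state
      }
      history[epoch] <- mean(losses)
    }
    structure(list(arch = arch, params = params, config = config,
                   history = tibble::tibble(epoch = seq_len(config$epochs),
                                            loss = history)),
              class = "triage_head")
  })
}

#' Predict abnormality probabilities
#'
#' One probability in `[0, 1]` per feature row — the predictor C1 of the
#' triage combination. Methods exist for the trained head and for each of
#' the four baseline classifiers returned by [fit_baselines()].
#'
#' @param object A fitted model.
#' @param features Feature table or numeric matrix.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict_proba <- function(object, features, ...) UseMethod("predict_proba")

features_as_matrix <- function(features) {
  if (is.data.frame(features)) feature_matrix(features)$x else features
}

#' @export
predict_proba.triage_head <- function(object, features, ...) {
  x <- features_as_matrix(features)
  as.vector(dense_forward(object$params, object$arch, x, train = FALSE)$out)
}

#' Fit the four baseline classifiers
#'
#' k-nearest neighbours (k = 5, Euclidean, ties to the lowest training
#' index), logistic regression, a radial-basis SVM with probability
#' calibration, and a 100-tree random forest, all behind the common
#' [predict_proba()] interface and all seeded. Baseline hyperparameters are
#' recorded in each fitted object.
#'
#' @param features Feature table or numeric matrix.
#' @param labels 0/1 labels (taken from a `label` column when omitted).
#' @param seed Integer seed.
#' @return Named list of fitted predictors:
#'   `knn`, `logistic`, `svm`, `random_forest`.
#' @export
fit_baselines <- function(features, labels = NULL, seed = 1) {
  fm <- if (is.data.frame(features)) feature_matrix(features) else
    list(x = features, label = NULL)
  y <- if (is.null(labels)) fm$label else as.integer(labels)
  if (is.null(y)) stop("labels are required", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  x <- fm$x
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  with_seed(seed, {
    knn <- structure(list(x = x, y = y, k = 5L), class = "triage_knn")
    df <- as.data.frame(x)
    logit <- suppressWarnings(glm(y ~ ., data = cbind(y = y, df),
                                  family = binomial()))
    logistic <- structure(list(fit = logit), class = "triage_logistic")
    # features arrive normalized; constant dimensions would trip the
    # internal scaler, so scaling is disabled here
    svm_fit <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                          probability = TRUE, scale = FALSE)
    svm <- structure(list(fit = svm_fit), class = "triage_svm")
    rf_fit <- randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                         ntree = 100)
    rf <- structure(list(fit = rf_fit), class = "triage_rf")
    list(knn = knn, logistic = logistic, svm = svm, random_forest = rf)
  })
}

#' @export
predict_proba.triage_knn <- function(object, features, ...) {
  x <- features_as_matrix(features)
  nn <- knn_indices(x, object$x, object$k)
  rowMeans(matrix(object$y[nn], nrow = nrow(x)))
}

#' @export
predict_proba.triage_logistic <- function(object, features, ...) {
  x <- features_as_matrix(features)
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  # rank deficiency is routine when D approaches n; predictions stay valid
  as.vector(suppressWarnings(
    predict(object$fit, newdata = as.data.frame(x), type = "response")))
}

#' @export
predict_proba.triage_svm <- function(object, features, ...) {
  x <- features_as_matrix(features)
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  pr <- attr(predict(object$fit, x, probability = TRUE), "probabilities")
  as.vector(pr[, "1"])
}

#' @export
predict_proba.triage_rf <- function(object, features, ...) {
  x <- features_as_matrix(features)
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  as.vector(predict(object$fit, x, type = "prob")[, "1"])
}
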
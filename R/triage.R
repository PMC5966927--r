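#' Empirical AUC (Mann-Whitney statistic)
#'
#' The probability that a random positive case outscores a random negative
#' case, estimated by pairwise comparison: strict wins count 1, ties count
#' 1/2 (so a constant score has AUC 0.5). Computed through midranks, which is
#' exactly the tie-credited pairwise count at any size.
#'
#' @param scores_pos Scores of the positive (diseased) cases.
#' @param scores_neg Scores of the negative (normal) cases.
#' @return The empirical AUC in `[0, 1]`.
#' @export
#' @examples
#' empirical_auc(c(0.8, 0.6), c(0.7, 0.1))
empirical_auc <- function(scores_pos, scores_neg) {
  n_pos <- length(scores_pos); n_neg <- length(scores_neg)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be non-empty for an AUC", call. = FALSE)
  }
  if (!all(is.finite(c(scores_pos, scores_neg)))) {
    stop("scores must be finite", call. = FALSE)
  }
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

auc_from_labels <- function(scores, labels) {
  empirical_auc(scores[labels == 1], scores[labels != 1])
}

#' Default coefficient grid for the score combination
#'
#' 0 plus 41 log-spaced magnitudes in `[1e-3, 1e3]` with both signs, ordered
#' by increasing magnitude (positive before negative). The wide span matters
#' because the combined predictors live on very different scales (a
#' probability near 1 versus a reconstruction error near 1e-3); the ordering
#' makes the tie rule "smallest magnitude first" fall out of a first-strict-
#' maximum scan.
#'
#' @return Numeric vector of candidate coefficients.
#' @export
default_beta_grid <- function() {
  mags <- 10^seq(-3, 3, length.out = 41)
  c(0, as.vector(rbind(mags, -mags)))
}

#' Fit the AUC-maximizing linear score combination
#'
#' Given per-case predictor values `C1 ... CP` (C1 the classifier
#' probability, C2 the reconstruction error, further predictors optional) and
#' binary truth labels, evaluates the empirical AUC of
#' `f_b(C) = C1 + b_2 C2 + ... + b_P C_P` over a coefficient grid and returns
#' the maximizer. C1's coefficient is fixed at 1; because every grid contains
#' 0, the fitted AUC is never below the AUC of C1 alone. Ties resolve to the
#' smallest total coefficient magnitude, then to grid order.
#'
#' @param scores Data frame with a 0/1 `label` column and at least two
#'   predictor columns (every non-label, non-case_id numeric column, in
#'   order, is a predictor).
#' @param beta_grid Candidate coefficient values for each of the P - 1 free
#'   coefficients (a vector, recycled to a list for P > 2), or a list of
#'   vectors. Must contain 0.
#' @return A `combination_model` with elements `beta`, `auc`, `predictors`,
#'   `n_pos`, `n_neg`.
#' @export
fit_combination <- function(scores, beta_grid = default_beta_grid()) {
  stopifnot(is.data.frame(scores), "label" %in% names(scores))
  labels <- as.integer(scores$label)
  if (length(unique(labels)) < 2L) {
    stop("labels are degenerate: need both classes", call. = FALSE)
  }
  pred_cols <- setdiff(names(scores), c("case_id", "label", "partition"))
  if (length(pred_cols) < 2L) {
    stop("need at least two predictor columns", call. = FALSE)
  }
  x <- as.matrix(scores[pred_cols])
  p_free <- length(pred_cols) - 1L
  grids <- if (is.list(beta_grid)) beta_grid else
    rep(list(beta_grid), p_free)
  stopifnot(length(grids) == p_free)
  if (!all(purrr::map_lgl(grids, function(g) any(g == 0)))) {
    stop("every coefficient grid must contain 0", call. = FALSE)
  }
  cand <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  # scan in order of total magnitude so the first strict maximum implements
  # the tie rule (smallest |b|, then grid order)
  ord <- order(rowSums(abs(cand)), seq_len(nrow(cand)))
  best <- NULL
  for (i in ord) {
    b <- cand[i, ]
    s <- x[, 1] + as.vector(x[, -1, drop = FALSE] %*% b)
    a <- auc_from_labels(s, labels)
    if (is.null(best) || a > best$auc + 1e-12) {
      best <- list(beta = b, auc = a)
    }
  }
  structure(list(beta = stats::setNames(best$beta, pred_cols[-1]),
                 auc = best$auc, predictors = pred_cols,
                 n_pos = sum(labels == 1), n_neg = sum(labels != 1)),
            class = "combination_model")
}

#' @export
predict.combination_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$predictors])
  x[, 1] + as.vector(x[, -1, drop = FALSE] %*% object$beta)
}

#' @exportS3Method generics::tidy
tidy.combination_model <- function(x, ...) {
  tibble::tibble(term = x$predictors,
                 estimate = c(1, unname(x$beta)),
                 fixed = c(TRUE, rep(FALSE, length(x$beta))))
}

#' @exportS3Method generics::glance
glance.combination_model <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
print.combination_model <- function(x, ...) {
  cat("AUC-maximizing linear combination\n")
  cat(sprintf("  score = %s\n",
              paste(c(x$predictors[1],
                      sprintf("%.4g * %s", x$beta, names(x$beta))),
                    collapse = " + ")))
  cat(sprintf("  empirical AUC = %.4f (n_pos = %d, n_neg = %d)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Fit the reconstruction-error / probability threshold pair
#'
#' Searches a grid of threshold pairs `(T, P)` with `0 < T < T_mean` (the
#' mean training reconstruction error) and `0.5 < P < 1`, scoring each case
#' by how many abnormality flags it raises — `(recon_err > T) + (prob > P)`,
#' an ordinal 0/1/2 score — and selecting the pair that maximizes the
#' empirical AUC of that score. Both grids lie strictly inside their open
#' intervals; ties resolve to the smaller `P`, then the smaller `T`.
#'
#' @param prob Classifier probabilities (predictor C1).
#' @param recon_err Reconstruction errors (predictor C2).
#' @param labels 0/1 truth labels.
#' @param t_mean Mean training reconstruction error bounding the `T` grid;
#'   defaults to `mean(recon_err)` but should be supplied from the
#'   autoencoder's training set.
#' @param grid_sizes Numbers of `T` and `P` grid points, `c(nT, nP)`.
#' @return A `threshold_rule` with elements `t`, `p`, `t_mean`, `auc`.
#' @export
fit_threshold_rule <- function(prob, recon_err, labels,
                               t_mean = mean(recon_err),
                               grid_sizes = c(25, 25)) {
  stopifnot(length(prob) == length(recon_err),
            length(prob) == length(labels))
  if (!is.finite(t_mean) || t_mean <= 0) {
    stop("`t_mean` must be a positive mean reconstruction error",
         call. = FALSE)
  }
  labels <- as.integer(labels)
  t_grid <- t_mean * seq_len(grid_sizes[1]) / (grid_sizes[1] + 1)
  p_grid <- 0.5 + 0.5 * seq_len(grid_sizes[2]) / (grid_sizes[2] + 1)
  best <- NULL
  for (p_thr in p_grid) {
    flag_p <- as.integer(prob > p_thr)
    for (t_thr in t_grid) {
      s <- as.integer(recon_err > t_thr) + flag_p
      a <- auc_from_labels(s, labels)
      if (is.null(best) || a > best$auc + 1e-12) {
        best <- list(t = t_thr, p = p_thr, auc = a)
      }
    }
  }
  structure(list(t = best$t, p = best$p, t_mean = t_mean, auc = best$auc,
                 score = "flag count: (recon_err > T) + (prob > P)"),
            class = "threshold_rule")
}

#' @export
predict.threshold_rule <- function(object, prob, recon_err, ...) {
  as.integer(recon_err > object$t) + as.integer(prob > object$p)
}

#' @exportS3Method generics::tidy
tidy.threshold_rule <- function(x, ...) {
  tibble::tibble(parameter = c("T", "P"), value = c(x$t, x$p),
                 lower = c(0, 0.5), upper = c(x$t_mean, 1))
}

#' @exportS3Method generics::glance
glance.threshold_rule <- function(x, ...) {
  tibble::tibble(auc = x$auc, t_mean = x$t_mean)
}

#' Three-level triage by multi-classifier vote
#'
#' Each case receives one binary vote per panel member (the four baseline
#' classifiers, the trained head, and the threshold-rule flag in the default
#' pipeline). A unanimous 0 panel triages the case `normal`, a unanimous 1
#' panel `abnormal`, and any disagreement `uncertain` — disagreement is
#' precisely the signal that a human reader should look.
#'
#' @param votes Matrix or data frame of 0/1 votes, one row per case and one
#'   column per voter (at least 2 voters).
#' @return Factor with levels `normal`, `abnormal`, `uncertain`.
#' @export
triage_vote <- function(votes) {
  v <- as.matrix(votes)
  if (ncol(v) < 2L) stop("need at least 2 voters per case", call. = FALSE)
  if (!all(v %in% c(0, 1))) stop("votes must be 0/1", call. = FALSE)
  s <- rowSums(v)
  factor(ifelse(s == 0, "normal", ifelse(s == ncol(v), "abnormal",
                                         "uncertain")),
         levels = c("normal", "abnormal", "uncertain"))
}

#' Evaluate a binary classification
#'
#' Precision, recall and F1 for both the abnormal (positive) and the normal
#' class, the 2x2 confusion matrix, and — when scores are supplied — the
#' empirical AUC. A class with no predicted members gets precision 0 with a
#' warning.
#'
#' @param pred Predicted 0/1 labels, or `NULL` to threshold `scores` at 0.5.
#' @param truth True 0/1 labels.
#' @param scores Optional continuous scores for the AUC.
#' @return A `triage_eval` object; see [tidy()] and [glance()] methods.
#' @export
evaluate_binary <- function(pred, truth, scores = NULL) {
  truth <- as.integer(truth)
  if (is.null(pred)) pred <- as.integer(scores > 0.5)
  pred <- as.integer(pred)
  stopifnot(length(pred) == length(truth))
  conf <- table(factor(truth, levels = c(0, 1)),
                factor(pred, levels = c(0, 1)), dnn = c("truth", "pred"))
  cls_metrics <- function(cls) {
    tp <- sum(pred == cls & truth == cls)
    fp <- sum(pred == cls & truth != cls)
    fn <- sum(pred != cls & truth == cls)
    if (tp + fp == 0) {
      warning(sprintf("no cases predicted as class %d; precision set to 0",
                      cls), call. = FALSE)
    }
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    tibble::tibble(class = ifelse(cls == 1, "abnormal", "normal"),
                   precision = precision, recall = recall, f1 = f1)
  }
  metrics <- dplyr::bind_rows(cls_metrics(1L), cls_metrics(0L))
  auc <- if (!is.null(scores) && length(unique(truth)) == 2L) {
    auc_from_labels(scores, truth)
  } else {
    NA_real_  # undefined when only one class is present
  }
  structure(list(metrics = metrics, confusion = conf, auc = auc,
                 n = length(truth)),
            class = "triage_eval")
}

#' @exportS3Method generics::tidy
tidy.triage_eval <- function(x, ...) x$metrics

#' @exportS3Method generics::glance
glance.triage_eval <- function(x, ...) {
  tibble::tibble(accuracy = sum(diag(x$confusion)) / x$n, auc = x$auc,
                 n = x$n)
}

#' @export
print.triage_eval <- function(x, ...) {
  cat("Binary evaluation (n =", x$n, ")\n")
  print(x$metrics)
  if (!is.na(x$auc)) cat(sprintf("empirical AUC: %.4f\n", x$auc))
  invisible(x)
}

#' Evaluate a three-level triage output
#'
#' Counts per level; precision within the definite levels (the fraction of
#' triaged-normal cases that are truly normal, likewise for abnormal); and
#' the pooled total precision over both definite levels. Levels with no
#' members report `NA`.
#'
#' @param triage_labels Factor or character vector in
#'   \{normal, abnormal, uncertain\}.
#' @param truth True 0/1 labels.
#' @return A `triage_levels_eval` object with fields `counts`,
#'   `precision_normal`, `precision_abnormal`, `total_precision`.
#' @export
evaluate_triage <- function(triage_labels, truth) {
  lv <- factor(as.character(triage_labels),
               levels = c("normal", "abnormal", "uncertain"))
  truth <- as.integer(truth)
  stopifnot(length(lv) == length(truth))
  counts <- table(lv)
  correct_normal <- sum(lv == "normal" & truth == 0)
  correct_abnormal <- sum(lv == "abnormal" & truth == 1)
  n_def <- sum(counts[c("normal", "abnormal")])
  structure(list(
    counts = counts,
    precision_normal = if (counts[["normal"]] > 0)
      correct_normal / counts[["normal"]] else NA_real_,
    precision_abnormal = if (counts[["abnormal"]] > 0)
      correct_abnormal / counts[["abnormal"]] else NA_real_,
    total_precision = if (n_def > 0)
      (correct_normal + correct_abnormal) / n_def else NA_real_,
    n = length(truth)
  ), class = "triage_levels_eval")
}

#' @exportS3Method generics::tidy
tidy.triage_levels_eval <- function(x, ...) {
  tibble::tibble(level = names(x$counts), n = as.integer(x$counts),
                 precision = c(x$precision_normal, x$precision_abnormal,
                               NA_real_))
}

#' @exportS3Method generics::glance
glance.triage_levels_eval <- function(x, ...) {
  tibble::tibble(total_precision = x$total_precision,
                 uncertain_fraction = x$counts[["uncertain"]] / x$n,
                 n = x$n)
}

#' @export
print.triage_levels_eval <- function(x, ...) {
  cat("Three-level triage evaluation (n =", x$n, ")\n")
  print(tidy(x))
  cat(sprintf("total precision over definite levels: %s\n",
              ifelse(is.na(x$total_precision), "n/a",
                     sprintf("%.3f", x$total_precision))))
  invisible(x)
}

#' Precision/recall sweep over reconstruction-error thresholds
#'
#' Evaluates the rule "error > t implies abnormal" at `n_points` thresholds
#' spanning slightly beyond the observed error range (half a grid step on
#' each side), so the sweep starts at recall 1 and ends at recall 0; recall
#' is non-increasing in the threshold.
#'
#' @param recon_err Reconstruction errors.
#' @param labels 0/1 truth labels.
#' @param n_points Number of thresholds (at least 2).
#' @return A tibble of class `threshold_sweep` with columns `threshold`,
#'   `precision`, `recall`.
#' @export
threshold_sweep <- function(recon_err, labels, n_points = 50) {
  stopifnot(n_points >= 2, length(recon_err) == length(labels))
  labels <- as.integer(labels)
  lo <- min(recon_err); hi <- max(recon_err)
  step <- if (hi > lo) (hi - lo) / (n_points - 1) else 1e-6
  ts <- seq(lo - step / 2, hi + step / 2, length.out = n_points)
  rows <- purrr::map(ts, function(t) {
    pred <- as.integer(recon_err > t)
    tp <- sum(pred == 1 & labels == 1)
    tibble::tibble(
      threshold = t,
      precision = if (sum(pred) > 0) tp / sum(pred) else NA_real_,
      recall = if (sum(labels) > 0) tp / sum(labels) else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("threshold_sweep", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.threshold_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("precision", "recall"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reconstruction-error threshold", y = NULL,
                  title = "Precision and recall versus threshold")
}
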
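# Euclidean distance matrix between rows of a and b.
row_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# k nearest neighbour indices of each row of `query` among rows of `ref`,
# excluding identical row indices when `exclude_self`; ties break to the
# lowest index.
knn_indices <- function(query, ref, k, exclude_self = FALSE) {
  d <- row_dist(query, ref)
  if (exclude_self) d[cbind(seq_len(nrow(query)), seq_len(nrow(query)))] <- Inf
  res <- apply(d, 1, function(di) order(di)[seq_len(k)])
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Synthetic minority over-sampling (SMOTE)
#'
#' Raises the minority class to `target_count` rows by interpolating new
#' points `x + u (x_nn - x)` with `u ~ U(0, 1)` between a minority sample and
#' one of its `k` nearest minority neighbours (Euclidean metric, ties to the
#' lowest index). Every synthetic point therefore lies on a segment between
#' two original minority points, inside their convex hull. Applied to
#' training features only; `k` is lowered to `n_minority - 1` when the
#' minority class is small, and fewer than 2 minority samples is an error.
#'
#' @param data Feature table with a 0/1 `label` column (features in all other
#'   numeric columns).
#' @param k Number of minority neighbours to interpolate towards.
#' @param target_count Desired minority count; defaults to the majority
#'   count, i.e. exact balance.
#' @param seed Integer seed.
#' @param u Optional fixed interpolation coefficient(s) in `[0, 1]` replacing
#'   the uniform draw (recycled); useful for deterministic checks.
#' @return The input table with synthetic minority rows (case ids
#'   `syn_0001...`) appended.
#' @export
smote <- function(data, k = 5, target_count = NULL, seed = 1, u = NULL) {
  fm <- feature_matrix(data)
  if (is.null(fm$label)) stop("`data` must contain a `label` column", call. = FALSE)
  counts <- table(factor(fm$label, levels = c(0L, 1L)))
  minority <- as.integer(names(counts)[which.min(counts)])
  n_min <- min(counts); n_maj <- max(counts)
  if (n_min < 2L) {
    stop("SMOTE needs at least 2 minority samples", call. = FALSE)
  }
  if (is.null(target_count)) target_count <- n_maj
  n_new <- target_count - n_min
  if (n_new <= 0) return(data)
  k <- min(k, n_min - 1L)
  xm <- fm$x[fm$label == minority, , drop = FALSE]
  nn <- knn_indices(xm, xm, k, exclude_self = TRUE)
  with_seed(seed, {
    base_idx <- rep_len(seq_len(n_min), n_new)[sample.int(n_new)]
    picks <- nn[cbind(base_idx, sample.int(k, n_new, replace = TRUE))]
    u <- if (is.null(u)) runif(n_new) else rep_len(u, n_new)
    syn <- xm[base_idx, , drop = FALSE] +
      u * (xm[picks, , drop = FALSE] - xm[base_idx, , drop = FALSE])
    syn_tbl <- tibble::as_tibble(as.data.frame(syn), .name_repair = "minimal")
    names(syn_tbl) <- colnames(fm$x)
    syn_tbl$label <- minority
    if ("case_id" %in% names(data)) {
      syn_tbl$case_id <- sprintf("syn_%04d", seq_len(n_new))
    }
    dplyr::bind_rows(tibble::as_tibble(data), syn_tbl)
  })
}

#' Remove majority members of Tomek links
#'
#' A Tomek link is a pair of opposite-class samples that are each other's
#' nearest neighbour; for every such link the majority-class member is
#' dropped, cleaning the class boundary. Used after [smote()] for the
#' SMOTE-Tomek condition.
#'
#' @param data Feature table with a 0/1 `label` column.
#' @return The cleaned table. A warning is raised if a class disappears.
#' @export
tomek_remove <- function(data) {
  fm <- feature_matrix(data)
  if (is.null(fm$label)) stop("`data` must contain a `label` column", call. = FALSE)
  y <- fm$label
  if (length(unique(y)) < 2L) return(tibble::as_tibble(data))
  nn1 <- as.vector(knn_indices(fm$x, fm$x, 1L, exclude_self = TRUE))
  majority <- as.integer(names(which.max(table(y))))
  drop <- logical(length(y))
  for (i in seq_along(y)) {
    j <- nn1[i]
    if (y[i] != y[j] && nn1[j] == i) {
      drop[if (y[i] == majority) i else j] <- TRUE
    }
  }
  out <- tibble::as_tibble(data)[!drop, , drop = FALSE]
  if (length(unique(out$label)) < 2L) {
    warning("Tomek-link removal left a single class", call. = FALSE)
  }
  out
}

#' Edited-nearest-neighbour cleaning
#'
#' Removes every sample whose `k`-nearest-neighbour majority vote (excluding
#' itself) disagrees with its own label; removal decisions are taken
#' simultaneously on the original data. A vote is a disagreement only when a
#' strict majority of the neighbours carries the opposite label. Used after
#' [smote()] for the SMOTE-ENN condition.
#'
#' @param data Feature table with a 0/1 `label` column.
#' @param k Neighbourhood size (default 3); `nrow(data)` must exceed `k`.
#' @return The cleaned table.
#' @export
enn_clean <- function(data, k = 3) {
  fm <- feature_matrix(data)
  if (is.null(fm$label)) stop("`data` must contain a `label` column", call. = FALSE)
  n <- length(fm$label)
  if (n <= k) stop("`enn_clean` needs more than `k` samples", call. = FALSE)
  nn <- knn_indices(fm$x, fm$x, k, exclude_self = TRUE)
  votes_against <- rowSums(matrix(fm$label[nn], nrow = n) !=
                             matrix(fm$label, n, k))
  tibble::as_tibble(data)[votes_against <= k / 2, , drop = FALSE]
}
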
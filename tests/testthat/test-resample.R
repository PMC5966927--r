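test_that("smote interpolates on minority segments and balances counts", {
  # two minority points with the interpolation coefficient pinned at 0.5
  d <- tibble::tibble(case_id = letters[1:5], label = c(1L, 1L, 0L, 0L, 0L),
                      x = c(0, 1, 5, 6, 7), y = c(0, 1, 5, 6, 7))
  out <- smote(d, k = 1, u = 0.5, seed = 1)
  syn <- out[grepl("^syn", out$case_id), ]
  expect_equal(nrow(syn), 1L)
  expect_equal(c(syn$x, syn$y), c(0.5, 0.5))

  # default target balances the classes exactly
  set.seed(41)
  big <- tibble::tibble(
    label = rep(c(0L, 1L), c(40, 12)),
    a = rnorm(52), b = rnorm(52), c = rnorm(52))
  bal <- smote(big, seed = 2)
  expect_equal(sum(bal$label == 1), sum(bal$label == 0))

  # every synthetic point lies on a segment between two original minority
  # points (checked against all pairs)
  xm <- as.matrix(big[big$label == 1L, c("a", "b", "c")])
  syn2 <- as.matrix(bal[-seq_len(nrow(big)), c("a", "b", "c")])
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((a + t * ab - p)^2))
  }
  for (i in seq_len(nrow(syn2))) {
    dmin <- Inf
    for (j in seq_len(nrow(xm) - 1)) for (k in (j + 1):nrow(xm)) {
      dmin <- min(dmin, seg_dist(syn2[i, ], xm[j, ], xm[k, ]))
    }
    expect_lt(dmin, 1e-9)
  }

  one <- tibble::tibble(label = c(1L, 0L, 0L), x = c(1, 2, 3))
  expect_error(smote(one), "at least 2 minority")
})

test_that("tomek-link removal matches a brute-force mutual-NN scan", {
  # 1-D: class 0 at {0, 10}, class 1 at {1} -> (0, 1) is a link; 0 removed
  d <- tibble::tibble(label = c(0L, 0L, 1L), x = c(0, 10, 1))
  out <- suppressWarnings(tomek_remove(d))
  expect_equal(out$x, c(10, 1))

  # well-separated classes: nothing removed
  set.seed(42)
  far <- tibble::tibble(label = rep(c(0L, 1L), each = 10),
                        x = c(rnorm(10), rnorm(10) + 100),
                        y = c(rnorm(10), rnorm(10)))
  expect_equal(nrow(tomek_remove(far)), 20L)

  # brute-force equivalence on random 30-point instances
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(60), 30, 2)
    y <- rbinom(30, 1, 0.35)
    if (length(unique(y)) < 2) next
    dd <- tibble::tibble(label = as.integer(y), a = x[, 1], b = x[, 2])
    got <- suppressWarnings(tomek_remove(dd))
    keep <- brute_force_tomek(x, y)
    expect_equal(got$a, x[keep, 1])
    expect_equal(got$label, as.integer(y[keep]))
  }
})

test_that("edited-nearest-neighbour cleaning matches its brute-force oracle", {
  # a class-1 point whose 3 nearest neighbours are all class 0 is removed
  d <- tibble::tibble(label = c(1L, 0L, 0L, 0L, 0L),
                      x = c(0, 0.1, 0.2, 0.3, 9))
  out <- enn_clean(d)
  expect_false(0 %in% out$x)
  expect_true(9 %in% out$x)

  # homogeneous data is untouched
  homo <- tibble::tibble(label = rep(1L, 6), x = rnorm(6))
  expect_equal(nrow(enn_clean(homo)), 6L)

  # brute-force equivalence on random 30-point instances
  for (seed in 1:5) {
    set.seed(seed + 100)
    x <- matrix(rnorm(60), 30, 2)
    y <- rbinom(30, 1, 0.4)
    dd <- tibble::tibble(label = as.integer(y), a = x[, 1], b = x[, 2])
    got <- enn_clean(dd)
    keep <- brute_force_enn(x, y, k = 3)
    expect_equal(got$a, x[keep, 1])
  }

  expect_error(enn_clean(d[1:3, ], k = 3), "more than")
})

test_that("tomek removal warns when a class is emptied", {
  d <- tibble::tibble(label = c(0L, 1L), x = c(0, 1))
  expect_warning(tomek_remove(d), "single class")
})
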
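test_that("classifier head architecture matches the printed layer table", {
  tab <- count_parameters(head_architecture())
  dense <- tab$params[tab$type == "dense"]
  expect_equal(dense, c(262656L, 262656L, 513L))
  bn <- tab$params[tab$type == "batchnorm"]
  expect_equal(bn, c(2048L, 2048L, 2048L))
  expect_equal(tab$output_shape[nrow(tab)], "1")
  expect_equal(sum(tab$params), 2048L * 3L + 262656L * 2L + 513L)
})

test_that("cross-entropy matches its closed forms", {
  expect_equal(cross_entropy(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(0.5, 0), log(2), tolerance = 1e-12)
  expect_lt(cross_entropy(1, 1), 1e-6)
  expect_lt(cross_entropy(0, 0), 1e-6)
  expect_equal(cross_entropy(0.9, 1), -log(0.9), tolerance = 1e-12)
  expect_equal(round(cross_entropy(0.9, 1), 5), 0.10536)
})

test_that("focal loss reduces to cross-entropy and matches the hand oracle", {
  grid <- expand.grid(p = seq(0.005, 0.995, length.out = 50), y = c(0, 1))
  expect_lt(max(abs(focal_loss(grid$p, grid$y, alpha = 1, gamma = 0) -
                      cross_entropy(grid$p, grid$y))), 1e-12)

  # 0.1 * 0.1^0.1 * (-ln 0.9)
  expect_equal(focal_loss(0.9, 1, 0.1, 0.1),
               0.1 * 0.1^0.1 * (-log(0.9)), tolerance = 1e-12)
  expect_equal(round(focal_loss(0.9, 1, 0.1, 0.1), 6), 0.008369)

  # vanishes as p_t -> 1, monotone decreasing in p_t
  expect_lt(focal_loss(1, 1), 1e-6)
  p <- seq(0.01, 0.99, length.out = 200)
  expect_true(all(diff(focal_loss(p, 1, 0.1, 0.1)) < 0))
  expect_true(all(diff(focal_loss(p, 0, 0.1, 0.1)) > 0))
  expect_error(focal_loss(0.5, 1, gamma = -1), "non-negative")
})

test_that("the head separates shifted features and predicts deterministically", {
  ft <- generate_feature_table(c(120, 80), dim = 32, class_shift = 10,
                               seed = 91)
  ftn <- normalize_features(ft)
  cfg <- head_config(epochs = 50, seed = 7)
  m <- train_head(ftn, config = cfg)
  p <- predict_proba(m, ftn)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(empirical_auc(p[ftn$label == 1], p[ftn$label == 0]), 0.95)

  # same seed, same fit; prediction has no stochastic component
  m2 <- train_head(ftn, config = cfg)
  expect_identical(m$params, m2$params)
  expect_identical(p, predict_proba(m, ftn))

  # duplicated inputs give duplicated outputs
  dup <- ftn[c(1, 1, 2), ]
  pd <- predict_proba(m, dup)
  expect_equal(pd[1], pd[2])

  expect_error(train_head(ftn[ftn$label == 0, ], config = cfg),
               "single class")
})

test_that("an unseparable fixture stays at chance level on held-out data", {
  tr <- generate_feature_table(c(120, 120), dim = 16, class_shift = 0,
                               seed = 92)
  te <- generate_feature_table(c(100, 100), dim = 16, class_shift = 0,
                               seed = 93)
  m <- train_head(normalize_features(tr),
                  config = head_config(epochs = 20, seed = 3))
  p <- predict_proba(m, normalize_features(tr, te))
  expect_lt(abs(empirical_auc(p[te$label == 1], p[te$label == 0]) - 0.5), 0.1)
})

test_that("the four baselines share one calibrated probability interface", {
  ft <- generate_feature_table(c(60, 60), dim = 10, class_shift = 5,
                               seed = 94)
  ftn <- normalize_features(ft)
  bl <- fit_baselines(ftn, seed = 5)
  expect_named(bl, c("knn", "logistic", "svm", "random_forest"))

  for (nm in names(bl)) {
    p <- predict_proba(bl[[nm]], ftn)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(empirical_auc(p[ftn$label == 1], p[ftn$label == 0]), 0.9)
  }

  # logistic probability at the training mean point is a proper probability
  center <- ftn[1, ]
  fm <- feature_matrix(ftn)
  center[paste0("V", 1:10)] <- as.list(colMeans(fm$x))
  pc <- predict_proba(bl$logistic, center)
  expect_true(pc > 0 && pc < 1)

  expect_error(fit_baselines(ftn[ftn$label == 1, ]), "single class")
})
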
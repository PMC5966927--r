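test_that("empirical AUC matches hand counts, ties and transforms", {
  expect_equal(empirical_auc(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(empirical_auc(0.5, 0.5), 0.5)
  # 4 pairs: 0.8>0.7, 0.8>0.1, 0.6<0.7, 0.6>0.1 -> 3/4
  expect_equal(empirical_auc(c(0.8, 0.6), c(0.7, 0.1)), 0.75)
  expect_error(empirical_auc(numeric(0), 1), "non-empty")
  expect_error(empirical_auc(c(1, NA), 0), "finite")

  # brute-force pairwise equivalence including ties, and invariance under
  # strictly increasing transforms
  set.seed(101)
  for (i in 1:40) {
    pos <- sample(seq(0, 1, by = 0.1), sample(1:20, 1), replace = TRUE)
    neg <- sample(seq(0, 1, by = 0.1), sample(1:20, 1), replace = TRUE)
    a <- empirical_auc(pos, neg)
    expect_equal(a, brute_force_auc(pos, neg), tolerance = 1e-12)
    expect_equal(empirical_auc(exp(3 * pos), exp(3 * neg)), a)
  }
})

test_that("the combination fit equals exhaustive search and never hurts C1", {
  # C2 identical to C1: AUC constant, tie rule picks beta = 0
  sc <- tibble::tibble(prob = c(0.9, 0.2, 0.7, 0.4),
                       recon_error = c(0.9, 0.2, 0.7, 0.4),
                       label = c(1, 0, 1, 0))
  m <- fit_combination(sc)
  expect_equal(unname(m$beta), 0)

  # 6-case instance against the independent double-loop oracle
  grid <- seq(-2, 2, by = 0.5)
  set.seed(102)
  for (i in 1:10) {
    c1 <- round(runif(6), 2); c2 <- round(runif(6), 2)
    lab <- c(1, 1, 0, 0, 1, 0)
    got <- fit_combination(tibble::tibble(prob = c1, recon_error = c2,
                                          label = lab), beta_grid = grid)
    want <- brute_force_combination(c1, c2, lab, grid)
    expect_equal(unname(got$beta), want$beta)
    expect_equal(got$auc, want$auc)
    # the grid contains 0, so the fit never falls below C1 alone
    expect_gte(got$auc, empirical_auc(c1[lab == 1], c1[lab == 0]))
  }

  # with a wide grid the fit also reaches C2's AUC up to grid resolution
  set.seed(103)
  c1 <- runif(40); c2 <- c(runif(20, 0.6, 1), runif(20, 0, 0.4))
  lab <- rep(c(1, 0), each = 20)
  wide <- fit_combination(tibble::tibble(prob = c1, recon_error = c2,
                                         label = lab))
  expect_gte(wide$auc, empirical_auc(c2[lab == 1], c2[lab == 0]) - 0.02)

  expect_error(fit_combination(tibble::tibble(prob = 1:3, recon_error = 1:3,
                                              label = c(1, 1, 1))),
               "degenerate")
  expect_error(fit_combination(sc, beta_grid = c(1, 2)), "contain 0")
})

test_that("combination objects expose tidy, glance and predict", {
  set.seed(104)
  sc <- tibble::tibble(prob = runif(30), recon_error = runif(30) / 100,
                       label = rep(c(0, 1), 15))
  m <- fit_combination(sc)
  td <- tidy(m)
  expect_equal(td$term, c("prob", "recon_error"))
  expect_equal(td$estimate[1], 1)
  gl <- glance(m)
  expect_true(gl$auc >= 0 && gl$auc <= 1)
  expect_equal(predict(m, sc), sc$prob + m$beta[["recon_error"]] * sc$recon_error)
})

test_that("threshold-pair search equals exhaustive search inside open bounds", {
  set.seed(105)
  for (i in 1:5) {
    prob <- runif(8); err <- runif(8, 0, 0.01)
    lab <- c(1, 0, 1, 0, 1, 0, 0, 1)
    tm <- mean(err)
    got <- fit_threshold_rule(prob, err, lab, t_mean = tm,
                              grid_sizes = c(5, 5))
    want <- brute_force_threshold_rule(prob, err, lab, tm, 5, 5)
    expect_equal(got$t, want$t)
    expect_equal(got$p, want$p)
    expect_equal(got$auc, want$auc)
    expect_true(got$t > 0 && got$t < tm)
    expect_true(got$p > 0.5 && got$p < 1)
  }

  # constant errors with a perfectly separating probability reach AUC 1
  prob <- c(0.9, 0.95, 0.1, 0.2)
  err <- rep(0.005, 4)
  r <- fit_threshold_rule(prob, err, c(1, 1, 0, 0), t_mean = 0.005,
                          grid_sizes = c(5, 25))
  expect_equal(r$auc, 1)

  expect_error(fit_threshold_rule(prob, err, c(1, 1, 0, 0), t_mean = 0),
               "positive")
})

test_that("the unanimity vote yields the three triage levels", {
  v <- rbind(c(0, 0, 0, 0, 0, 0),
             c(1, 1, 1, 1, 1, 1),
             c(0, 1, 0, 0, 0, 0))
  expect_equal(as.character(triage_vote(v)),
               c("normal", "abnormal", "uncertain"))
  expect_error(triage_vote(matrix(1, 3, 1)), "at least 2 voters")
  expect_error(triage_vote(matrix(2, 3, 3)), "0/1")
})

test_that("binary evaluation reproduces the worked precision figures", {
  # 390 of 395 predicted-normal correct; 83 of 88 predicted-abnormal correct
  pred <- c(rep(0, 395), rep(1, 88))
  truth <- c(rep(0, 390), rep(1, 5), rep(0, 5), rep(1, 83))
  ev <- evaluate_binary(pred, truth)
  m <- tidy(ev)
  expect_equal(round(m$precision[m$class == "normal"], 3), 0.987)
  expect_equal(round(m$precision[m$class == "abnormal"], 3), 0.943)
  expect_equal(sum(ev$confusion), 483)

  perfect <- evaluate_binary(truth, truth, scores = truth)
  mp <- tidy(perfect)
  expect_true(all(mp$precision == 1 & mp$recall == 1 & mp$f1 == 1))
  expect_equal(perfect$auc, 1)

  expect_warning(ev0 <- evaluate_binary(rep(0, 4), c(0, 0, 1, 1)),
                 "precision set to 0")
  expect_equal(tidy(ev0)$precision[tidy(ev0)$class == "abnormal"], 0)
})

test_that("triage evaluation pools the definite levels", {
  lv <- c(rep("normal", 395), rep("abnormal", 88), rep("uncertain", 261))
  truth <- c(rep(0, 390), rep(1, 5), rep(0, 5), rep(1, 83),
             rep(c(0, 1), c(200, 61)))
  ev <- evaluate_triage(lv, truth)
  expect_equal(round(ev$precision_normal, 3), 0.987)
  expect_equal(round(ev$precision_abnormal, 3), 0.943)
  expect_equal(round(ev$total_precision, 3), 0.979)

  all_unc <- evaluate_triage(rep("uncertain", 5), c(0, 1, 0, 1, 0))
  expect_true(is.na(all_unc$precision_normal))
  expect_true(is.na(all_unc$total_precision))

  exact <- evaluate_triage(c("normal", "abnormal"), c(0, 1))
  expect_equal(exact$total_precision, 1)
})

test_that("the threshold sweep brackets the error range monotonically", {
  set.seed(106)
  for (i in 1:5) {
    err <- runif(40, 0, 0.01)
    lab <- rbinom(40, 1, 0.4)
    if (sum(lab) == 0) lab[1] <- 1
    sw <- threshold_sweep(err, lab, n_points = 25)
    expect_equal(sw$recall[1], 1)
    expect_equal(sw$recall[nrow(sw)], 0)
    expect_true(all(diff(sw$recall) <= 1e-12))
  }
  expect_s3_class(autoplot(threshold_sweep(runif(10), rbinom(10, 1, 0.5))),
                  "ggplot")
})
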
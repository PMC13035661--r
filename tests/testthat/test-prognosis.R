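test_that("AUC matches pair-counting closed forms", {
  expect_equal(roc_auc(c(2, 3, 0, 1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(1, 3, 0, 2), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both")
})

test_that("trapezoid AUC equals brute-force pair counting on random cohorts", {
  set.seed(7)
  for (i in 1:60) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    # integer-valued markers guarantee ties
    x <- c(sample(0:6, n1, replace = TRUE), sample(0:6, n0, replace = TRUE))
    y <- c(rep(1, n1), rep(0, n0))
    expect_equal(roc_auc(x, y)$auc, bruteforce_auc(x, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(8)
  for (i in 1:10) {
    x <- round(rnorm(40), 1)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    mine <- roc_auc(x, y)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, x, direction = "<", quiet = TRUE)))
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("AUC flips under negation and is invariant to monotone transforms", {
  set.seed(9)
  x <- c(rnorm(20, 1), rnorm(25))
  y <- c(rep(1, 20), rep(0, 25))
  expect_equal(roc_auc(x, y)$auc + roc_auc(-x, y)$auc, 1)
  expect_equal(roc_auc(exp(x), y)$auc, roc_auc(x, y)$auc)
  expect_equal(ks_statistic(exp(x[y == 1]), exp(x[y == 0])),
               ks_statistic(x[y == 1], x[y == 0]))
  # the direction flag recovers markers where smaller values are adverse
  expect_equal(roc_auc(-x, y, direction = "less")$auc, roc_auc(x, y)$auc)
})

test_that("ROC curve is monotone and tidy/glance/autoplot work", {
  set.seed(10)
  x <- rnorm(50); y <- rbinom(50, 1, plogis(x))
  r <- roc_auc(x, y, ci = TRUE)
  tb <- tidy(r)
  expect_true(all(diff(tb$sensitivity) <= 0))   # sens falls as threshold rises
  expect_true(all(diff(tb$specificity) >= 0))
  g <- glance(r)
  expect_true(g$auc_ci_low <= g$auc && g$auc <= g$auc_ci_high)
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("DeLong intervals match an independent implementation", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(60); y <- rbinom(60, 1, plogis(x))
    if (sum(y) < 2 || sum(1 - y) < 2) next
    mine <- auc_confidence_interval(x, y)
    ref <- pROC::ci.auc(pROC::roc(y, x, direction = "<", quiet = TRUE),
                        method = "delong")
    expect_equal(unname(mine[["low"]]), max(0, ref[1]), tolerance = 1e-9)
    expect_equal(unname(mine[["high"]]), min(1, ref[3]), tolerance = 1e-9)
  }
})

test_that("DeLong interval covers the null AUC and degenerates safely", {
  set.seed(13)
  cover <- replicate(300, {
    x <- rnorm(400)
    y <- rep(c(1, 0), each = 200)
    ci <- auc_confidence_interval(x, y)
    ci[["low"]] <= 0.5 && 0.5 <= ci[["high"]]
  })
  expect_gte(mean(cover), 0.93)

  # perfect separation: variance degenerates and the bound sits at 1
  expect_warning(
    ci <- auc_confidence_interval(c(10, 11, 12, 0, 1, 2), rep(c(1, 0), each = 3)),
    "degenerate"
  )
  expect_equal(ci[["high"]], 1)

  # all tied: degenerate variance
  expect_warning(ci2 <- auc_confidence_interval(rep(5, 8), rep(c(1, 0), 4)),
                 "degenerate")
  expect_equal(unname(ci2), c(0.5, 0.5))

  # tiny overlapping samples: wide but ordered around the AUC
  ci3 <- auc_confidence_interval(c(1, 3, 2, 4), c(1, 1, 0, 0))
  auc3 <- roc_auc(c(1, 3, 2, 4), c(1, 1, 0, 0))$auc
  expect_lt(ci3[["low"]], auc3)
  expect_gt(ci3[["high"]], auc3)
  expect_error(auc_confidence_interval(c(1, 2), c(1, 0)), "at least 2")

  # seeded bootstrap alternative is reproducible
  set.seed(99)
  x <- rnorm(40); y <- rbinom(40, 1, plogis(x))
  b1 <- auc_confidence_interval(x, y, method = "bootstrap", seed = 5)
  b2 <- auc_confidence_interval(x, y, method = "bootstrap", seed = 5)
  expect_identical(b1, b2)
})

test_that("the Youden operating point maximises J with low-threshold ties", {
  r <- roc_auc(c(3, 4, 5, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  yj <- youden_operating_point(r)
  expect_equal(yj$threshold, 3)   # J = 2/3 ties with threshold 4; lower wins
  expect_equal(yj$se, 1)
  expect_equal(yj$sp, 2 / 3, tolerance = 1e-12)

  perfect <- youden_operating_point(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0)))
  expect_equal(unlist(perfect[c("se", "sp", "ppv", "npv")]),
               c(se = 1, sp = 1, ppv = 1, npv = 1))

  flat <- youden_operating_point(roc_auc(rep(2, 6), rep(c(1, 0), 3)))
  expect_equal(flat$threshold, 2)
  expect_equal(flat$se, 1)
  expect_equal(flat$sp, 0)
})

test_that("Youden point matches an exhaustive threshold sweep on random data", {
  set.seed(14)
  for (i in 1:20) {
    x <- sample(0:8, 30, replace = TRUE)
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    r <- roc_auc(x, y)
    yj <- youden_operating_point(r)
    sweep_j <- vapply(sort(unique(x)), function(t) {
      mean(x[y == 1] >= t) + mean(x[y == 0] < t) - 1
    }, numeric(1))
    expect_equal(yj$j, max(sweep_j), tolerance = 1e-12)
  }
})

test_that("KS statistic matches the pooled-ECDF brute force and stats::ks.test", {
  expect_equal(ks_statistic(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(ks_statistic(c(1, 3), c(2, 4)), 0.5)
  expect_equal(ks_statistic(c(1, 5, 9), c(1, 5, 9)), 0)
  set.seed(15)
  for (i in 1:20) {
    a <- round(rnorm(sample(5:20, 1)), 1)
    b <- round(rnorm(sample(5:20, 1), 0.5), 1)
    expect_equal(ks_statistic(a, b), bruteforce_ks(a, b), tolerance = 1e-12)
    expect_equal(ks_statistic(a, b),
                 unname(suppressWarnings(stats::ks.test(a, b)$statistic)),
                 tolerance = 1e-12)
  }
  expect_error(ks_statistic(numeric(0), 1), "non-empty")
})

test_that("group tests pick the right family and calibrate type-I error", {
  same <- group_difference_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  big <- group_difference_test(rnorm(40), rnorm(40))
  expect_equal(big$method, "two-sample t")

  skewed <- group_difference_test(rexp(15)^3, rexp(15)^3)
  expect_match(skewed$method, "Mann-Whitney")

  forced <- group_difference_test(runif(40), runif(40),
                                  force_nonparametric = TRUE)
  expect_match(forced$method, "Mann-Whitney")

  paired <- group_difference_test(rnorm(35), rnorm(35), paired = TRUE)
  expect_equal(paired$method, "paired t")
  expect_error(group_difference_test(rnorm(5), rnorm(6), paired = TRUE),
               "equal lengths")
  expect_error(group_difference_test(1, rnorm(5)), "n >= 2")

  set.seed(16)
  rej <- replicate(500, {
    group_difference_test(rnorm(50), rnorm(50))$p_value < 0.05
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)

  shifted <- group_difference_test(rnorm(30), rnorm(30, 2))
  expect_lt(shifted$p_value, 0.001)
})

test_that("likelihood-ratio test matches glm deviances and flags separation", {
  set.seed(17)
  x <- rnorm(200)
  y <- rbinom(200, 1, plogis(x))
  lr <- likelihood_ratio_test(x, y)
  fit <- glm(y ~ x, family = binomial())
  expect_equal(lr$lr_statistic, fit$null.deviance - fit$deviance,
               tolerance = 1e-6)
  expect_error(likelihood_ratio_test(y + rnorm(200, 0, 1e-4), y), "separation")
  expect_error(likelihood_ratio_test(x, rep(1, 200)), "both")

  # power under a strong effect: slope 1 per SD at n = 200
  hits <- replicate(100, {
    xx <- rnorm(200)
    yy <- rbinom(200, 1, plogis(xx))
    likelihood_ratio_test(xx, yy)$p_value < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("marker evaluation assembles the per-marker report", {
  cp <- remodeling_cohort_params("center1")
  cohort <- simulate_marker_cohort(cp$params, cp$n_event, cp$n_nonevent,
                                   seed = 21)
  rep <- evaluate_markers(cohort, c("d_max", "fl_glo", "fl_loc"))
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$auc >= rep$auc_ci_low & rep$auc <= rep$auc_ci_high))
  expect_true(all(rep$se >= 0 & rep$se <= 1 & rep$sp >= 0 & rep$sp <= 1))
  expect_true(all(rep$ks >= 0 & rep$ks <= 1))
  expect_true(all(rep$group_p < 0.05))   # clearly separated groups
  expect_error(evaluate_markers(cohort, "absent"), "missing columns")
  cohort$outcome <- 0
  expect_error(evaluate_markers(cohort, "fl_loc"), "single class")
})
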
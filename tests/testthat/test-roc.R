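test_that("AUC equals the Mann-Whitney pair probability", {
  r <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  r2 <- roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r2$auc, 0.75)

  # brute-force pair counting on random data with ties
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    scores <- sample(1:6, n, replace = TRUE)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels)$auc, auc_pairs(scores, labels))
  }

  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC is near one-half for uninformative scores", {
  set.seed(23)
  scores <- rnorm(2000)
  labels <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.03)
})

test_that("AUC agrees with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  scores <- round(rnorm(80), 1)  # ties present
  labels <- rbinom(80, 1, 0.4)
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("bootstrap AUC interval is reproducible and degenerates correctly", {
  scores <- c(1:10, 21:30)
  labels <- rep(c(0, 1), each = 10)
  ci <- bootstrap_auc_ci(scores, labels, reps = 200, seed = 5)
  expect_equal(as.numeric(ci), c(1, 1))
  set.seed(37)
  s <- rnorm(60) + rep(c(0, 1), c(40, 20))
  l <- rep(c(0, 1), c(40, 20))
  c1 <- bootstrap_auc_ci(s, l, reps = 500, seed = 11)
  c2 <- bootstrap_auc_ci(s, l, reps = 500, seed = 11)
  expect_identical(c1, c2)
  expect_true(c1[1] <= c1[2])
})

test_that("bootstrap AUC interval attains near-nominal coverage", {
  # binormal generator with true AUC 0.85: delta = sqrt(2) * qnorm(0.85)
  delta <- sqrt(2) * qnorm(0.85)
  covered <- vapply(1:200, function(r) {
    set.seed(5000 + r)
    s <- c(rnorm(60), rnorm(20, delta))
    l <- rep(c(0, 1), c(60, 20))
    ci <- bootstrap_auc_ci(s, l, level = 0.95, reps = 1000)
    ci[1] <= 0.85 && 0.85 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("unpaired DeLong statistic behaves like a rank-based test", {
  set.seed(41)
  s <- rnorm(50); l <- rep(c(0, 1), 25)
  ra <- roc_auc(s, l)
  expect_equal(delong_unpaired(ra, ra)$D, 0)

  # invariance under common strictly monotone transform
  s2 <- rnorm(40) + rep(c(0, 1), 20); l2 <- rep(c(0, 1), 20)
  rb <- roc_auc(s2, l2)
  d1 <- delong_unpaired(ra, rb)
  d2 <- delong_unpaired(roc_auc(exp(s), l), roc_auc(exp(s2), l2))
  expect_equal(d1$D, d2$D, tolerance = 1e-12)
  expect_equal(d1$df, d2$df, tolerance = 1e-12)

  one_class <- list(n_pos = 1L, n_neg = 10L)
  expect_error(delong_unpaired(ra, structure(one_class, class = "vrt_roc")),
               "at least 2")
})

test_that("unpaired DeLong matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  s1 <- rnorm(60) + rep(c(0, 1.2), c(35, 25)); l1 <- rep(c(0, 1), c(35, 25))
  s2 <- rnorm(45) + rep(c(0, 0.8), c(30, 15)); l2 <- rep(c(0, 1), c(30, 15))
  mine <- delong_unpaired(roc_auc(s1, l1), roc_auc(s2, l2))
  ref <- pROC::roc.test(pROC::roc(l1, s1, quiet = TRUE, direction = "<"),
                        pROC::roc(l2, s2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = FALSE)
  expect_equal(mine$D, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("Youden cutoff maximizes J, verified by exhaustive search", {
  r <- roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))
  y <- youden_cutoff(r)
  # brute force over all cut positions
  js <- vapply(r$thresholds, function(t) {
    mean(c(2, 4) > t) + mean(c(1, 3) <= t) - 1
  }, numeric(1))
  expect_equal(y$j, max(js))

  rperf <- roc_auc(c(1:5, 11:15), rep(c(0, 1), each = 5))
  yperf <- youden_cutoff(rperf)
  expect_equal(yperf$j, 1)
  expect_equal(yperf$sensitivity, 1)
  expect_equal(yperf$specificity, 1)
  expect_equal(yperf$cutoff, 8)  # midpoint between adjacent observed scores

  # monotone transform moves the cutoff but not J
  set.seed(47)
  s <- rnorm(40); l <- rbinom(40, 1, 0.5); l[1:2] <- c(0, 1)
  y1 <- youden_cutoff(roc_auc(s, l))
  y2 <- youden_cutoff(roc_auc(2 * s + 10, l))
  expect_equal(y1$j, y2$j, tolerance = 1e-12)
  expect_equal(y2$cutoff, 2 * y1$cutoff + 10, tolerance = 1e-9)
})

test_that("encompassment rule uses closed-interval containment", {
  expect_false(ci_encompassment(c(0.8008, 0.9725), c(0.6667, 0.9333)))
  expect_true(ci_encompassment(c(0, 1), c(0.2, 0.9)))
  expect_true(ci_encompassment(c(0.5, 0.9), c(0.5, 0.9)))
  expect_false(ci_encompassment(c(0.5, 0.9), c(0.49, 0.9)))
})

test_that("subgroup ROC comparison separates diagnosis in both offense strata", {
  sim <- simulate_cohort(default_calibration(), seed = 71)
  idx <- compute_vrt_index(sim$trials, impute_method = "individual_mean")
  cmp <- roc_comparison(idx, sim$participants, reps = 500, seed = 72)
  expect_gt(cmp$auc_history, 0.5)
  expect_gt(cmp$auc_no_history, 0.5)
  expect_true(is.finite(cmp$delong$p))
  expect_lt(cmp$youden$cutoff, Inf)
  expect_identical(cmp$encompassed,
                   ci_encompassment(cmp$ci95_history, cmp$ci90_no_history))
})

test_that("both subgroup AUCs exceed chance with high replicate frequency", {
  # under the default calibration the diagnosis contrast is large; the
  # lower bootstrap bound should clear 0.5 in nearly all cohorts
  hits <- vapply(1:100, function(r) {
    sim <- simulate_cohort(default_calibration(), seed = 7000 + r)
    idx <- compute_vrt_index(sim$trials, impute_method = "individual_mean")
    d <- merge(idx, sim$participants, by = "participant_id")
    hist <- d$cso | d$csam
    ok <- TRUE
    for (sub in list(d[hist, ], d[!hist, ])) {
      ci <- bootstrap_auc_ci(sub$value, sub$pedohebephilia, level = 0.90,
                             reps = 300)
      ok <- ok && ci[1] > 0.5
    }
    ok
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
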
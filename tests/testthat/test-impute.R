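test_that("individual-mean imputation fills with the participant's category mean", {
  tr <- make_participant_trials("A", list(FT2 = c(1000, 1400, rep(NA, 6))))
  out <- impute_individual_mean(tr)
  expect_s3_class(out, "vrt_imputation")
  expect_equal(out$m, 1L)
  comp <- out$datasets[[1]]
  filled <- comp$latency_ms[comp$category == "FT2" & comp$imputed]
  expect_equal(filled, rep(1200, 6))
  expect_false(any(is.na(comp$latency_ms)))
})

test_that("simple imputations are the identity on complete data", {
  sim <- simulate_cohort({
    cfg <- default_calibration(n_participants = 10L)
    cfg$censor_at <- Inf; cfg$mcar_rate <- 0
    cfg
  }, seed = 4)
  expect_equal(sum(sim$trials$missing), 0L)
  for (f in list(impute_individual_mean, impute_regression)) {
    comp <- f(sim$trials)$datasets[[1]]
    expect_equal(comp$latency_ms, sim$trials$latency_ms)
    expect_false(any(comp$imputed))
  }
})

test_that("individual-mean imputation requires an observed value in the category", {
  tr <- make_participant_trials("A", list(FT5 = rep(NA_real_, 8)))
  expect_error(impute_individual_mean(tr), "EMPTY_CATEGORY")
})

test_that("regression imputation predicts from the other category means", {
  # perfectly collinear toy: every participant's category means are equal,
  # so the fitted model must return each participant's own level
  set.seed(31)
  trs <- list()
  for (i in 1:6) {
    lev <- 900 + 150 * i
    lat <- lapply(setNames(nm = vrt_categories()$category),
                  function(x) lev + c(-2, 2, -1, 1, 0, 0, -3, 3))
    trs[[i]] <- make_participant_trials(paste0("P", i), lat)
  }
  # hide two trials of P3 in MT2
  tr <- do.call(rbind, trs)
  hide <- which(tr$participant_id == "P3" & tr$category == "MT2")[1:2]
  tr$latency_ms[hide] <- NA
  tr$rating[hide] <- NA
  tr$missing[hide] <- TRUE
  comp <- impute_regression(tr)$datasets[[1]]
  expect_equal(comp$latency_ms[hide], rep(1350, 2), tolerance = 1e-6)
})

test_that("regression-imputed values are consistent with the generator's structure", {
  cfg <- default_calibration(n_participants = 400L)
  sim <- simulate_cohort(cfg, seed = 55)
  comp <- impute_regression(sim$trials)$datasets[[1]]
  d <- merge(comp, sim$participants[, c("participant_id", "pedohebephilia")],
             by = "participant_id")
  imp <- d[d$imputed & d$pedohebephilia, ]
  # MCAR-missing trials of diagnosed participants: imputed values should
  # center near the group/category mean (within 2 SE under the calibration)
  for (k in unique(imp$category)) {
    v <- imp$latency_ms[imp$category == k]
    if (length(v) < 10) next
    mu <- cfg$latency_mean["interest", k]
    se <- sqrt(cfg$latency_sd["interest", k]^2 + cfg$speed_sd^2 +
                 cfg$child_shift_sd^2) / sqrt(length(v))
    expect_lt(abs(mean(v) - mu), 2 * (se + 60))
  }
})

test_that("PMM draws observed donor values, reproducibly", {
  sim <- simulate_cohort(default_calibration(n_participants = 60L), seed = 14)
  tr <- sim$trials
  out1 <- impute_pmm(tr, m = 5, k_donors = 5, classes = "none", seed = 99)
  out2 <- impute_pmm(tr, m = 5, k_donors = 5, classes = "none", seed = 99)
  expect_equal(out1$m, 5L)
  expect_identical(lapply(out1$datasets, `[[`, "latency_ms"),
                   lapply(out2$datasets, `[[`, "latency_ms"))

  # every imputed value is an observed category mean of some participant
  cm <- category_means(tr)
  for (ds in out1$datasets) {
    imp <- ds[ds$imputed, ]
    for (k in unique(imp$category)) {
      donors <- cm$mean_raw[cm$category == k & !is.na(cm$mean_raw)]
      expect_true(all(imp$latency_ms[imp$category == k] %in% donors))
    }
  }
})

test_that("by-individual PMM restricts donors to the participant's own trials", {
  sim <- simulate_cohort(default_calibration(n_participants = 40L), seed = 15)
  tr <- sim$trials
  out <- impute_pmm(tr, m = 3, classes = "by_individual", seed = 7)
  for (ds in out$datasets) {
    imp <- which(ds$imputed)
    for (i in imp) {
      own <- tr$latency_ms[tr$participant_id == ds$participant_id[i] &
                             tr$category == ds$category[i]]
      expect_true(ds$latency_ms[i] %in% own[!is.na(own)])
    }
  }
})

test_that("PMM warns when the donor pool is smaller than k", {
  tr <- make_participant_trials("A", list(MT1 = c(950, 1050, 980, 1020,
                                                  990, NA, NA, NA)))
  expect_warning(impute_pmm(tr, m = 2, k_donors = 50, classes = "by_individual",
                            seed = 1),
                 "donor pool smaller")
})

test_that("Rubin pooling reproduces hand-computed values", {
  # zero between-imputation variance
  p <- pool_rubin(rep(1, 5), rep(0.04, 5), df_complete = 100)
  expect_equal(p$estimate, 1)
  expect_equal(p$B, 0)
  expect_equal(p$T, 0.04)

  # m = 2 hand computation: W = 1, B = 0.5, T = 1 + 1.5 * 0.5 = 1.75
  p2 <- pool_rubin(c(0, 1), c(1, 1), df_complete = 50)
  expect_equal(p2$estimate, 0.5)
  expect_equal(p2$W, 1)
  expect_equal(p2$B, 0.5)
  expect_equal(p2$T, 1.75)
  # Barnard-Rubin df by hand: lambda = 1.5*0.5/1.75; df_old = (m-1)/lambda^2;
  # df_obs = (51/53)*50*(1-lambda); df = df_old*df_obs/(df_old+df_obs)
  lambda <- 0.75 / 1.75
  df_old <- 1 / lambda^2
  df_obs <- (51 / 53) * 50 * (1 - lambda)
  expect_equal(p2$df, df_old * df_obs / (df_old + df_obs), tolerance = 1e-12)
  expect_equal(p2$ci, 0.5 + c(-1, 1) * qt(0.975, p2$df) * sqrt(1.75),
               tolerance = 1e-12)

  expect_error(pool_rubin(1, 1, 10), "multiple imputations")

  # T >= W always
  set.seed(88)
  for (r in 1:20) {
    est <- rnorm(5); v <- runif(5)
    pr <- pool_rubin(est, v, 30)
    expect_gte(pr$T, pr$W)
  }
})

test_that("H1 conclusions agree across imputation methods on one cohort", {
  # sensitivity harness: signs and significance of the diagnosis effect
  # should not depend on the imputation scheme (soft check, reported)
  sim <- simulate_cohort(default_calibration(), seed = 61)
  flags <- c()
  for (method in c("individual_mean", "regression", "pmm", "pmm_by_individual")) {
    idx <- compute_vrt_index(sim$trials, impute_method = method, seed = 62)
    fit <- if (is.data.frame(idx)) {
      fit_interaction_model(merge(idx, sim$participants, by = "participant_id"))
    } else {
      fit_interaction_pooled(idx, sim$participants)
    }
    cf <- fit$coefficients
    i <- match("pedohebephilia", cf$term)
    flags[method] <- sign(cf$beta[i]) * (cf$p[i] < 0.05)
  }
  expect_true(all(flags == 1))
})
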
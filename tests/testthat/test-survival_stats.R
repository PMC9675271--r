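test_that("KM estimator: product-limit arithmetic and median", {
  # events at t = 1 and t = 2, no censoring
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km$surv, c(0.5, 0))
  expect_equal(km$median, 1)
  expect_true(km$median_reached)
  # all censored: S = 1 throughout, median not reached
  km2 <- km_estimate(c(3, 5, 7), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  expect_false(km2$median_reached)
  expect_true(is.na(km2$median))
  # step function is non-increasing with S(0) = 1 implied
  sv <- simulate_survival(data.frame(z = rep(0, 100)), 0,
                          baseline_rate = 0.1, censor_rate = 0.05,
                          seed = 1)
  km3 <- km_estimate(sv$time, sv$event)
  expect_true(all(diff(km3$surv) <= 1e-12))
  expect_true(all(km3$surv <= 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank test matches a by-hand O-E computation", {
  # 6 subjects, two groups, all events, no ties
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  group <- c("a", "b", "a", "b", "a", "b")
  # by hand: at each event time, O - E for group a, hypergeometric variance
  o_minus_e <- 0; v <- 0
  for (t in time) {
    at_risk <- time >= t
    n <- sum(at_risk); n_a <- sum(at_risk & group == "a")
    d <- 1
    o <- as.numeric(group[time == t] == "a")
    e <- d * n_a / n
    o_minus_e <- o_minus_e + (o - e)
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  manual <- o_minus_e^2 / v
  lr <- logrank_test(time, event, group)
  expect_equal(lr$statistic, manual, tolerance = 1e-12)
  expect_equal(lr$df, 1L)
  # label symmetry
  lr2 <- logrank_test(time, event, ifelse(group == "a", "b", "a"))
  expect_equal(lr2$statistic, lr$statistic)
  expect_error(logrank_test(time, event, rep("a", 6)), "two groups")
})

test_that("Cox wrapper matches the Efron partial-likelihood oracle", {
  set.seed(NULL)
  x <- data.frame(z1 = withr::with_seed(10, rnorm(50)),
                  z2 = withr::with_seed(11, rbinom(50, 1, 0.5)))
  sv <- simulate_survival(x, c(z1 = 0.5, z2 = -0.7),
                          baseline_rate = 0.1, censor_rate = 0.05,
                          seed = 12)
  fit <- cox_fit(sv$time, sv$event, x)
  beta_oracle <- oracle_cox_efron(sv$time, sv$event, as.matrix(x))
  expect_equal(fit$beta, unname(beta_oracle), tolerance = 1e-4)
  expect_true(all(fit$hr > 0))
  expect_true(all(fit$ci_low <= fit$hr & fit$hr <= fit$ci_high))
  # two identical groups: beta ~ 0, p ~ 1
  xid <- data.frame(z = rep(c(0, 1), each = 20))
  svid <- data.frame(time = rep(c(1:10, 2:11), 2),
                     event = rep(1, 40))
  fit0 <- cox_fit(svid$time[1:40], svid$event[1:40], xid)
  expect_lt(abs(fit0$beta), 0.05)
  expect_gt(fit0$p_wald, 0.9)
  expect_error(cox_fit(sv$time, sv$event, data.frame(c1 = rep(1, 50))),
               "constant")
})

test_that("maxstat recovers a planted cutpoint and is deterministic", {
  n <- 400
  x <- withr::with_seed(20, runif(n, 0, 10))
  rate <- ifelse(x > 5, 0.3, 0.1)   # hazard triples above x = 5
  time <- withr::with_seed(21, rexp(n, rate))
  event <- rep(1, n)
  ms <- maxstat_cutoff(time, event, x, n_perm = 200, seed = 22)
  expect_lt(abs(ms$cutoff - 5), 0.5)
  expect_lt(ms$p_value, 0.05)
  ms2 <- maxstat_cutoff(time, event, x, n_perm = 200, seed = 22)
  expect_identical(ms, ms2)
  # cutoff strictly inside the quantile window
  expect_gt(ms$cutoff, quantile(x, 0.10))
  expect_lt(ms$cutoff, quantile(x, 0.90))
  expect_error(maxstat_cutoff(time, event, rep(1, n)), "constant")
})

test_that("lasso-Cox: penalty limits and signal recovery", {
  n <- 300
  x <- as.data.frame(withr::with_seed(30, {
    m <- matrix(rnorm(n * 10), ncol = 10)
    colnames(m) <- paste0("v", 1:10)
    m
  }))
  sv <- simulate_survival(x, c(v1 = 1, v2 = -1, rep(0, 8)),
                          baseline_rate = 0.05, censor_rate = 0.02,
                          seed = 31)
  # lambda -> infinity: empty model
  big <- lasso_cox(sv$time, sv$event, x, lambda = 10)
  expect_length(big$selected, 0L)
  # lambda = 0 reproduces the unpenalized Cox fit
  x2 <- x[, 1:3]
  free <- lasso_cox(sv$time, sv$event, x2, lambda = 0)
  ref <- cox_fit(sv$time, sv$event, x2)
  expect_equal(unname(free$coef), ref$beta, tolerance = 1e-3)
  # CV-lambda keeps the signals
  cvfit <- lasso_cox(sv$time, sv$event, x, lambda = "cv", seed = 32,
                     n_folds = 5)
  expect_true(all(c("v1", "v2") %in% cvfit$selected))
})

test_that("stability selection keeps signals, drops noise, reproduces", {
  n <- 300
  x <- as.data.frame(withr::with_seed(40, {
    m <- matrix(rnorm(n * 5), ncol = 5)
    colnames(m) <- c("signal", paste0("noise", 1:4))
    m
  }))
  sv <- simulate_survival(x, c(signal = 1.5, rep(0, 4)),
                          baseline_rate = 0.05, censor_rate = 0.02,
                          seed = 41)
  res <- stability_selection(sv$time, sv$event, x, n_bootstrap = 50,
                             seed = 42, n_folds = 5, nlambda = 30)
  expect_s3_class(res, "stability_result")
  expect_true(all(res$selection_frequency >= 0 &
                    res$selection_frequency <= 1))
  sig <- res[res$variable == "signal", ]
  expect_true(sig$retained)
  expect_gte(sig$selection_frequency, 0.95)
  expect_true(all(!res$retained[res$variable != "signal"]))
  # retained HR summaries: interval ordered and bracketing exp(1.5) loosely
  expect_lte(sig$hr_ci_low, sig$hr_ci_high)
  expect_gt(sig$hr_mean, exp(1.5) * 0.7)
  expect_lt(sig$hr_mean, exp(1.5) * 1.4)
  # reproducible under the master seed
  res2 <- stability_selection(sv$time, sv$event, x, n_bootstrap = 50,
                              seed = 42, n_folds = 5, nlambda = 30)
  expect_identical(res, res2)
  # the protocol constants default to the published values
  expect_equal(formals(stability_selection)$n_bootstrap, 500)
  expect_equal(formals(stability_selection)$retain_threshold, 0.90)
  expect_equal(eval(formals(stability_selection)$hr_quantiles),
               c(0.05, 0.95))
})
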
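# Survival branch: Cox fits, backward elimination, Kaplan-Meier, log-rank.

toy_surv <- function() {
  list(time = c(1, 2, 3, 4, 5, 6), event = rep(1, 6),
       x = c(1, 1, 0, 1, 0, 0))
}

# Manual two-group log-rank computation (Mantel-Haenszel), written out
# from the standard formula.
manual_logrank <- function(time, event, group) {
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

test_that("the Newton-Raphson estimate maximizes the Efron likelihood", {
  d <- toy_surv()
  fit <- cox_fit(d$time, d$event, data.frame(x = d$x))
  b_grid <- grid_max_beta(d$time, d$event, d$x)
  expect_lt(abs(fit$table$beta - b_grid), 1e-4)
  expect_gte(fit$loglik[2], fit$loglik[1])
})

test_that("a permuted covariate recovers the null at scale", {
  co <- simulate_cohort(cohort_sim_spec(n = 5000, seed = 51))
  withr::with_seed(52, x <- sample(co$gcs_low))
  fit <- cox_fit(co$time, co$event, data.frame(x = x))
  expect_lt(abs(fit$table$beta), 0.1)
  expect_true(fit$table$lo < 1 && fit$table$hi > 1)
})

test_that("doubling a covariate halves its coefficient", {
  co <- simulate_cohort(cohort_sim_spec(n = 300, seed = 53))
  x <- co$age
  f1 <- cox_fit(co$time, co$event, data.frame(x = x))
  f2 <- cox_fit(co$time, co$event, data.frame(x = 2 * x))
  expect_equal(f2$table$beta, f1$table$beta / 2, tolerance = 1e-8)
})

test_that("degenerate inputs are reported, not silently fitted", {
  co <- simulate_cohort(cohort_sim_spec(n = 60, seed = 54))
  expect_warning(
    fit <- cox_fit(co$time, co$event,
                   data.frame(x = co$gcs_low, k = rep(1, 60))),
    "constant covariate")
  expect_identical(fit$table$term, "xTRUE")
  expect_error(cox_fit(co$time, rep(0, 60), data.frame(x = co$gcs_low)),
               "at least one event")
  # perfect separation: events only where x = 1, monotone likelihood
  tm <- c(1, 2, 3, 10, 11, 12)
  ev <- c(1, 1, 1, 0, 0, 0)
  expect_warning(cox_fit(tm, ev, data.frame(x = c(1, 1, 1, 0, 0, 0))),
                 "monotone likelihood|beta may be infinite")
})

test_that("backward elimination drops null covariates and keeps strong ones", {
  spec <- cohort_sim_spec(n = 1000, seed = 55,
                          true_log_hr = c(gcs_low = log(4), vessel_tica = 0,
                                          vessel_mca = 0, dtabr_high = 0))
  co <- simulate_cohort(spec)
  withr::with_seed(56, noise <- rnorm(1000))
  sel <- backward_select(co$time, co$event,
                         data.frame(gcs_low = co$gcs_low, noise = noise))
  expect_identical(sel$retained, "gcs_low")
  expect_identical(sel$dropped, "noise")
  # a single significant covariate is a fixed point
  sel2 <- backward_select(co$time, co$event,
                          data.frame(gcs_low = co$gcs_low))
  expect_identical(sel2$retained, "gcs_low")
  expect_identical(sel2$dropped, character(0))
})

test_that("a final model never reports non-significant covariates", {
  for (s in 57:59) {
    co <- simulate_cohort(cohort_sim_spec(
      n = 1000, seed = s,
      true_log_hr = c(gcs_low = 0, vessel_tica = 0, vessel_mca = 0,
                      dtabr_high = 0)))
    sel <- backward_select(co$time, co$event,
                           data.frame(g = co$gcs_low, d = co$dtabr_high))
    expect_true(is.null(sel$fit) || all(sel$fit$table$p <= 0.05))
  }
})

test_that("factor covariates are eliminated as whole blocks", {
  co <- simulate_cohort(cohort_sim_spec(
    n = 800, seed = 60,
    true_log_hr = c(gcs_low = log(4), vessel_tica = 0, vessel_mca = 0,
                    dtabr_high = log(4))))
  sel <- backward_select(co$time, co$event,
                         data.frame(gcs_low = co$gcs_low,
                                    vessel = co$vessel,
                                    dtabr_high = co$dtabr_high))
  if ("vessel" %in% sel$dropped)
    expect_false(any(grepl("vessel", sel$fit$table$term)))
})

test_that("Kaplan-Meier equals the empirical survival without censoring", {
  withr::with_seed(61, tm <- sort(rexp(20) * 30) + 1)
  km <- km_fit(tm, rep(1, 20))
  expect_equal(km$curves$surv, 1 - seq_len(20) / 20, tolerance = 1e-12)
  expect_equal(km$curves$surv[20], 0)
  expect_equal(unname(km$median), sort(tm)[10])
})

test_that("all-censored data keep survival at one, median not reached", {
  km <- km_fit(c(90, 90, 90), c(0, 0, 0))
  expect_true(all(km$curves$surv == 1))
  expect_true(is.na(km$median))
})

test_that("the product-limit curve converges to the exponential form", {
  spec <- cohort_sim_spec(
    n = 5000, true_log_hr = c(gcs_low = 0, vessel_tica = 0,
                              vessel_mca = 0, dtabr_high = 0),
    baseline_hazard = 0.012, seed = 62)
  co <- simulate_cohort(spec)
  km <- km_fit(co$time, co$event)
  grid <- km$curves$time[km$curves$time < 90]
  s_hat <- km$curves$surv[km$curves$time < 90]
  expect_lt(max(abs(s_hat - exp(-0.012 * grid))), 0.02)
})

test_that("the log-rank statistic equals the manual computation", {
  d <- toy_surv()
  lr <- logrank_test(d$time, d$event, d$x)
  expect_equal(lr$statistic, manual_logrank(d$time, d$event, d$x),
               tolerance = 1e-12)
  expect_equal(lr$df, 1L)
})

test_that("log-rank has power under a fourfold hazard ratio", {
  withr::with_seed(63, {
    g <- rep(0:1, each = 250)
    tm <- pmin(rexp(500, rate = 0.01 * exp(log(4) * g)), 90)
    ev <- tm < 90
    expect_lt(logrank_test(tm, ev, g)$p, 0.001)
  })
})

test_that("log-rank p-values are calibrated under the null", {
  ps <- vapply(1:50, function(s) {
    withr::with_seed(1000 + s, {
      g <- rep(0:1, each = 1000)
      tm <- pmin(rexp(2000, rate = 0.01), 90)
      ev <- tm < 90
      logrank_test(tm, ev, g)$p
    })
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
  expect_error(logrank_test(c(1, 2), c(1, 1), c(1, 1)), "2 non-empty groups")
})
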
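toy_series <- function(n_pre, n_post, beta = c(0.05, -0.001, 0.01, 0.002),
                       sigma = 0, seed = 1,
                       start = as.Date("2020-03-01")) {
  ser <- generate_its_series(beta[1], beta[2], beta[3], beta[4],
                             n_pre, n_post, sigma, seed, start_date = start)
  list(series = ser[, c("date", "proportion")],
       policy_date = attr(ser, "policy_date"))
}

test_that("the design matrix is built exactly as specified", {
  ts <- toy_series(15, 15)
  d <- build_its_design(ts$series, ts$policy_date, 15)
  expect_identical(nrow(d), 30L)
  expect_identical(d$t, 1:30)
  expect_identical(d$policy, c(rep(0L, 15), rep(1L, 15)))
  expect_identical(d$policy[16], 1L)          # policy flips at row 16
  expect_identical(d$date[16], ts$policy_date) # policy day is first post day
  expect_identical(d$t_policy, d$t * d$policy)
  # window 2, written out exhaustively
  ts2 <- toy_series(2, 2)
  d2 <- build_its_design(ts2$series, ts2$policy_date, 2)
  expect_identical(d2$t, 1:4)
  expect_identical(d2$policy, c(0L, 0L, 1L, 1L))
  expect_identical(d2$t_policy, c(0L, 0L, 3L, 4L))
  expect_identical(d2$date, ts2$policy_date + (-2:1))
  # permuting input rows leaves the design unchanged
  perm <- sample(nrow(ts$series))
  d3 <- build_its_design(ts$series[perm, ], ts$policy_date, 15)
  expect_identical(d, d3)
})

test_that("missing days are interpolated up to a limit, then refused", {
  ts <- toy_series(10, 10)
  holey <- ts$series[-c(5, 12), ]
  expect_warning(d <- build_its_design(holey, ts$policy_date, 10),
                 "interpolated 2")
  expect_identical(nrow(d), 20L)
  expect_equal(d$y[5], (d$y[4] + d$y[6]) / 2, tolerance = 1e-12)
  # more than 20% missing is refused, naming dates
  holey2 <- ts$series[-(3:8), ]
  expect_error(build_its_design(holey2, ts$policy_date, 10), "missing dates")
  # a missing edge day cannot be interpolated
  expect_error(build_its_design(ts$series[-1, ], ts$policy_date, 10),
               "missing dates")
})

test_that("noiseless planted coefficients are recovered exactly", {
  planted <- c(0.0528, -0.0021, -0.0214, 0.002)
  ts <- toy_series(15, 15, beta = planted)
  fit <- fit_segmented_ols(build_its_design(ts$series, ts$policy_date, 15))
  expect_equal(fit$coefficients$estimate, planted, tolerance = 1e-10)
  # fitted + residuals reproduce y
  d <- build_its_design(ts$series, ts$policy_date, 15)
  expect_equal(unname(fit$fitted + fit$residuals), d$y, tolerance = 1e-10)
})

test_that("a constant series gives zero slopes and zero F numerator", {
  d <- tibble::tibble(date = as.Date("2020-03-01") + 0:19,
                      proportion = rep(0.04, 20))
  fit <- fit_segmented_ols(build_its_design(d, as.Date("2020-03-11"), 10))
  expect_equal(fit$coefficients$estimate[2:4], rep(0, 3), tolerance = 1e-12)
  # zero F numerator: the model explains nothing beyond the mean
  expect_lt(sum((fit$fitted - 0.04)^2), 1e-20)
})

test_that("inference matches a textbook normal-equations OLS oracle", {
  set.seed(33)
  for (rep in 1:5) {
    ts <- toy_series(15, 15, beta = c(0.05, -0.002, -0.02, 0.003),
                     sigma = 0.004, seed = 100 + rep)
    d <- build_its_design(ts$series, ts$policy_date, 15)
    fit <- fit_segmented_ols(d)
    X <- cbind(1, d$t, d$policy, d$t_policy)
    want <- oracle_ols(X, d$y)
    expect_equal(fit$coefficients$estimate, unname(want$est), tolerance = 1e-10)
    expect_equal(fit$coefficients$std_error, unname(want$se), tolerance = 1e-10)
    expect_equal(fit$coefficients$statistic, unname(want$t), tolerance = 1e-10)
    expect_equal(fit$coefficients$p_value, unname(want$p), tolerance = 1e-10)
    expect_equal(fit$f_statistic, want$f, tolerance = 1e-10)
    expect_equal(fit$f_p_value, want$f_p, tolerance = 1e-10)
  }
})

test_that("date shifts change only the intercept", {
  ts <- toy_series(15, 15, sigma = 0.003, seed = 8)
  f1 <- fit_segmented_ols(build_its_design(ts$series, ts$policy_date, 15))
  shifted <- ts$series
  shifted$date <- shifted$date + 1000
  f2 <- fit_segmented_ols(build_its_design(shifted, ts$policy_date + 1000, 15))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-12)
})

test_that("Newey-West errors differ from classical but keep estimates", {
  ts <- toy_series(15, 15, sigma = 0.003, seed = 12)
  d <- build_its_design(ts$series, ts$policy_date, 15)
  f_cl <- fit_segmented_ols(d)
  f_nw <- fit_segmented_ols(d, hac = TRUE)
  expect_equal(f_cl$coefficients$estimate, f_nw$coefficients$estimate)
  expect_false(isTRUE(all.equal(f_cl$coefficients$std_error,
                                f_nw$coefficients$std_error)))
  expect_true(f_cl$durbin_watson > 0 && f_cl$durbin_watson < 4)
})

test_that("sensitivity analysis is stable on noiseless data", {
  planted <- c(0.05, -0.001, 0.012, 0.0015)
  ts <- toy_series(25, 25, beta = planted)
  out <- sensitivity_analysis(ts$series, ts$policy_date,
                              windows = c(10, 15, 20, 25))
  expect_identical(nrow(out), 4L)
  # slopes are window-invariant; intercept and step re-parameterize exactly
  # with the window's time origin (t restarts at 1 on each window's first day)
  expect_equal(out$time, rep(planted[2], 4), tolerance = 1e-9)
  expect_equal(out$time_policy, rep(planted[4], 4), tolerance = 1e-9)
  shift <- 25 - out$window_days
  expect_equal(out$intercept, planted[1] + planted[2] * shift, tolerance = 1e-9)
  expect_equal(out$policy, planted[3] + planted[4] * shift, tolerance = 1e-9)
  expect_true(attr(out, "sign_stable")$policy)
  # a single window reproduces the plain fit
  one <- sensitivity_analysis(ts$series, ts$policy_date, windows = 15)
  f15 <- fit_segmented_ols(build_its_design(ts$series, ts$policy_date, 15))
  expect_equal(one$policy, f15$coefficients$estimate[3], tolerance = 1e-12)
})

test_that("type-I error of the policy test is nominal", {
  reps <- 400
  rej <- vapply(seq_len(reps), function(s) {
    ser <- generate_its_series(0.05, 0, 0, 0, 15, 15, sigma = 0.003, seed = s)
    f <- fit_segmented_ols(build_its_design(ser[, c("date", "proportion")],
                                            attr(ser, "policy_date"), 15))
    f$coefficients$p_value[3] < 0.05
  }, logical(1))
  # binomial 3-SE band around 0.05 at 400 reps
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("planted slope changes are recovered with low bias", {
  gamma <- 0.002
  est <- vapply(1:300, function(s) {
    ser <- generate_its_series(0.05, -0.002, -0.02, gamma, 15, 15,
                               sigma = 0.002, seed = 2000 + s)
    f <- fit_segmented_ols(build_its_design(ser[, c("date", "proportion")],
                                            attr(ser, "policy_date"), 15))
    f$coefficients$estimate[4]
  }, numeric(1))
  expect_lt(abs(mean(est) - gamma), 0.05 * abs(gamma) +
              3 * sd(est) / sqrt(length(est)))
})
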
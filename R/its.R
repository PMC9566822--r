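#' Build an interrupted-time-series design around a policy date
#'
#' The design covers `window_days` days before and after the policy date:
#' time index `t = 1, ..., 2 * window_days` starting on the first
#' pre-policy day, a policy indicator `P` that is 0 before the policy date
#' and 1 from the policy date onward (the policy day itself is the first
#' post-policy day), and their interaction `t * P`. Missing days inside the
#' window are linearly interpolated with a warning; more than 20% missing,
#' or a missing first/last day, refuses to fit and names the missing
#' dates.
#'
#' @param series A tibble/data.frame with columns `date` and `proportion`
#'   (daily values; row order is irrelevant).
#' @param policy_date The intervention date.
#' @param window_days Days on each side of the policy date (default 15).
#' @return A tibble `date`, `t`, `policy`, `t_policy`, `y` of
#'   `2 * window_days` rows, with attributes `policy_date` and
#'   `window_days`.
#' @export
build_its_design <- function(series, policy_date, window_days = 15) {
  stopifnot(all(c("date", "proportion") %in% names(series)), window_days >= 2)
  policy_date <- as.Date(policy_date)
  dates <- seq(policy_date - window_days, policy_date + window_days - 1, by = "day")
  s <- series[!duplicated(series$date), ]
  y <- s$proportion[match(dates, as.Date(s$date))]
  miss <- is.na(y)
  if (any(miss)) {
    if (miss[1] || miss[length(y)] || mean(miss) > 0.20)
      stop("insufficient coverage of the policy window; missing dates: ",
           paste(format(dates[miss]), collapse = ", "))
    warning(sprintf("interpolated %d missing day(s) inside the window: %s",
                    sum(miss), paste(format(dates[miss]), collapse = ", ")))
    y <- stats::approx(x = which(!miss), y = y[!miss], xout = seq_along(y))$y
  }
  n <- 2L * window_days
  t <- seq_len(n)
  p <- as.integer(t > window_days)
  out <- tibble(date = dates, t = t, policy = p, t_policy = t * p, y = y)
  attr(out, "policy_date") <- policy_date
  attr(out, "window_days") <- as.integer(window_days)
  out
}

#' Fit the segmented regression of an interrupted time series
#'
#' Ordinary least squares of the daily proportion on `[1, t, P, t * P]`:
#' the intercept is the modelled level on day `t = 0`, `t` the pre-policy
#' slope, `P` the immediate level change at the policy date and `t * P` the
#' post-policy slope change. Classical standard errors by default;
#' `hac = TRUE` switches to Newey-West errors. The Durbin-Watson statistic
#' is reported so serial correlation can be judged either way.
#'
#' @param design A design from [build_its_design()].
#' @param hac Use heteroskedasticity-and-autocorrelation-consistent
#'   (Newey-West) standard errors instead of classical ones.
#' @return An object of class `its_fit`: `coefficients` tibble (`term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`), `f_statistic`,
#'   `f_p_value`, `durbin_watson`, `sigma`, `n`, `policy_date`,
#'   `window_days`, `fitted`, `residuals`, and the underlying `lm` object.
#' @export
fit_segmented_ols <- function(design, hac = FALSE) {
  stopifnot(all(c("t", "policy", "t_policy", "y") %in% names(design)))
  fit <- stats::lm(y ~ t + policy + t_policy, data = design)
  if (qr(fit)$rank < 4) stop("singular design")
  est <- stats::coef(fit)
  vc <- if (hac) {
    # fixed truncation lag (the usual 4*(n/100)^(2/9) rule) keeps the
    # bandwidth sane on short policy windows
    lag <- max(1L, floor(4 * (nrow(design) / 100)^(2 / 9)))
    sandwich::NeweyWest(fit, lag = lag, prewhite = FALSE)
  } else suppressWarnings(stats::vcov(fit))
  se <- sqrt(diag(vc))
  df <- stats::df.residual(fit)
  tstat <- est / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # a noiseless planted series fits perfectly; summary()'s near-zero-residual
  # warning is expected there, not informative
  sm <- suppressWarnings(summary(fit))
  fs <- sm$fstatistic
  e <- stats::residuals(fit)
  dw <- sum(diff(e)^2) / sum(e^2)
  structure(list(
    coefficients = tibble(
      term = c("intercept", "time", "policy", "time_policy"),
      estimate = unname(est), std_error = unname(se),
      statistic = unname(tstat), p_value = unname(pval)),
    f_statistic = unname(fs[1]),
    f_p_value = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
    durbin_watson = dw, sigma = sm$sigma, n = nrow(design),
    policy_date = attr(design, "policy_date"),
    window_days = attr(design, "window_days"),
    fitted = stats::fitted(fit), residuals = e, hac = hac, lm = fit),
    class = "its_fit")
}

#' @export
print.its_fit <- function(x, ...) {
  cat(sprintf("Interrupted time series fit (window %s days, n = %d%s)\n",
              x$window_days %||% "?", x$n, if (x$hac) ", Newey-West SE" else ""))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  cat(sprintf("F = %.3f (p = %.4g), Durbin-Watson = %.3f\n",
              x$f_statistic, x$f_p_value, x$durbin_watson))
  invisible(x)
}

#' Sensitivity of ITS estimates to the window length
#'
#' Refits the segmented regression for each window length and summarizes
#' the sign stability of the policy step and slope-change estimates.
#'
#' @param series Daily series (`date`, `proportion`) covering the largest
#'   window.
#' @param policy_date Intervention date.
#' @param windows Window lengths in days (default `c(10, 15, 20, 25)`).
#' @param hac Passed to [fit_segmented_ols()].
#' @return Tibble with one row per window: estimates, p-values, F; the
#'   sign-stability summary (are all `policy` and all `time_policy`
#'   estimates of one sign) is in attribute `sign_stable`.
#' @export
sensitivity_analysis <- function(series, policy_date, windows = c(10, 15, 20, 25),
                                 hac = FALSE) {
  rows <- lapply(windows, function(w) {
    f <- fit_segmented_ols(build_its_design(series, policy_date, w), hac = hac)
    cf <- f$coefficients
    tibble(window_days = w,
           intercept = cf$estimate[1], p_intercept = cf$p_value[1],
           time = cf$estimate[2], p_time = cf$p_value[2],
           policy = cf$estimate[3], p_policy = cf$p_value[3],
           time_policy = cf$estimate[4], p_time_policy = cf$p_value[4],
           f_statistic = f$f_statistic, f_p_value = f$f_p_value)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "sign_stable") <- list(
    policy = length(unique(sign(out$policy))) == 1,
    time_policy = length(unique(sign(out$time_policy))) == 1)
  out
}
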
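#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Successes (vector), `0 <= k <= n`.
#' @param n Trials (vector, `n >= 1`).
#' @param level Confidence level (default 0.95).
#' @return A two-column matrix `low`, `high`, bounds inside `[0, 1]`;
#'   `k = 0` gives a lower bound of exactly 0 and `k = n` an upper bound of
#'   exactly 1.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(k < 0 | k > n)) stop("need 0 <= k <= n")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  low <- pmax(centre - half, 0)
  high <- pmin(centre + half, 1)
  low[k == 0] <- 0
  high[k == n] <- 1
  cbind(low = low, high = high)
}

period_start <- function(date, granularity) {
  switch(granularity,
         day = date,
         week = date - (as.integer(format(date, "%u")) - 1L),  # ISO week, Monday
         month = as.Date(format(date, "%Y-%m-01")),
         stop("granularity must be day, week or month"))
}

period_end <- function(start, granularity) {
  switch(granularity,
         day = start,
         week = start + 6L,
         month = as.Date(format(start + 32L, "%Y-%m-01")) - 1L)
}

#' Aggregate matched tweets into proportion series
#'
#' Computes, per period and stratum, the proportion of mental-health
#' matched tweets among all eligible (denominator) tweets, with a 95%
#' confidence interval. Multi-label tweets count once in each matched
#' subgroup's numerator and once in the any-subgroup numerator, so
#' subgroup proportions may sum above the overall proportion.
#'
#' @param matched Tibble of matched tweets with columns `created_at` (or
#'   `date`), a `subgroups` list-column, and any stratum columns used.
#' @param eligible Tibble of denominator tweets (same date convention and
#'   stratum columns).
#' @param granularity `"day"`, `"week"` (ISO, Monday start) or `"month"`
#'   (calendar), all UTC.
#' @param by Stratum columns: any of `"state"`, `"cohort"`, `"subgroup"`.
#'   `"subgroup"` unnests the multi-label subgroup sets.
#' @param level Confidence level for the Wilson interval.
#' @param ci_method `"wilson"` (default) or `"normal"` (Wald) for
#'   comparison with normal-approximation intervals.
#' @return Tibble: `period_start`, `period_end`, `granularity`, stratum
#'   columns, `numerator`, `denominator`, `proportion`, `ci_low`,
#'   `ci_high`. Periods with matches but a zero denominator raise an error
#'   (inconsistent inputs); periods with denominator tweets and no matches
#'   get numerator 0.
#' @export
aggregate_proportions <- function(matched, eligible,
                                  granularity = c("week", "month", "day"),
                                  by = character(), level = 0.95,
                                  ci_method = c("wilson", "normal")) {
  granularity <- match.arg(granularity)
  ci_method <- match.arg(ci_method)
  stopifnot(all(by %in% c("state", "cohort", "subgroup")))
  strat_den <- setdiff(by, "subgroup")

  m <- tibble(date = tweet_date(matched))
  for (s in strat_den) m[[s]] <- matched[[s]]
  if ("subgroup" %in% by) {
    stopifnot(!is.null(matched$subgroups))
    reps <- lengths(matched$subgroups)
    m <- m[rep(seq_len(nrow(m)), reps), , drop = FALSE]
    m$subgroup <- unlist(matched$subgroups)
  }
  e <- tibble(date = tweet_date(eligible))
  for (s in strat_den) e[[s]] <- eligible[[s]]

  m$period_start <- period_start(m$date, granularity)
  e$period_start <- period_start(e$date, granularity)
  den <- dplyr::count(e, dplyr::across(dplyr::all_of(c("period_start", strat_den))),
                      name = "denominator")
  num <- dplyr::count(m, dplyr::across(dplyr::all_of(c("period_start", by))),
                      name = "numerator")
  if ("subgroup" %in% by) {
    grid <- tidyr::crossing(den, subgroup = sort(unique(m$subgroup)))
  } else grid <- den
  out <- dplyr::left_join(grid, num,
                          by = c("period_start", by))
  out$numerator[is.na(out$numerator)] <- 0L
  orphan <- dplyr::anti_join(num, den, by = c("period_start", strat_den))
  if (nrow(orphan) > 0)
    stop("matched tweets in periods/strata with zero denominator: inconsistent inputs")
  out$proportion <- out$numerator / out$denominator
  ci <- if (ci_method == "wilson") {
    wilson_ci(out$numerator, out$denominator, level)
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    se <- sqrt(out$proportion * (1 - out$proportion) / out$denominator)
    cbind(low = pmax(out$proportion - z * se, 0),
          high = pmin(out$proportion + z * se, 1))
  }
  out$ci_low <- ci[, "low"]
  out$ci_high <- ci[, "high"]
  out$period_end <- period_end(out$period_start, granularity)
  out$granularity <- granularity
  out <- out[order(out$period_start), ]
  dplyr::relocate(as_tibble(out), "period_start", "period_end", "granularity")
}

tweet_date <- function(x) {
  if ("date" %in% names(x)) as.Date(x$date) else as.Date(x$created_at)
}

#' Mean tweets per user on each topic, by cohort
#'
#' The denominator for a cohort is its number of distinct users (including
#' users with no tweet on the topic), so averages are comparable across
#' topics.
#'
#' @param assignments Tibble with columns `user_id` and `topic`, one row
#'   per assigned tweet.
#' @param user_cohorts Tibble `user_id`, `cohort`: the full user roster per
#'   cohort. Every assigned tweet's user must appear here.
#' @return Tibble `cohort`, `topic`, `avg` (mean tweets per user), one row
#'   per cohort x topic in the cross of observed topics and cohorts.
#' @export
per_user_topic_average <- function(assignments, user_cohorts) {
  stopifnot(all(c("user_id", "topic") %in% names(assignments)),
            all(c("user_id", "cohort") %in% names(user_cohorts)))
  if (nrow(user_cohorts) == 0) stop("empty cohort roster")
  if (anyDuplicated(user_cohorts$user_id))
    stop("user appears twice in the cohort roster")
  miss <- setdiff(assignments$user_id, user_cohorts$user_id)
  if (length(miss)) stop("assigned tweets from users missing a cohort label")
  n_users <- dplyr::count(user_cohorts, .data$cohort, name = "n_users")
  if (any(n_users$n_users == 0)) stop("empty cohort")
  a <- dplyr::left_join(assignments, user_cohorts, by = "user_id")
  counts <- dplyr::count(a, .data$cohort, .data$topic, name = "n_tweets")
  grid <- tidyr::crossing(cohort = n_users$cohort,
                          topic = sort(unique(assignments$topic)))
  out <- dplyr::left_join(grid, counts, by = c("cohort", "topic"))
  out$n_tweets[is.na(out$n_tweets)] <- 0L
  out <- dplyr::left_join(out, n_users, by = "cohort")
  out$avg <- out$n_tweets / out$n_users
  out[, c("cohort", "topic", "avg")]
}

#' Log ratio of per-user topic usage between cohorts
#'
#' `log(avg_hcw / avg_gen)`, the cohort-contrast statistic for per-user
#' topic averages. When either average is zero and user counts are
#' supplied, a Haldane-style half-tweet is added to both cohorts' totals
#' (`avg' = (avg * n_users + 0.5) / n_users`) so every topic gets a finite
#' ratio; such values are flagged.
#'
#' @param avg_hcw,avg_gen Mean tweets per user (vectors recycled to common
#'   length).
#' @param n_hcw_users,n_gen_users Optional cohort sizes enabling the
#'   zero-count smoothing.
#' @return Tibble `log_ratio`, `smoothed`. Without smoothing, `avg_gen = 0`
#'   yields `NA` with a warning (undefined ratio).
#' @export
log_topic_ratio <- function(avg_hcw, avg_gen, n_hcw_users = NULL,
                            n_gen_users = NULL) {
  n <- max(length(avg_hcw), length(avg_gen))
  h <- rep_len(avg_hcw, n); g <- rep_len(avg_gen, n)
  if (any(h < 0 | g < 0)) stop("averages must be non-negative")
  zero <- h == 0 | g == 0
  smoothed <- rep(FALSE, n)
  if (any(zero)) {
    if (!is.null(n_hcw_users) && !is.null(n_gen_users)) {
      h[zero] <- (h[zero] * n_hcw_users + 0.5) / n_hcw_users
      g[zero] <- (g[zero] * n_gen_users + 0.5) / n_gen_users
      smoothed[zero] <- TRUE
    } else if (any(g == 0)) {
      warning("avg_gen is zero and no user counts supplied: ratio undefined")
    }
  }
  tibble(log_ratio = ifelse(g > 0 & h > 0, log(h / g), NA_real_),
         smoothed = smoothed)
}
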
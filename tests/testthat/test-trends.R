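test_that("Wilson interval matches a numerical score-test inversion", {
  cases <- rbind(c(7, 50), c(1, 10), c(25, 30), c(499, 1000), c(3, 3),
                 c(0, 10))
  for (i in seq_len(nrow(cases))) {
    k <- cases[i, 1]; n <- cases[i, 2]
    got <- wilson_ci(k, n)
    want <- oracle_wilson(k, n)
    expect_equal(unname(got[1, "low"]), unname(want["low"]), tolerance = 1e-10)
    expect_equal(unname(got[1, "high"]), unname(want["high"]), tolerance = 1e-10)
  }
  expect_identical(unname(wilson_ci(0, 10)[1, "low"]), 0)
  expect_identical(unname(wilson_ci(10, 10)[1, "high"]), 1)
  expect_error(wilson_ci(1, 0), "n")
  expect_error(wilson_ci(5, 3), "k")
})

test_that("Wilson interval width shrinks monotonically in n at fixed k/n", {
  ns <- c(10, 40, 160, 640, 2560)
  w <- vapply(ns, function(n) diff(wilson_ci(0.3 * n, n)[1, ]), numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("proportion aggregation reproduces printed-precision shares", {
  # the corpus-level subgroup shares are fixed arithmetic identities
  total <- 4213005
  expect_identical(round(100 * 2161357 / total, 1), 51.3)
  expect_identical(round(100 * 1923635 / total, 2), 45.66)
  expect_identical(round(100 * 225205 / total, 2), 5.35)
  expect_identical(round(100 * 150006 / total, 2), 3.56)
  expect_identical(round(100 * 789967 / total, 2), 18.75)
  expect_identical(round(100 * 49307 / total, 2), 1.17)
})

test_that("aggregation counts, strata and CIs are consistent", {
  dates <- as.Date("2020-03-02") + 0:13    # two ISO weeks
  matched <- tibble::tibble(
    date = dates[c(1, 2, 3, 8, 9)],
    state = c("Ohio", "Ohio", "Texas", "Ohio", "Texas"),
    subgroups = list("anxiety", c("anxiety", "depression"), "depression",
                     "insomnia", "anxiety"))
  eligible <- tibble::tibble(date = rep(dates, 2),
                             state = rep(c("Ohio", "Texas"), each = 14))
  out <- aggregate_proportions(matched, eligible, granularity = "week")
  expect_identical(out$denominator, c(14L, 14L))
  expect_identical(out$numerator, c(3L, 2L))
  expect_true(all(out$ci_low <= out$proportion & out$proportion <= out$ci_high))
  # numerators telescope across periods within a stratum
  by_state <- aggregate_proportions(matched, eligible, granularity = "week",
                                    by = "state")
  expect_identical(sum(by_state$numerator[by_state$state == "Ohio"]), 3L)
  # multi-label tweets count once per matched subgroup
  by_sub <- aggregate_proportions(matched, eligible, granularity = "month",
                                  by = "subgroup")
  expect_identical(sum(by_sub$numerator), 6L)   # 5 tweets, one double-labelled
  expect_gt(sum(by_sub$numerator), nrow(matched))
  # order invariance
  perm <- sample(nrow(matched))
  out2 <- aggregate_proportions(matched[perm, ], eligible[sample(28), ],
                                granularity = "week")
  expect_identical(out, out2)
  # matches without denominators are inconsistent inputs
  bad_m <- tibble::tibble(date = as.Date("2021-01-01"), subgroups = list("anxiety"))
  expect_error(aggregate_proportions(bad_m, eligible), "denominator")
})

test_that("weekly proportions recover a planted emission rate", {
  cfg <- synth_config(
    n_users = 800, tweets_per_user = 20, spam_users = 0,
    baseline_rates = rbind(general = c(anxiety = 0, depression = 0.05,
                                       insomnia = 0, addiction = 0),
                           hcw = c(anxiety = 0, depression = 0.05,
                                   insomnia = 0, addiction = 0)),
    its_effects = list(),      # no planted policy effects anywhere
    nuisance_fractions = c(url = 0, retweet = 0, non_english = 0,
                           multi_state_user = 0),
    seed = 23)
  f <- withr::local_tempfile(fileext = ".jsonl")
  generate_corpus(cfg, f, lexicon = mh_lex)
  res <- apply_filters(read_tweet_stream(f), mh_lex, spam_threshold = 1000)
  out <- aggregate_proportions(res$kept, res$eligible, granularity = "week")
  overall <- sum(out$numerator) / sum(out$denominator)
  se <- sqrt(0.05 * 0.95 / sum(out$denominator))
  expect_lt(abs(overall - 0.05), 3 * se)
})

test_that("per-user topic averages include zero-tweet users in denominators", {
  assignments <- tibble::tibble(user_id = c("a", "a", "a"), topic = c(2, 2, 2))
  roster <- tibble::tibble(user_id = c("a", "b"), cohort = c("hcw", "hcw"))
  out <- per_user_topic_average(assignments, roster)
  expect_identical(out$avg[out$topic == 2], 1.5)   # 3 tweets over 2 users
  roster1 <- tibble::tibble(user_id = "a", cohort = "hcw")
  out1 <- per_user_topic_average(assignments, roster1)
  expect_identical(out1$avg, 3)
  # symmetric cohorts give identical maps
  a2 <- tibble::tibble(user_id = c("a", "b"), topic = c(1, 1))
  r2 <- tibble::tibble(user_id = c("a", "b"), cohort = c("x", "y"))
  out2 <- per_user_topic_average(a2, r2)
  expect_identical(out2$avg[out2$cohort == "x"], out2$avg[out2$cohort == "y"])
  expect_error(per_user_topic_average(a2, r2[0, ]), "empty")
  expect_error(per_user_topic_average(a2, tibble::tibble(user_id = "a",
                                                         cohort = "x")),
               "missing")
})

test_that("a planted two-fold HCW topic excess is recovered", {
  cfg <- synth_config(n_users = 1500, tweets_per_user = 10, spam_users = 0,
                      nuisance_fractions = c(url = 0, retweet = 0,
                                             non_english = 0,
                                             multi_state_user = 0),
                      hcw_fraction = 0.3,
                      hcw_topic_bias = c(topic = 1, factor = 2), seed = 41)
  f <- withr::local_tempfile(fileext = ".jsonl")
  truth <- generate_corpus(cfg, f, lexicon = mh_lex)
  tw <- truth$tweets
  roster <- tibble::tibble(user_id = truth$users$user_id,
                           cohort = truth$users$cohort)
  avg <- per_user_topic_average(
    tibble::tibble(user_id = tw$user_id, topic = tw$topic), roster)
  wide <- tidyr::pivot_wider(avg, names_from = cohort, values_from = avg)
  lr <- log_topic_ratio(wide$hcw, wide$general)$log_ratio
  # planted log-ratio on topic 1: log(w_hcw[1]/w_gen[1]) with equal tweet
  # volumes per user
  k <- cfg$topic_params$k_true
  planted <- log((2 / (k + 1)) / (1 / k))
  expect_lt(abs(lr[1] - planted), 0.15)
})

test_that("log topic ratio handles identity, zeros and smoothing", {
  expect_equal(log_topic_ratio(2, 1)$log_ratio, log(2))
  expect_equal(log_topic_ratio(1, 1)$log_ratio, 0)
  expect_warning(out <- log_topic_ratio(1, 0), "undefined")
  expect_true(is.na(out$log_ratio))
  sm <- log_topic_ratio(0, 0.5, n_hcw_users = 10, n_gen_users = 10)
  expect_true(sm$smoothed)
  expect_equal(sm$log_ratio, log((0.5 / 10) / ((0.5 * 10 + 0.5) / 10)))
  expect_error(log_topic_ratio(-1, 1), "non-negative")
})
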